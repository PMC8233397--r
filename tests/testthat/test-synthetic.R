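test_that("configuration validation rejects infeasible setups", {
  drugs <- tibble::tibble(name = c("a", "b"), class = c("X", "Y"),
                          weight = c(1, 1))
  events <- tibble::tibble(name = c("e1", "e2"), weight = c(1, 3))
  expect_s3_class(simulation_config(100, drugs, events, lambda_events = 0.5),
                  "simulation_config")
  expect_error(simulation_config(100, drugs, events, lambda_events = 5),
               "infeasible")
  expect_error(simulation_config(100, drugs, dplyr::mutate(events, weight = -1)),
               "non-negative")
  expect_error(simulation_config(
    100, drugs, events, lambda_events = 0.5,
    signals = tibble::tibble(drug = "zz", event = "e1", multiplier = 2)),
    "not in universe")
  cfg <- simulation_config(100, drugs, events, lambda_events = 0.5)
  # weights normalized
  expect_equal(sum(cfg$events$weight), 1)
})

test_that("identical seeds give byte-identical output, different seeds differ", {
  cfg <- acei_arb_config(n_reports = 300, seed = 5)
  s1 <- generate_reports(cfg)
  s2 <- generate_reports(cfg)
  expect_identical(s1$reports, s2$reports)
  expect_identical(s1$truth$mention_map, s2$truth$mention_map)
  s3 <- generate_reports(acei_arb_config(n_reports = 300, seed = 6))
  expect_false(identical(s1$reports$reactions, s3$reports$reactions))
})

test_that("zero corruption renders every mention verbatim canonical and fully recoverable", {
  cfg <- acei_arb_config(n_reports = 500, seed = 2, corruption_rate = 0)
  sim <- generate_reports(cfg)
  mm <- sim$truth$mention_map
  expect_true(all(mm$render == "canonical"))
  hit <- map_drug(mm$mention, default_drug_dictionary())
  expect_true(all(hit == mm$ingredient))
})

test_that("emitted triples equal the generator's internal tally", {
  cfg <- acei_arb_config(n_reports = 400, seed = 13)
  sim <- generate_reports(cfg)
  expect_equal(nrow(sim$truth$mention_map),
               sum(lengths(sim$reports$drug_mentions)))
  # every report has >= 1 event and no duplicate preferred terms inside one
  n_ev <- lengths(sim$reports$reactions)
  expect_true(all(n_ev >= 1))
  dedup <- vapply(sim$reports$reactions,
                  function(r) anyDuplicated(tolower(r)) == 0, logical(1))
  expect_true(all(dedup))
})

test_that("corrupted mentions stay within the configured edit distance of their source", {
  cfg <- acei_arb_config(n_reports = 2000, seed = 17, corruption_rate = 0.3)
  sim <- generate_reports(cfg)
  mm <- sim$truth$mention_map
  corr <- mm[mm$render == "corrupted", ]
  expect_gt(nrow(corr), 50)
  dict <- default_drug_dictionary()
  for (k in seq_len(nrow(corr))) {
    own_aliases <- c(corr$ingredient[k],
                     dict$alias[dict$ingredient == corr$ingredient[k]])
    dmin <- min(adist(clean_name(corr$mention[k]), own_aliases))
    expect_lte(dmin, cfg$corruption$max_edits)
    # rejection guard: never within max_edits of a different ingredient
    other <- dict$alias[dict$ingredient != corr$ingredient[k]]
    expect_gt(min(adist(clean_name(corr$mention[k]), other)),
              cfg$corruption$max_edits)
  }
})

test_that("realized counts under the null match expectation within 4 SD", {
  # uniform event weights make the truth formula exact under
  # without-replacement sampling (exchangeability)
  drugs <- tibble::tibble(name = paste0("drug", 1:4), class = "X",
                          weight = c(0.4, 0.3, 0.2, 0.1))
  events <- tibble::tibble(name = paste0("ev", 1:8), weight = rep(1 / 8, 8))
  cfg <- simulation_config(20000, drugs, events, lambda_events = 0.5,
                           corruption = list(rate = 0, max_edits = 2),
                           seed = 99)
  sim <- generate_reports(cfg)
  norm <- tibble::tibble(
    report_id = sim$reports$report_id,
    quarter = sim$reports$quarter, age = sim$reports$age,
    weight = sim$reports$weight, sex = sim$reports$sex,
    indication = sim$reports$indication,
    drugs = lapply(sim$reports$drug_mentions, tolower),
    events = lapply(sim$reports$reactions, tolower),
    unmapped_drugs = list(character()), unmapped_events = list(character())
  )
  cube <- build_cube(norm, drugs$name, events$name)
  E <- sim$truth$expected_counts
  # Poisson-scale SD bound per cell
  for (j in drugs$name) for (i in events$name) {
    expect_lt(abs(cube$counts[i, j] - E[i, j]), 4 * sqrt(E[i, j]) + 4,
              label = paste(i, j))
  }
})

test_that("the asymptotic PRR of an injected pair matches the documented formula", {
  drugs <- tibble::tibble(name = c("sig", "c1", "c2"), class = "X",
                          weight = c(0.2, 0.4, 0.4))
  events <- tibble::tibble(name = paste0("ev", 1:10),
                           weight = c(0.3, rep(0.7 / 9, 9)))
  signals <- tibble::tibble(drug = "sig", event = "ev2", multiplier = 3)
  cfg <- simulation_config(100000, drugs, events, signals = signals,
                           lambda_events = 0.25,
                           corruption = list(rate = 0, max_edits = 2),
                           seed = 123)
  sim <- generate_reports(cfg)
  norm <- tibble::tibble(
    report_id = sim$reports$report_id, quarter = "x", age = 50, weight = 70,
    sex = "F", indication = "Hypertension",
    drugs = lapply(sim$reports$drug_mentions, tolower),
    events = lapply(sim$reports$reactions, tolower),
    unmapped_drugs = list(character()), unmapped_events = list(character())
  )
  cube <- build_cube(norm, drugs$name, events$name)
  got <- prr(cube, "ev2", "sig")$prr
  want <- prr_asymptote(cfg, "sig", "ev2")
  expect_equal(want, 3 / (1 + (0.7 / 9) * 2), tolerance = 1e-12)
  expect_lt(abs(got - want) / want, 0.10)
})

test_that("study-shaped configuration validates and carries the documented signals", {
  cfg <- acei_arb_config()
  expect_s3_class(cfg, "simulation_config")
  expect_equal(nrow(cfg$drugs), 16)
  expect_equal(sum(cfg$drugs$class == "ACEI"), 10)
  expect_equal(nrow(cfg$events), 13)
  expect_setequal(unique(cfg$signals$drug), c("quinapril", "trandolapril"))
  expect_setequal(unique(cfg$signals$multiplier), c(5, 3))
  # null variant drops all signals
  expect_equal(nrow(acei_arb_config(signal_multipliers = numeric())$signals), 0)
})

test_that("write_simulation emits both dialects plus truth and they reconcile", {
  cfg <- acei_arb_config(n_reports = 120, seed = 3)
  sim <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  flat <- read_flat_csv(paths["flat"])
  expect_equal(nrow(flat), nrow(sim$reports))
  trio <- read_faers_quarter(paths["demo"], paths["drug"], paths["reac"])
  expect_equal(nrow(trio), nrow(sim$reports))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(length(truth$expected_counts), nrow(cfg$drugs) + 1)  # + event col
  expect_equal(names(truth$expected_counts)[1], "event")
})
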