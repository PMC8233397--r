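test_that("build_cube counts distinct report-drug-event triples", {
  norm <- structure(tibble::tibble(
    report_id = c("r1", "r2"),
    quarter = "2010Q1", age = 50, weight = 70, sex = "F",
    indication = "Hypertension",
    drugs = list("a", c("a", "b")),
    events = list(c("x", "y", "x"), "y"),
    unmapped_drugs = list(character(), character()),
    unmapped_events = list(character(), character())
  ), class = c("normalized_reports", "tbl_df", "tbl", "data.frame"))
  cube <- build_cube(norm[1, ], c("a", "b"), c("x", "y"))
  expect_equal(cube$counts["x", "a"], 1L)   # duplicate mention counts once
  expect_equal(cube$counts["y", "a"], 1L)
  expect_equal(unname(cube$n_j), c(2, 0))
  expect_equal(cube$N, 2)
  # a report with two drugs contributes to both columns
  cube2 <- build_cube(norm, c("a", "b"), c("x", "y"))
  expect_equal(cube2$counts["y", "b"], 1L)
  expect_equal(unname(cube2$n_j), c(3, 1))
})

test_that("cube margins equal brute-force triple enumeration on generated reports", {
  cfg <- acei_arb_config(n_reports = 200, seed = 8)
  sim <- generate_reports(cfg)
  norm <- normalize_reports(sim$reports, default_drug_dictionary(),
                            default_event_vocabulary())
  cube <- build_cube(norm, cfg$drugs$name, cfg$events$name)
  trip <- triples_of(norm)
  expect_equal(cube$N, length(trip))
  for (d in sample(cfg$drugs$name, 4)) {
    expect_equal(unname(cube$n_j[d]),
                 sum(grepl(paste0("\\|", d, "\\|"), trip)))
  }
})

test_that("prr reproduces the 2x2 worked example and handles degenerate cells", {
  counts <- matrix(0L, 2, 2, dimnames = list(c("e1", "e2"), c("d1", "d2")))
  counts["e1", "d1"] <- 6L; counts["e2", "d1"] <- 14L
  counts["e1", "d2"] <- 24L; counts["e2", "d2"] <- 176L
  cube <- new_cube(counts)
  res <- prr(cube, "e1", "d1")
  expect_equal(res$prr, (6 / 20) / ((30 - 6) / (220 - 20)))  # = 2.5
  expect_equal(res$prr, 2.5, tolerance = 1e-12)

  # proportional table -> PRR 1 everywhere
  prop <- new_cube(matrix(c(10L, 30L, 20L, 60L), 2, 2,
                          dimnames = list(c("e1", "e2"), c("d1", "d2"))))
  st <- signal_table(prop)
  expect_true(all(abs(st$prr - 1) < 1e-12))

  # zero numerator -> PRR 0, undefined CI, never flagged
  z <- counts; z["e1", "d1"] <- 0L
  res0 <- prr(new_cube(z), "e1", "d1")
  expect_equal(res0$prr, 0)
  expect_true(is.na(res0$ci_low))
  expect_false(apply_criteria(res0)$flagged)

  expect_error(prr(cube, 5, 1), "out of range")
})

test_that("as_printed CI matches direct evaluation of the published formula", {
  sd_expected <- sqrt((20 - 6) / (20 * 6) + (220 - 20) / (20 * 220))
  ci <- compute_ci(6, 20, 30, 220, variant = "as_printed")
  expect_equal(ci$sd_log, sd_expected, tolerance = 1e-12)
  expect_equal(ci$ci_low, exp(log(2.5) - 1.96 * sd_expected), tolerance = 1e-12)
  expect_equal(ci$ci_high, exp(log(2.5) + 1.96 * sd_expected), tolerance = 1e-12)

  set.seed(17)
  for (k in 1:200) {
    n_j <- sample(5:400, 1)
    r <- sample.int(n_j, 1)
    extra <- sample(50:4000, 1)
    t_i <- r + sample.int(extra, 1)
    N <- n_j + extra
    ci <- compute_ci(r, n_j, t_i, N, variant = "as_printed")
    expect_equal(ci$sd_log, sqrt((n_j - r) / (n_j * r) + (N - n_j) / (n_j * N)),
                 tolerance = 1e-12)
  }
})

test_that("delta_standard SD matches an independent delta-method oracle", {
  set.seed(23)
  for (k in 1:1000) {
    a <- sample.int(50, 1)
    b <- sample(0:80, 1)
    c <- sample.int(60, 1)
    d <- sample(0:500, 1)
    # delta-method SE of log[(a/(a+b)) / (c/(c+d))] on the 2x2 table
    oracle <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
    got <- compute_ci(a, a + b, a + c, a + b + c + d,
                      variant = "delta_standard")
    expect_equal(got$sd_log, oracle, tolerance = 1e-10)
  }
})

test_that("CI width shrinks toward 1 as counts grow at fixed proportions", {
  widths <- vapply(c(1, 10, 100, 1000), function(m) {
    ci <- compute_ci(5 * m, 20 * m, 30 * m, 220 * m)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("criteria coding agrees with a truth-table enumeration, with boundaries", {
  # all 8 boolean combinations of (r>3, prr>2, ci_low>1)
  grid <- expand.grid(c1 = c(FALSE, TRUE), c2 = c(FALSE, TRUE),
                      c3 = c(FALSE, TRUE))
  for (k in seq_len(nrow(grid))) {
    row <- tibble::tibble(
      r = if (grid$c1[k]) 10 else 2,
      prr = if (grid$c2[k]) 5 else 1.5,
      ci_low = if (grid$c3[k]) 1.4 else 0.7
    )
    out <- apply_criteria(row)
    expect_equal(out$criteria_code, sum(grid$c1[k], grid$c2[k], grid$c3[k]))
    expect_equal(out$flagged, all(grid$c1[k], grid$c2[k], grid$c3[k]))
  }
  # strict boundaries: r = 3 fails "more than 3", r = 4 passes; PRR = 2 and
  # ci_low = 1 both fail their strict inequalities
  expect_equal(apply_criteria(tibble::tibble(r = 3, prr = 8, ci_low = 3))$criteria_code, 2L)
  expect_equal(apply_criteria(tibble::tibble(r = 4, prr = 8, ci_low = 3))$criteria_code, 3L)
  expect_equal(apply_criteria(tibble::tibble(r = 5, prr = 2, ci_low = 3))$criteria_code, 2L)
  expect_equal(apply_criteria(tibble::tibble(r = 5, prr = 8, ci_low = 1))$criteria_code, 2L)
  # undefined PRR fails criteria 2 and 3
  und <- apply_criteria(tibble::tibble(r = 5, prr = NA_real_, ci_low = NA_real_))
  expect_equal(und$criteria_code, 1L)
  expect_false(und$flagged)
  # example coding from the published table caption
  expect_equal(apply_criteria(tibble::tibble(r = 5, prr = 1.2, ci_low = 0.8))$criteria_code, 1L)
  expect_equal(apply_criteria(tibble::tibble(r = 2, prr = 8, ci_low = 3))$criteria_code, 2L)
})

test_that("signal_table covers every pair, in order, invariant to column permutation", {
  cfg <- acei_arb_config(n_reports = 1000, seed = 4)
  sim <- generate_reports(cfg)
  norm <- normalize_reports(sim$reports, default_drug_dictionary(),
                            default_event_vocabulary())
  cube <- build_cube(norm, cfg$drugs$name, pulmonary_events())
  st <- signal_table(cube)
  expect_equal(nrow(st), 13 * 16)
  expect_equal(st$drug, rep(cfg$drugs$name, each = 13))

  perm <- sample(seq_along(cube$drugs))
  cube_p <- new_cube(cube$counts[, perm])
  st_p <- signal_table(cube_p)
  key <- function(x) paste(x$drug, x$event)
  expect_equal(st_p$prr[match(key(st), key(st_p))], st$prr)
  expect_equal(st_p$ci_low[match(key(st), key(st_p))], st$ci_low)
})

test_that("PRR is scale invariant and its CI never widens under scaling", {
  counts <- matrix(c(6L, 14L, 24L, 176L, 3L, 9L), 2, 3,
                   dimnames = list(c("e1", "e2"), c("d1", "d2", "d3")))
  st1 <- signal_table(new_cube(counts))
  for (m in c(2L, 5L)) {
    stm <- signal_table(new_cube(counts * m))
    expect_equal(stm$prr, st1$prr, tolerance = 1e-12)
    defined <- !is.na(st1$ci_low)
    expect_true(all((stm$ci_high - stm$ci_low)[defined] <=
                      (st1$ci_high - st1$ci_low)[defined] + 1e-12))
  }
})

test_that("log-scale identity and CI ordering hold for defined pairs", {
  cfg <- acei_arb_config(n_reports = 800, seed = 14)
  sim <- generate_reports(cfg)
  norm <- normalize_reports(sim$reports, default_drug_dictionary(),
                            default_event_vocabulary())
  st <- signal_table(build_cube(norm, cfg$drugs$name, pulmonary_events()))
  def <- !is.na(st$prr) & st$prr > 0 & !is.na(st$ci_low)
  expect_true(any(def))
  expect_equal(exp(log(st$prr[def])), st$prr[def], tolerance = 1e-12)
  expect_true(all(st$ci_low[def] < st$ci_high[def]))
  expect_true(all(st$ci_low[def] <= st$prr[def] & st$prr[def] <= st$ci_high[def]))
})

test_that("profile percentages sum to 100 and match a brute-force groupby", {
  counts <- matrix(c(5L, 15L, 10L, 20L, 0L, 50L), 2, 3,
                   dimnames = list(c("e1", "e2"), c("d1", "d2", "d3")))
  cube <- new_cube(counts)
  grouping <- c(d1 = "A", d2 = "A", d3 = "B")
  pp <- profile_percentages(cube, grouping)
  expect_equal(sum(pp$percentage), 100)
  expect_equal(pp$percentage[pp$event == "e1" & pp$group == "A"],
               100 * (5 + 10) / 100)
  # single group: event marginals
  pp1 <- profile_percentages(cube, c(d1 = "g", d2 = "g", d3 = "g"))
  expect_equal(sort(pp1$percentage), sort(unname(100 * rowSums(counts) / 100)))
  expect_error(profile_percentages(new_cube(counts * 0L), grouping), "empty cube")
  expect_error(profile_percentages(cube, c(d1 = "A")), "does not cover")
})

test_that("haldane continuity add-on gives defined CIs for zero cells", {
  counts <- matrix(c(0L, 20L, 24L, 176L), 2, 2,
                   dimnames = list(c("e1", "e2"), c("d1", "d2")))
  st <- signal_table(new_cube(counts), haldane = TRUE)
  expect_true(all(!is.na(st$prr)))
  expect_true(all(!is.na(st$ci_low)))
})
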