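# Synthetic spontaneous-report generator with known ground truth: drug
# usage marginals, event baselines, injected drug-event disproportionality
# (multiplier theta), optional covariate effects on exposure and event
# occurrence, and drug-name corruption with a rejection guard so that
# normalization accuracy has a clean ceiling.

.covariate_keys <- c("sex_m", "age_65plus", "weight_90plus")

.norm_weights <- function(w, what) {
  if (any(is.na(w)) || any(w < 0) || sum(w) <= 0) {
    stop(what, " weights must be non-negative and sum to a positive value")
  }
  w / sum(w)
}

#' Build and validate a simulation configuration
#'
#' @param n_reports Number of reports to generate.
#' @param drugs Data frame with columns `name`, `class`, `weight` (usage
#'   weights; normalized to sum to 1).
#' @param events Data frame with columns `name`, `weight` (baseline event
#'   weights; normalized).
#' @param signals Data frame with columns `drug`, `event`, `multiplier`
#'   (theta >= 0), or `NULL` for a null configuration.
#' @param lambda_events Events per report follow 1 + Poisson(lambda),
#'   truncated at the event-universe size. `1 + lambda_events` must not
#'   exceed the number of events.
#' @param covariates List with `age_mean`, `age_sd` (truncated to 18-100
#'   years), `weight_mean`, `weight_sd` (truncated to 40-200 kg),
#'   `prob_male`.
#' @param exposure_effects Data frame (`covariate`, `drug`, `log_odds`)
#'   tilting drug assignment; `covariate` is one of `"sex_m"`,
#'   `"age_65plus"`, `"weight_90plus"`. `NULL` for none.
#' @param event_effects Data frame (`covariate`, `event`, `log_odds`)
#'   tilting event occurrence the same way.
#' @param corruption List with `rate` (probability rho that a drug mention
#'   is rendered as an alias or corrupted string, split evenly) and
#'   `max_edits` (maximum random edit operations).
#' @param aliases Named list mapping each drug name to its alias strings
#'   (may be empty).
#' @param indications Data frame with columns `label`, `weight`.
#' @param multi_drug_lambda Mean number of additional drugs per report
#'   (default 0: one drug per report, which keeps the PRR ground truth
#'   analytically tractable).
#' @param seed Integer seed fixing the full output stream.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_reports,
                              drugs,
                              events,
                              signals = NULL,
                              lambda_events = 1.5,
                              covariates = list(age_mean = 60, age_sd = 15,
                                                weight_mean = 80, weight_sd = 18,
                                                prob_male = 0.5),
                              exposure_effects = NULL,
                              event_effects = NULL,
                              corruption = list(rate = 0.1, max_edits = 2),
                              aliases = NULL,
                              indications = tibble(label = "Hypertension",
                                                   weight = 1),
                              multi_drug_lambda = 0,
                              seed = 1L) {
  drugs <- as_tibble(drugs)
  events <- as_tibble(events)
  stopifnot(all(c("name", "class", "weight") %in% names(drugs)),
            all(c("name", "weight") %in% names(events)),
            n_reports >= 1, lambda_events >= 0, multi_drug_lambda >= 0)
  if (anyDuplicated(drugs$name) || anyDuplicated(events$name)) {
    stop("drug and event names must be unique")
  }
  drugs$weight <- .norm_weights(drugs$weight, "drug")
  events$weight <- .norm_weights(events$weight, "event")
  if (1 + lambda_events > nrow(events)) {
    stop("infeasible config: mean events per report (1 + lambda_events) ",
         "exceeds the event universe")
  }
  if (!is.null(signals)) {
    signals <- as_tibble(signals)
    stopifnot(all(c("drug", "event", "multiplier") %in% names(signals)))
    if (any(signals$multiplier < 0)) stop("signal multipliers must be >= 0")
    if (!all(signals$drug %in% drugs$name)) stop("signal drug not in universe")
    if (!all(signals$event %in% events$name)) stop("signal event not in universe")
  } else {
    signals <- tibble(drug = character(), event = character(),
                      multiplier = numeric())
  }
  stopifnot(corruption$rate >= 0, corruption$rate <= 1,
            corruption$max_edits >= 1)
  for (eff in list(exposure_effects, event_effects)) {
    if (!is.null(eff) && !all(eff$covariate %in% .covariate_keys)) {
      stop("effect covariate must be one of: ",
           paste(.covariate_keys, collapse = ", "))
    }
  }
  if (is.null(aliases)) {
    aliases <- setNames(vector("list", nrow(drugs)), drugs$name)
  }
  indications <- as_tibble(indications)
  indications$weight <- .norm_weights(indications$weight, "indication")
  structure(list(n_reports = as.integer(n_reports), drugs = drugs,
                 events = events, signals = signals,
                 lambda_events = lambda_events, covariates = covariates,
                 exposure_effects = exposure_effects,
                 event_effects = event_effects,
                 corruption = corruption, aliases = aliases,
                 indications = indications,
                 multi_drug_lambda = multi_drug_lambda,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# theta matrix (events x drugs), 1 everywhere except injected pairs
.theta_matrix <- function(config) {
  th <- matrix(1, nrow(config$events), nrow(config$drugs),
               dimnames = list(config$events$name, config$drugs$name))
  if (nrow(config$signals) > 0) {
    th[cbind(match(config$signals$event, config$events$name),
             match(config$signals$drug, config$drugs$name))] <-
      config$signals$multiplier
  }
  th
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

.indicator <- function(key, age, weight, sex) {
  switch(key,
         sex_m = sex == "M",
         age_65plus = age >= 65,
         weight_90plus = weight >= 90,
         stop("unknown covariate key: ", key))
}

# expected events per report, accounting for truncation at the universe size
.expected_m <- function(lambda, n_events) {
  k <- 0:max(50, ceiling(lambda + 12 * sqrt(lambda + 1)))
  sum(stats::dpois(k, lambda) * pmin(1 + k, n_events))
}

# one random edit (substitute/insert/delete a lowercase letter)
.random_edit <- function(s) {
  chars <- strsplit(s, "")[[1]]
  op <- sample(c("sub", "ins", "del"), 1)
  if (op == "del" && length(chars) <= 2) op <- "sub"
  if (op == "sub") {
    pos <- sample(length(chars), 1)
    chars[pos] <- sample(letters, 1)
  } else if (op == "ins") {
    pos <- sample(length(chars) + 1, 1)
    chars <- append(chars, sample(letters, 1), after = pos - 1)
  } else {
    pos <- sample(length(chars), 1)
    chars <- chars[-pos]
  }
  paste(chars, collapse = "")
}

.case_style <- function(x, style) {
  switch(style,
         upper = toupper(x),
         title = paste0(toupper(substring(x, 1, 1)), substring(x, 2)),
         x)
}

#' Generate a synthetic report set with ground truth
#'
#' Samples, for each report: demographics (truncated-normal age and weight,
#' Bernoulli sex), an indication label, a drug from the usage weights
#' (optionally tilted by covariate-exposure log-odds), an event count
#' `1 + Poisson(lambda)` truncated at the universe size, and that many
#' distinct events with probabilities proportional to baseline weight times
#' the pair's injected multiplier (optionally tilted by covariate-event
#' log-odds). Drug mentions are rendered verbatim as the canonical name, a
#' brand alias, or a corrupted string (probabilities `1 - rho`, `rho/2`,
#' `rho/2`); corrupted strings stay within `max_edits` edits of their
#' source, keep at least 5 characters after cleaning, and are rejected if
#' they land within `max_edits` edits of a different ingredient's alias.
#' The whole stream is deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#'
#' @return List with `reports` (a [report_set()]) and `truth` (list:
#'   `expected_counts` events x drugs matrix of baseline expectations
#'   `n w_j E[m] p(i|j)`, exact when covariate effects are absent;
#'   `signals`; `mention_map` tibble mapping every rendered mention to its
#'   true ingredient; `seed`).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_reports
  D <- nrow(config$drugs)
  E <- nrow(config$events)

  age <- .rtruncnorm(n, config$covariates$age_mean, config$covariates$age_sd,
                     18, 100)
  weight <- .rtruncnorm(n, config$covariates$weight_mean,
                        config$covariates$weight_sd, 40, 200)
  sex <- ifelse(runif(n) < config$covariates$prob_male, "M", "F")
  indication <- config$indications$label[
    sample.int(nrow(config$indications), n, replace = TRUE,
               prob = config$indications$weight)]
  quarter <- paste0(sample(2004:2019, n, replace = TRUE), "Q",
                    sample.int(4, n, replace = TRUE))

  # drug assignment, optionally tilted by covariate -> exposure effects
  if (is.null(config$exposure_effects) || nrow(config$exposure_effects) == 0) {
    drug_idx <- sample.int(D, n, replace = TRUE, prob = config$drugs$weight)
  } else {
    tilt <- matrix(0, n, D)
    for (k in seq_len(nrow(config$exposure_effects))) {
      eff <- config$exposure_effects[k, ]
      ind <- .indicator(eff$covariate, age, weight, sex)
      tilt[ind, match(eff$drug, config$drugs$name)] <-
        tilt[ind, match(eff$drug, config$drugs$name)] + eff$log_odds
    }
    drug_idx <- integer(n)
    pattern <- apply(tilt, 1, paste, collapse = ",")
    for (pat in unique(pattern)) {
      rows <- which(pattern == pat)
      w <- config$drugs$weight * exp(tilt[rows[1], ])
      drug_idx[rows] <- sample.int(D, length(rows), replace = TRUE,
                                   prob = w / sum(w))
    }
  }
  drug_lists <- as.list(drug_idx)
  if (config$multi_drug_lambda > 0) {
    extra <- pmin(rpois(n, config$multi_drug_lambda), D - 1)
    for (r in which(extra > 0)) {
      pool <- setdiff(seq_len(D), drug_idx[r])
      w <- config$drugs$weight[pool]
      drug_lists[[r]] <- c(drug_idx[r],
                           sample(pool, extra[r], prob = w / sum(w)))
    }
  }

  # events: 1 + Poisson(lambda) distinct events, weights p_i * theta_ij,
  # tilted by covariate -> event effects
  theta <- .theta_matrix(config)
  m <- pmin(1 + rpois(n, config$lambda_events), E)
  ev_tilt_keys <- if (is.null(config$event_effects)) character() else
    unique(config$event_effects$covariate)
  ind_mat <- vapply(ev_tilt_keys,
                    function(k) .indicator(k, age, weight, sex), logical(n))
  if (length(ev_tilt_keys) > 0 && n == 1) ind_mat <- matrix(ind_mat, 1)
  event_lists <- vector("list", n)
  # group reports sharing (primary drug, event-tilt pattern): same weights
  grp_key <- paste(drug_idx,
                   if (length(ev_tilt_keys) > 0)
                     apply(ind_mat, 1, paste, collapse = ",") else "")
  for (key in unique(grp_key)) {
    rows <- which(grp_key == key)
    j <- drug_idx[rows[1]]
    w <- config$events$weight * theta[, j]
    if (length(ev_tilt_keys) > 0) {
      for (k in seq_len(nrow(config$event_effects))) {
        eff <- config$event_effects[k, ]
        if (ind_mat[rows[1], eff$covariate]) {
          ei <- match(eff$event, config$events$name)
          w[ei] <- w[ei] * exp(eff$log_odds)
        }
      }
    }
    if (sum(w) <= 0) stop("event weights vanished for drug ",
                          config$drugs$name[j])
    for (r in rows) {
      event_lists[[r]] <- sample.int(E, m[r], replace = FALSE, prob = w)
    }
  }

  # render drug mentions: canonical / alias / corrupted
  rendered <- render_mentions(config, drug_lists)

  report_ids <- sprintf("R%07d", seq_len(n))
  reactions <- lapply(event_lists, function(ei) {
    vapply(config$events$name[ei], function(s) {
      .case_style(s, sample(c("lower", "upper", "title"), 1))
    }, character(1), USE.NAMES = FALSE)
  })
  reports <- report_set(
    tibble(report_id = report_ids, quarter = quarter, age = age,
           weight = weight, sex = sex, indication = indication,
           drug_mentions = rendered$mentions, reactions = reactions),
    provenance = tibble(source = "synthetic", records = n)
  )

  p_cond <- sweep(config$events$weight * theta, 2,
                  colSums(config$events$weight * theta), "/")
  e_m <- .expected_m(config$lambda_events, E)
  expected <- p_cond * matrix(rep(n * config$drugs$weight * e_m, each = E),
                              E, D)
  dimnames(expected) <- list(config$events$name, config$drugs$name)

  mention_map <- rendered$map
  mention_map$report_id <- rep(report_ids, lengths(drug_lists))
  truth <- list(expected_counts = expected, signals = config$signals,
                mention_map = mention_map[c("report_id", "mention",
                                            "ingredient", "render", "n_edits")],
                expected_events_per_report = e_m, seed = config$seed)
  list(reports = reports, truth = truth)
}

# Render every drug mention, with rejection-guarded corruption. Returns the
# per-report mention lists plus a flat map of mention -> true ingredient.
render_mentions <- function(config, drug_lists) {
  D <- nrow(config$drugs)
  canon <- config$drugs$name
  alias_of <- lapply(canon, function(d) {
    a <- config$aliases[[d]]
    if (is.null(a)) character() else tolower(a)
  })
  # alias pool of *other* ingredients, for the rejection guard
  all_aliases <- unlist(lapply(seq_len(D), function(j) {
    setNames(c(tolower(canon[j]), alias_of[[j]]),
             rep(canon[j], 1 + length(alias_of[[j]])))
  }))
  rho <- config$corruption$rate
  max_edits <- config$corruption$max_edits

  flat_idx <- unlist(drug_lists, use.names = FALSE)
  n_m <- length(flat_idx)
  u <- runif(n_m)
  render <- ifelse(u < 1 - rho, "canonical",
                   ifelse(u < 1 - rho / 2, "alias", "corrupted"))
  # no alias table -> render canonical instead
  has_alias <- lengths(alias_of)[flat_idx] > 0
  render[render == "alias" & !has_alias] <- "canonical"

  mention <- character(n_m)
  n_edits <- integer(n_m)
  styles <- sample(c("lower", "upper", "title"), n_m, replace = TRUE)
  for (k in seq_len(n_m)) {
    j <- flat_idx[k]
    if (render[k] == "canonical") {
      mention[k] <- .case_style(canon[j], styles[k])
    } else if (render[k] == "alias") {
      a <- sample(alias_of[[j]], 1)
      mention[k] <- .case_style(a, styles[k])
    } else {
      src_pool <- c(tolower(canon[j]), alias_of[[j]])
      other <- all_aliases[names(all_aliases) != canon[j]]
      ok <- FALSE
      for (try in 1:50) {
        s <- sample(src_pool, 1)
        ed <- sample.int(max_edits, 1)
        cand <- s
        for (e in seq_len(ed)) cand <- .random_edit(cand)
        cand_clean <- clean_name(cand)
        if (nchar(cand_clean) < 5) next
        if (length(other) > 0 &&
            min(adist(cand_clean, other, costs = 1)) <= max_edits) next
        mention[k] <- cand
        n_edits[k] <- ed
        ok <- TRUE
        break
      }
      if (!ok) {
        mention[k] <- .case_style(canon[j], styles[k])
        render[k] <- "canonical"
      }
    }
  }
  map <- tibble(mention = mention, ingredient = canon[flat_idx],
                render = render, n_edits = n_edits)
  mentions <- split(mention, rep(seq_along(drug_lists), lengths(drug_lists)))
  list(mentions = unname(mentions), map = map)
}

#' Asymptotic PRR implied by a configuration
#'
#' With all other drugs at baseline, the large-sample PRR of pair (i, j)
#' approaches `theta_ij / sum_k p_k theta_kj`: the drug's boosted
#' conditional share of event i over the comparator share `p_i`. For a
#' single injected pair this reduces to `theta / (1 + p_i (theta - 1))`.
#' (First-order in the events-per-report mean; sampling events without
#' replacement shrinks large shares slightly.)
#'
#' @param config A [simulation_config()].
#' @param drug,event The pair of interest.
#' @return The asymptotic PRR.
#' @export
prr_asymptote <- function(config, drug, event) {
  theta <- .theta_matrix(config)[, drug]
  theta[[event]] / sum(config$events$weight * theta)
}

#' Configuration shaped like the published ACEI/ARB analysis
#'
#' Sixteen antihypertensives (ten ACE inhibitors, six ARBs) with plausible
#' US usage weights, the thirteen pulmonary adverse events with realistic
#' relative frequencies, and two injected signal drugs emulating the
#' quinapril/trandolapril pattern: quinapril at multiplier 5 on pleural
#' effusion, pulmonary edema and sinusitis, and trandolapril at multiplier 3
#' on a disjoint pair, dysphonia and pneumonia aspiration. The boosted
#' subsets are
#' kept to a modest share of the baseline event mass on purpose: a
#' multiplier applied to events carrying most of the mass renormalizes
#' away, because the PRR compares event shares within a drug (see the
#' vignette). Defaults to 5,000 reports, 10% alias/corruption rendering,
#' brand aliases from [default_drug_dictionary()].
#'
#' @param n_reports Number of reports (default 5000).
#' @param seed Seed (default 1).
#' @param signal_multipliers Named vector of per-drug multipliers (default
#'   `c(quinapril = 5, trandolapril = 3)`); use an empty vector for a null
#'   configuration with no injected signals.
#' @param corruption_rate Probability a mention is rendered as alias or
#'   corrupted (default 0.1).
#'
#' @return A [simulation_config()].
#' @export
acei_arb_config <- function(n_reports = 5000, seed = 1L,
                              signal_multipliers = c(quinapril = 5,
                                                     trandolapril = 3),
                              corruption_rate = 0.1) {
  drugs <- tibble(
    name = c("lisinopril", "enalapril", "ramipril", "benazepril", "captopril",
             "quinapril", "perindopril", "fosinopril", "trandolapril",
             "cilazapril",
             "losartan", "valsartan", "irbesartan", "olmesartan",
             "telmisartan", "azilsartan"),
    class = c(rep("ACEI", 10), rep("ARB", 6)),
    weight = c(0.27, 0.07, 0.06, 0.05, 0.03, 0.045, 0.02, 0.02, 0.035, 0.015,
               0.16, 0.09, 0.04, 0.05, 0.03, 0.015)
  )
  events <- tibble(
    name = c("dyspnea", "cough", "pneumonia", "nasopharyngitis", "sinusitis",
             "pleural effusion", "bronchitis", "oropharyngeal pain",
             "dysphonia", "pulmonary edema", "pneumonia aspiration",
             "emphysema", "pleurisy"),
    weight = c(0.28, 0.22, 0.09, 0.05, 0.04, 0.05, 0.05, 0.05, 0.04, 0.05,
               0.02, 0.02, 0.04)
  )
  signal_events <- list(
    quinapril = c("pleural effusion", "pulmonary edema", "sinusitis"),
    trandolapril = c("dysphonia", "pneumonia aspiration")
  )
  signals <- if (length(signal_multipliers) > 0) {
    dplyr::bind_rows(lapply(names(signal_multipliers), function(d) {
      ev <- signal_events[[d]]
      if (is.null(ev)) ev <- setdiff(events$name, c("emphysema", "pleurisy"))
      tibble(drug = d, event = ev,
             multiplier = unname(signal_multipliers[d]))
    }))
  } else NULL

  dict <- default_drug_dictionary()
  aliases <- lapply(drugs$name, function(d) {
    setdiff(dict$alias[dict$ingredient == d], d)
  })
  names(aliases) <- drugs$name

  simulation_config(
    n_reports = n_reports, drugs = drugs, events = events, signals = signals,
    lambda_events = 0.5,
    corruption = list(rate = corruption_rate, max_edits = 2),
    aliases = aliases, seed = seed
  )
}

#' Write a simulation to disk
#'
#' Emits the FAERS-style `$`-delimited trio, the flat CSV, the ground truth
#' as a JSON sidecar, and the configuration as JSON.
#'
#' @param sim Result of [generate_reports()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named vector of paths written.
#' @export
write_simulation <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- write_faers_quarter(sim$reports, out_dir)
  flat <- file.path(out_dir, "reports_flat.csv")
  write_flat_csv(sim$reports, flat)
  truth_path <- file.path(out_dir, "truth.json")
  truth <- sim$truth
  truth$expected_counts <- dplyr::bind_cols(
    tibble(event = rownames(truth$expected_counts)),
    as_tibble(truth$expected_counts))
  jsonlite::write_json(truth, truth_path, dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
  invisible(c(paths, flat = flat, truth = truth_path))
}
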