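# End-to-end orchestration: ingest -> normalize -> filter -> cube -> signal
# table -> covariate checks -> Friedman comparisons -> PCA, with fixed-order
# CSV artifacts and a machine-readable run log. The pipeline is a pure
# function of (input files, config, seed).

#' Build and validate a pipeline run configuration
#'
#' Either `simulate = TRUE` with a [simulation_config()] in `sim_config`,
#' or input paths: a flat CSV (`flat_csv`) or the FAERS-style trio
#' (`demo`, `drug`, `reac`).
#'
#' @param out_dir Output directory for artifacts.
#' @param simulate Generate the input with [generate_reports()]?
#' @param sim_config A [simulation_config()] (required when `simulate`).
#' @param flat_csv,demo,drug,reac Input paths (when not simulating).
#' @param dict A [drug_dictionary()]; default bundled ACEI/ARB dictionary.
#' @param vocab An [event_vocabulary()]; default bundled vocabulary.
#' @param max_dist Fuzzy-matching threshold for drug names.
#' @param indication_include,indication_exclude,event_whitelist,class_whitelist,keep_missing_indication
#'   Cohort filter settings (see [filter_cohort()]).
#' @param ci_variant `"as_printed"` or `"delta_standard"`.
#' @param ce_threshold Change-in-estimate threshold for covariate checks.
#' @param max_covariate_pairs At most this many flagged pairs get a
#'   covariate check (in signal-table order; default 20).
#' @param alpha Significance threshold reported in the log (default 0.05).
#' @param seed Seed for the run.
#'
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = FALSE, sim_config = NULL,
                            flat_csv = NULL, demo = NULL, drug = NULL,
                            reac = NULL,
                            dict = default_drug_dictionary(),
                            vocab = default_event_vocabulary(),
                            max_dist = 2,
                            indication_include = "hypertension",
                            indication_exclude = c("pulmonary\\s+arterial\\s+hypertension",
                                                   "intracranial\\s+hypertension"),
                            event_whitelist = pulmonary_events(),
                            class_whitelist = NULL,
                            keep_missing_indication = FALSE,
                            ci_variant = "as_printed",
                            ce_threshold = 0.10,
                            max_covariate_pairs = 20,
                            alpha = 0.05,
                            seed = 1L) {
  if (simulate) {
    if (is.null(sim_config)) stop("simulate = TRUE needs a sim_config")
  } else if (is.null(flat_csv) && (is.null(demo) || is.null(drug) || is.null(reac))) {
    stop("provide either flat_csv or the demo/drug/reac trio, or simulate")
  }
  stopifnot(ci_variant %in% c("as_printed", "delta_standard"),
            max_dist >= 0, ce_threshold > 0, alpha > 0, alpha < 1)
  structure(list(out_dir = out_dir, simulate = simulate,
                 sim_config = sim_config, flat_csv = flat_csv,
                 demo = demo, drug = drug, reac = reac,
                 dict = dict, vocab = vocab, max_dist = max_dist,
                 indication_include = indication_include,
                 indication_exclude = indication_exclude,
                 event_whitelist = event_whitelist,
                 class_whitelist = class_whitelist,
                 keep_missing_indication = keep_missing_indication,
                 ci_variant = ci_variant, ce_threshold = ce_threshold,
                 max_covariate_pairs = max_covariate_pairs,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — ingest, normalize, filter, cube, signal
#' table, covariate checks, Friedman comparisons, PCA — writing one CSV
#' artifact per stage plus a JSON run log with per-stage row counts and
#' warning counts. A failing stage halts the run with a stage-named error
#' and leaves a `FAILED` marker in the output directory. Re-running with
#' the same config and seed reproduces every artifact byte-identically.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the output directory, the artifact paths,
#'   and the in-memory stage results (`signal_table`, `comparisons`,
#'   `covariate_checks`, `pca`, `cube`, `log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  log <- list(seed = config$seed, stages = list())
  n_warn <- 0
  note <- function(stage, ...) {
    log$stages[[stage]] <<- list(...)
  }
  on.exit({
    if (!file.exists(file.path(out_dir, "run_log.json"))) {
      writeLines("pipeline failed before completion", failed_marker)
    }
  })
  set.seed(config$seed)
  withCallingHandlers({
    # -- ingest ------------------------------------------------------------
    reports <- .stage("ingest", log, {
      if (config$simulate) {
        sim <- generate_reports(config$sim_config)
        sim$reports
      } else if (!is.null(config$flat_csv)) {
        read_flat_csv(config$flat_csv)
      } else {
        read_faers_quarter(config$demo, config$drug, config$reac)
      }
    })
    flat <- flat_triples(reports)
    p1 <- file.path(out_dir, "01_reports_flat.csv")
    readr::write_csv(flat, p1, progress = FALSE)
    note("ingest", reports = nrow(reports), triples = nrow(flat))

    # -- normalize ---------------------------------------------------------
    normalized <- .stage("normalize", log,
                         normalize_reports(reports, config$dict, config$vocab,
                                           max_dist = config$max_dist))
    unmapped_drugs <- sum(lengths(normalized$unmapped_drugs))
    unmapped_events <- sum(lengths(normalized$unmapped_events))
    p2 <- file.path(out_dir, "02_normalized_triples.csv")
    norm_triples <- .normalized_triples(normalized)
    readr::write_csv(norm_triples, p2, progress = FALSE)
    note("normalize", reports = nrow(normalized),
         unmapped_drug_mentions = unmapped_drugs,
         unmapped_event_mentions = unmapped_events)

    # -- filter ------------------------------------------------------------
    cohort <- .stage("filter", log, suppressWarnings(
      filter_cohort(normalized,
                    indication_include = config$indication_include,
                    indication_exclude = config$indication_exclude,
                    event_whitelist = config$event_whitelist,
                    class_whitelist = config$class_whitelist,
                    dict = config$dict,
                    keep_missing_indication = config$keep_missing_indication)))
    note("filter", reports_in = nrow(normalized), reports_kept = nrow(cohort))

    # -- cube --------------------------------------------------------------
    cls <- unique(as_tibble(config$dict)[c("ingredient", "class")])
    drug_universe <- if (is.null(config$class_whitelist)) cls$ingredient else
      cls$ingredient[cls$class %in% config$class_whitelist]
    cube <- .stage("cube", log,
                   build_cube(cohort, drug_universe, config$event_whitelist))
    p3 <- file.path(out_dir, "03_cube.csv")
    readr::write_csv(as_tibble(cube$counts, rownames = "event"), p3,
                     progress = FALSE)
    note("cube", triples = cube$N, drugs = length(cube$drugs),
         events = length(cube$events))

    # -- signal table ------------------------------------------------------
    sig <- .stage("signal", log,
                  signal_table(cube, ci_variant = config$ci_variant))
    p4 <- file.path(out_dir, "04_signal_table.csv")
    write_signal_table(sig, p4)
    note("signal", pairs = nrow(sig), flagged = sum(sig$flagged),
         undefined_prr = sum(is.na(sig$prr)))

    # -- covariate checks --------------------------------------------------
    flagged_pairs <- head(sig[sig$flagged, c("drug", "event")],
                          config$max_covariate_pairs)
    checks <- .stage("adjust", log,
                     check_all(cohort, flagged_pairs,
                               threshold = config$ce_threshold))
    p5 <- file.path(out_dir, "05_covariate_checks.csv")
    readr::write_csv(checks, p5, progress = FALSE)
    note("adjust", pairs_checked = nrow(checks),
         negligible = sum(checks$negligible %in% TRUE))

    # -- Friedman comparisons ----------------------------------------------
    comparisons <- .stage("compare", log, suppressWarnings(
      run_group_comparisons(cube,
                            class_of = setNames(cls$class, cls$ingredient))))
    p6 <- file.path(out_dir, "06_friedman_comparisons.csv")
    readr::write_csv(comparisons, p6, progress = FALSE)
    note("compare", comparisons = nrow(comparisons),
         significant = sum(comparisons$p_value < config$alpha))

    # -- PCA ---------------------------------------------------------------
    pca <- .stage("pca", log, {
      m <- .prr_matrix_for_pca(sig, cube)
      pca_prr(m)
    })
    p7 <- file.path(out_dir, "07_pca.csv")
    readr::write_csv(.pca_long(pca), p7, progress = FALSE)
    note("pca", components = length(pca$sdev),
         variance_pc1 = pca$variance_explained[1],
         variance_pc2 = if (length(pca$sdev) > 1) pca$variance_explained[2]
                        else NA_real_)
  }, warning = function(w) {
    n_warn <<- n_warn + 1
    invokeRestart("muffleWarning")
  })

  log$warnings <- n_warn
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  artifacts <- file.path(out_dir, c("01_reports_flat.csv",
                                    "02_normalized_triples.csv",
                                    "03_cube.csv", "04_signal_table.csv",
                                    "05_covariate_checks.csv",
                                    "06_friedman_comparisons.csv",
                                    "07_pca.csv"))
  invisible(list(out_dir = out_dir, artifacts = artifacts, log = log,
                 cube = cube, signal_table = sig, covariate_checks = checks,
                 comparisons = comparisons, pca = pca))
}

# normalized reports as one row per (report, drug, event) pair
.normalized_triples <- function(normalized) {
  rows <- lapply(seq_len(nrow(normalized)), function(k) {
    d <- normalized$drugs[[k]]
    e <- normalized$events[[k]]
    if (length(d) == 0 || length(e) == 0) return(NULL)
    grid <- expand.grid(drug = d, event = e, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    tibble(report_id = normalized$report_id[k], drug = grid$drug,
           event = grid$event)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) tibble(report_id = character(), drug = character(),
                             event = character()) else out
}

# drugs x events PRR matrix for PCA; undefined PRRs imputed as 0
.prr_matrix_for_pca <- function(sig, cube) {
  m <- matrix(sig$prr, nrow = length(cube$events),
              dimnames = list(cube$events, cube$drugs))
  m[is.na(m)] <- 0
  t(m)
}

.pca_long <- function(pca) {
  comp <- paste0("PC", seq_along(pca$sdev))
  scores <- as_tibble(pca$scores, rownames = "name")
  names(scores)[-1] <- comp
  scores$part <- "score"
  loadings <- as_tibble(pca$loadings, rownames = "name")
  names(loadings)[-1] <- comp
  loadings$part <- "loading"
  ve_wide <- as_tibble(matrix(pca$variance_explained, 1,
                              dimnames = list(NULL, comp)))
  ve <- dplyr::bind_cols(tibble(name = "(all)", part = "variance_explained"),
                         ve_wide)
  out <- dplyr::bind_rows(scores, loadings, ve)
  out[c("part", "name", comp)]
}
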