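# Drug x event contingency cube and PRR disproportionality statistics.
#
# The counting unit is the distinct (report, drug, event) triple: r_ij is the
# number of reports mentioning drug j and event i, n_j = sum_i r_ij is drug
# j's total event mentions, and N = sum_j n_j. The comparator for pair (i, j)
# is the event-i share among all remaining drugs of the analysis universe:
#
#   PRR_ij = (r_ij / n_j) / ((T_i - r_ij) / (N - n_j)),  T_i = sum_j r_ij.

#' Build the drug x event contingency cube
#'
#' Counts distinct (report, drug, event) triples over fixed drug and event
#' universes. A report mentioning one drug and two whitelisted events
#' contributes one count to each of the two cells of that drug's column; a
#' report with two drugs contributes to both columns. Duplicate mentions
#' within a report count once.
#'
#' @param reports A `normalized_reports` tibble (see [normalize_reports()]).
#' @param drug_universe Ordered character vector of canonical ingredients
#'   (the cube's columns).
#' @param event_universe Ordered character vector of preferred terms (rows).
#'
#' @return A `contingency_cube`: list with `counts` (events x drugs integer
#'   matrix), `drugs`, `events`, `n_j` (per-drug totals) and `N`.
#' @export
build_cube <- function(reports, drug_universe, event_universe) {
  stopifnot(length(drug_universe) > 0, length(event_universe) > 0)
  if (anyDuplicated(drug_universe) || anyDuplicated(event_universe)) {
    stop("drug and event universes must not contain duplicates")
  }
  pairs <- lapply(seq_len(nrow(reports)), function(k) {
    d <- intersect(unique(reports$drugs[[k]]), drug_universe)
    e <- intersect(unique(reports$events[[k]]), event_universe)
    if (length(d) == 0 || length(e) == 0) return(NULL)
    expand.grid(drug = d, event = e, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)
  })
  pairs <- dplyr::bind_rows(pairs)
  counts <- if (nrow(pairs) == 0) {
    matrix(0L, length(event_universe), length(drug_universe))
  } else {
    unclass(table(factor(pairs$event, levels = event_universe),
                  factor(pairs$drug, levels = drug_universe)))
  }
  counts <- matrix(as.integer(counts), length(event_universe),
                   length(drug_universe),
                   dimnames = list(event_universe, drug_universe))
  new_cube(counts)
}

#' Construct a contingency cube from a count matrix
#'
#' @param counts Events x drugs matrix of non-negative integer counts with
#'   dimnames.
#' @return A `contingency_cube` with margins recomputed from `counts`.
#' @export
new_cube <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            !is.null(rownames(counts)), !is.null(colnames(counts)))
  structure(list(counts = counts,
                 events = rownames(counts),
                 drugs = colnames(counts),
                 n_j = colSums(counts),
                 N = sum(counts)),
            class = "contingency_cube")
}

#' @export
print.contingency_cube <- function(x, ...) {
  cat("<contingency_cube> ", length(x$events), " events x ",
      length(x$drugs), " drugs, N = ", x$N, "\n", sep = "")
  invisible(x)
}

# Vectorized core: PRR, SD on the log scale, and the 95% CI, for parallel
# vectors of cell count r, drug margin n_j, event total t_i and grand total
# N. Undefined PRRs (empty drug column or empty comparator) are NA; r = 0
# with a populated column gives PRR = 0 with an undefined CI.
.prr_core <- function(r, n_j, t_i, N, ci_variant = c("as_printed", "delta_standard"),
                      haldane = FALSE) {
  ci_variant <- match.arg(ci_variant)
  len <- max(length(r), length(n_j), length(t_i), length(N))
  r <- rep_len(as.numeric(r), len)
  n_j <- rep_len(as.numeric(n_j), len)
  t_i <- rep_len(as.numeric(t_i), len)
  N <- rep_len(as.numeric(N), len)
  if (haldane) {
    r <- r + 0.5
    n_j <- n_j + 1
    t_i <- t_i + 1
    N <- N + 2
  }
  c_ev <- t_i - r         # comparator event count
  c_tot <- N - n_j        # comparator total
  prr <- rep(NA_real_, length(r))
  def <- n_j > 0 & c_ev > 0 & c_tot > 0
  prr[def] <- (r[def] / n_j[def]) / (c_ev[def] / c_tot[def])

  sd_log <- rep(NA_real_, length(r))
  ok <- def & r > 0
  if (ci_variant == "as_printed") {
    # sqrt((n_j - r)/(n_j r) + (N - n_j)/(n_j N))
    sd_log[ok] <- sqrt((n_j[ok] - r[ok]) / (n_j[ok] * r[ok]) +
                         (N[ok] - n_j[ok]) / (n_j[ok] * N[ok]))
  } else {
    # textbook delta-method SE of log PRR on the 2x2 table
    sd_log[ok] <- sqrt(1 / r[ok] - 1 / n_j[ok] + 1 / c_ev[ok] - 1 / c_tot[ok])
  }
  ci_low <- exp(log(prr) - 1.96 * sd_log)
  ci_high <- exp(log(prr) + 1.96 * sd_log)
  ci_low[!ok] <- NA_real_
  ci_high[!ok] <- NA_real_
  tibble(r = r, n_j = n_j, comparator_event_count = c_ev,
         comparator_total = c_tot, prr = prr, sd_log = sd_log,
         ci_low = ci_low, ci_high = ci_high)
}

#' PRR statistics from raw counts
#'
#' Vectorized PRR, log-scale SD and 95% CI straight from the four counts of
#' the 2x2 table implied by (`r_ij`, `n_j`, `event_total`, `N`): the cell,
#' the drug margin, the event total over all drugs, and the grand total.
#' This is the computational core behind [prr()] and [signal_table()].
#'
#' @param r_ij,n_j,event_total,N Count vectors (recycled to a common
#'   length).
#' @param ci_variant `"as_printed"` or `"delta_standard"` (see [prr()]).
#' @param haldane Apply a 0.5 continuity add-on (default off).
#' @return Tibble with `r`, `n_j`, `comparator_event_count`,
#'   `comparator_total`, `prr`, `sd_log`, `ci_low`, `ci_high`.
#' @export
prr_from_counts <- function(r_ij, n_j, event_total, N,
                            ci_variant = c("as_printed", "delta_standard"),
                            haldane = FALSE) {
  .prr_core(r_ij, n_j, event_total, N, ci_variant = ci_variant,
            haldane = haldane)
}

#' PRR for one drug-event pair
#'
#' @param cube A `contingency_cube`.
#' @param i Event index or preferred-term name.
#' @param j Drug index or ingredient name.
#' @param ci_variant `"as_printed"` uses the published SD formula
#'   `sqrt((n_j - r)/(n_j r) + (N - n_j)/(n_j N))`; `"delta_standard"` uses
#'   the textbook delta-method standard error of log PRR. See the package
#'   vignette for the difference.
#' @param haldane Apply a 0.5 continuity add-on to all cells (default off).
#'
#' @return One-row tibble with `drug`, `event`, `r`, `n_j`, comparator
#'   counts, `prr`, `sd_log`, `ci_low`, `ci_high`.
#' @export
prr <- function(cube, i, j, ci_variant = c("as_printed", "delta_standard"),
                haldane = FALSE) {
  if (is.character(i)) i <- match(i, cube$events)
  if (is.character(j)) j <- match(j, cube$drugs)
  if (is.na(i) || is.na(j) || i < 1 || i > length(cube$events) ||
      j < 1 || j > length(cube$drugs)) {
    stop("event or drug index out of range")
  }
  core <- .prr_core(cube$counts[i, j], cube$n_j[[j]],
                    sum(cube$counts[i, ]), cube$N,
                    ci_variant = ci_variant, haldane = haldane)
  tibble(drug = cube$drugs[j], event = cube$events[i], core)
}

#' Log-scale SD and 95% confidence interval for a PRR
#'
#' Computes `exp(ln(PRR) +/- 1.96 * SD)` from the four counts of the
#' implied 2x2 table. With `variant = "as_printed"` the SD is
#' `sqrt((n_j - r)/(n_j r) + (N - n_j)/(n_j N))`; with
#' `"delta_standard"` it is `sqrt(1/r - 1/n_j + 1/c - 1/(N - n_j))` where
#' `c = event_total - r` is the comparator event count.
#'
#' @param r_ij Cell count (>= 1 for a defined interval; `r_ij = 0` returns
#'   `NA`s, not an error).
#' @param n_j Drug margin.
#' @param event_total Event-i total over all drugs.
#' @param N Grand total.
#' @param variant `"as_printed"` or `"delta_standard"`.
#'
#' @return Tibble with `sd_log`, `ci_low`, `ci_high`.
#' @export
compute_ci <- function(r_ij, n_j, event_total, N,
                       variant = c("as_printed", "delta_standard")) {
  core <- .prr_core(r_ij, n_j, event_total, N, ci_variant = variant)
  core[c("sd_log", "ci_low", "ci_high")]
}

#' Apply the three signal criteria
#'
#' Criterion 1: more than 3 occurrences (`r > 3`). Criterion 2: `PRR > 2`.
#' Criterion 3: lower 95% CI bound `> 1`. `criteria_code` is the number of
#' criteria met (0-3) and a pair is `flagged` iff all three hold. An
#' undefined PRR fails criteria 2 and 3.
#'
#' @param result Tibble with columns `r`, `prr`, `ci_low` (e.g. from
#'   [prr()] or [signal_table()]).
#' @return `result` with `criteria_code` and `flagged` columns added.
#' @export
apply_criteria <- function(result) {
  c1 <- result$r > 3
  c2 <- !is.na(result$prr) & result$prr > 2
  c3 <- !is.na(result$ci_low) & result$ci_low > 1
  result$criteria_code <- as.integer(c1) + as.integer(c2) + as.integer(c3)
  result$flagged <- c1 & c2 & c3
  result
}

#' Full signal table for a cube
#'
#' One row per (drug, event) pair of the universes, in universe order
#' (drug-major), with PRR, log-scale SD, 95% CI and the three-criterion
#' code. Deterministic.
#'
#' @inheritParams prr
#' @return Tibble with one row per pair and columns `drug`, `event`, `r`,
#'   `n_j`, `comparator_event_count`, `comparator_total`, `prr`, `sd_log`,
#'   `ci_low`, `ci_high`, `criteria_code`, `flagged`.
#' @export
signal_table <- function(cube, ci_variant = c("as_printed", "delta_standard"),
                         haldane = FALSE) {
  E <- length(cube$events)
  D <- length(cube$drugs)
  j <- rep(seq_len(D), each = E)
  i <- rep(seq_len(E), times = D)
  t_i <- rowSums(cube$counts)
  core <- .prr_core(cube$counts[cbind(i, j)], cube$n_j[j], t_i[i], cube$N,
                    ci_variant = ci_variant, haldane = haldane)
  apply_criteria(tibble(drug = cube$drugs[j], event = cube$events[i], core))
}

#' Write a signal table as CSV
#'
#' Fixed column order (drug, event, r, n_j, prr, sd_log, ci_low, ci_high,
#' criteria_code, flagged); numbers rounded to 6 significant digits.
#'
#' @param x A [signal_table()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signal_table <- function(x, path) {
  out <- x[c("drug", "event", "r", "n_j", "prr", "sd_log",
             "ci_low", "ci_high", "criteria_code", "flagged")]
  for (col in c("prr", "sd_log", "ci_low", "ci_high")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Event profile percentages by drug group
#'
#' For each (event, group) cell: 100 x (the group's count of that event)
#' divided by the total event count over all analyzed drugs, so all cells
#' sum to 100.
#'
#' @param cube A `contingency_cube` with at least one count.
#' @param grouping Named character vector mapping every drug of the cube to
#'   a group label.
#' @return Tibble with columns `event`, `group`, `count`, `percentage`.
#' @export
profile_percentages <- function(cube, grouping) {
  missing_drugs <- setdiff(cube$drugs, names(grouping))
  if (length(missing_drugs) > 0) {
    stop("grouping does not cover drug(s): ",
         paste(missing_drugs, collapse = ", "))
  }
  if (cube$N == 0) stop("empty cube")
  g <- factor(grouping[cube$drugs])
  agg <- t(rowsum(t(cube$counts), g))   # events x groups
  out <- tidyr::pivot_longer(
    as_tibble(agg, rownames = "event"),
    -"event", names_to = "group", values_to = "count"
  )
  out$percentage <- 100 * out$count / cube$N
  out
}
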