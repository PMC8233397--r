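# Covariate-robustness check: is Pr(event | drug, age, weight, sex) close
# enough to Pr(event | drug) that the unadjusted PRR can be trusted?
#
# Crude model:    event ~ exposure
# Adjusted model: event ~ exposure + age_group + weight_group + sex
# The drug coefficient is compared by the conventional change-in-estimate
# rule: negligible confounding when |adjusted - crude| / max(|crude|, eps)
# falls below the threshold (default 10%).

# Coarse clinical bins keep every cell populated at simulation scale.
.age_bins <- c(0, 18, 45, 65, 130)
.weight_bins <- c(0, 60, 90, 700)

.bin_covariates <- function(age, weight) {
  list(
    age_group = cut(age, breaks = .age_bins, right = FALSE,
                    include.lowest = TRUE),
    weight_group = cut(weight, breaks = .weight_bins, right = FALSE,
                       include.lowest = TRUE)
  )
}

.non_estimable <- function(drug, event, reason, n_used = NA_integer_) {
  tibble(drug = drug, event = event,
         crude_log_odds = NA_real_, adjusted_log_odds = NA_real_,
         relative_change = NA_real_, negligible = NA,
         n_used = n_used, status = reason)
}

#' Change-in-estimate confounding check for one drug-event pair
#'
#' Fits crude and covariate-adjusted logistic regressions of event presence
#' on drug exposure over the reports with complete age, weight and sex, and
#' compares the exposure coefficients. Reports with missing covariates are
#' excluded from this check only (complete-case), never from the PRR
#' pipeline. Separation or non-convergence yields a non-estimable record,
#' never an error.
#'
#' @param reports A `normalized_reports` tibble.
#' @param drug Canonical ingredient defining exposure.
#' @param event Preferred term defining the response.
#' @param threshold Change-in-estimate threshold for "negligible"
#'   (default 0.10).
#' @param eps Guard for near-zero crude coefficients in the relative change
#'   denominator (default 0.05).
#'
#' @return One-row tibble: `drug`, `event`, `crude_log_odds`,
#'   `adjusted_log_odds`, `relative_change`, `negligible`, `n_used`,
#'   `status` (`"ok"` or the reason the check was not estimable).
#' @export
covariate_check <- function(reports, drug, event, threshold = 0.10, eps = 0.05) {
  complete <- !is.na(reports$age) & !is.na(reports$weight) &
    reports$sex %in% c("M", "F")
  dat <- reports[complete, ]
  if (nrow(dat) < 20) {
    return(.non_estimable(drug, event, "fewer than 20 complete-covariate reports",
                          nrow(dat)))
  }
  y <- vapply(dat$events, function(e) event %in% e, logical(1))
  x <- vapply(dat$drugs, function(d) drug %in% d, logical(1))
  if (all(x) || !any(x)) {
    return(.non_estimable(drug, event, "no exposure contrast", nrow(dat)))
  }
  if (sum(y[x]) == 0 || sum(y[!x]) == 0) {
    return(.non_estimable(drug, event, "event absent in one exposure arm",
                          nrow(dat)))
  }
  bins <- .bin_covariates(dat$age, dat$weight)
  frame <- data.frame(y = y, x = x,
                      age_group = bins$age_group,
                      weight_group = bins$weight_group,
                      sex = factor(dat$sex))
  # constant covariate columns carry no information and would break glm
  covars <- c("age_group", "weight_group", "sex")
  covars <- covars[vapply(frame[covars],
                          function(v) length(unique(v)) > 1, logical(1))]
  adj_formula <- stats::reformulate(c("x", covars), response = "y")

  fit_crude <- tryCatch(
    suppressWarnings(glm(y ~ x, data = frame, family = binomial())),
    error = function(e) NULL)
  fit_adj <- tryCatch(
    suppressWarnings(glm(adj_formula, data = frame, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit_crude) || is.null(fit_adj) ||
      !fit_crude$converged || !fit_adj$converged) {
    return(.non_estimable(drug, event, "model did not converge", nrow(dat)))
  }
  crude <- unname(coef(fit_crude)["xTRUE"])
  adjusted <- unname(coef(fit_adj)["xTRUE"])
  if (!is.finite(crude) || !is.finite(adjusted) ||
      abs(crude) > 15 || abs(adjusted) > 15) {
    return(.non_estimable(drug, event, "separation", nrow(dat)))
  }
  rel <- abs(adjusted - crude) / max(abs(crude), eps)
  tibble(drug = drug, event = event,
         crude_log_odds = crude, adjusted_log_odds = adjusted,
         relative_change = rel, negligible = rel < threshold,
         n_used = nrow(dat), status = "ok")
}

#' Covariate checks for a list of drug-event pairs
#'
#' @param reports A `normalized_reports` tibble.
#' @param pairs Data frame with columns `drug` and `event`.
#' @param threshold,eps Passed to [covariate_check()].
#' @return Tibble with one row per pair, order preserved; non-estimable
#'   pairs are retained with their status.
#' @export
check_all <- function(reports, pairs, threshold = 0.10, eps = 0.05) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(tibble(drug = character(), event = character(),
                  crude_log_odds = numeric(), adjusted_log_odds = numeric(),
                  relative_change = numeric(), negligible = logical(),
                  n_used = integer(), status = character()))
  }
  dplyr::bind_rows(Map(function(d, e) {
    covariate_check(reports, d, e, threshold = threshold, eps = eps)
  }, pairs$drug, pairs$event))
}
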