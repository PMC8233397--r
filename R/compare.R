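# Friedman rank tests across drug groups blocked by adverse events, and the
# eight group/pairwise comparisons of the analysis (ACEIs-beta, ARBs,
# quinapril, trandolapril).

#' Pooled group PRR vector over events
#'
#' Collapses a set of drugs into one pseudo-drug (counts summed across
#' members) and computes its per-event PRR against all remaining drugs of
#' the cube's universe. A singleton group reproduces that drug's PRRs
#' exactly.
#'
#' @param cube A `contingency_cube`.
#' @param group Non-empty character vector of drugs, a strict subset of the
#'   cube's universe.
#' @param ci_variant Passed through to the PRR core (CI columns unused
#'   here).
#' @return Named numeric vector of PRRs, one per event (NA where
#'   undefined).
#' @export
pool_group_prr <- function(cube, group, ci_variant = "as_printed") {
  stopifnot(length(group) > 0)
  unknown <- setdiff(group, cube$drugs)
  if (length(unknown) > 0) {
    stop("group drug(s) not in cube: ", paste(unknown, collapse = ", "))
  }
  rest <- setdiff(cube$drugs, group)
  if (length(rest) == 0) stop("group exhausts the drug universe: no comparator")
  in_group <- cube$drugs %in% group
  r <- rowSums(cube$counts[, in_group, drop = FALSE])
  t_i <- rowSums(cube$counts)
  n_g <- sum(cube$n_j[in_group])
  core <- .prr_core(r, rep(n_g, length(r)), t_i, rep(cube$N, length(r)),
                    ci_variant = ci_variant)
  setNames(core$prr, cube$events)
}

# Tie-corrected Friedman Q for a blocks x treatments value matrix.
# Q = 12 * sum_j (R_j - b(k+1)/2)^2 / (b k (k+1) - sum_blocks(t^3 - t)/(k-1))
# with R_j the column rank sums (average ranks for ties). Returns 0 when
# every block is completely tied (denominator 0).
.friedman_q <- function(values) {
  ranks <- t(apply(values, 1, rank))
  b <- nrow(values)
  k <- ncol(values)
  tie_term <- sum(apply(ranks, 1, function(u) {
    tab <- table(u)
    sum(tab^3 - tab)
  }))
  denom <- b * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) return(0)
  num <- 12 * sum((colSums(ranks) - b * (k + 1) / 2)^2)
  num / denom
}

#' Friedman rank test over a blocks x treatments matrix
#'
#' Ranks values within each block (average ranks for ties) and computes the
#' tie-corrected Friedman statistic Q. The p-value comes either from the
#' chi-square approximation with k-1 degrees of freedom, or from the exact
#' permutation distribution over the within-block orderings — enumerated
#' completely when there are at most `enumerate_limit` orderings, otherwise
#' estimated from `n_perm` sampled orderings (set the RNG seed for
#' reproducibility).
#'
#' @param values Numeric matrix, blocks (>= 2) x treatments (>= 2), no
#'   missing cells.
#' @param method `"chi2_approx"` (default) or `"exact_permutation"`.
#' @param n_perm Number of sampled orderings when full enumeration is too
#'   large (default 4000).
#' @param enumerate_limit Maximum number of orderings to enumerate
#'   exhaustively (default 1e6).
#'
#' @return Tibble with `statistic`, `df`, `p_value`, `method`, `n_blocks`,
#'   `n_treatments`.
#' @export
friedman_test <- function(values, method = c("chi2_approx", "exact_permutation"),
                          n_perm = 4000, enumerate_limit = 1e6) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("need at least 2 blocks and 2 treatments")
  }
  if (anyNA(values)) stop("value matrix has missing cells")
  b <- nrow(values)
  k <- ncol(values)
  q_obs <- .friedman_q(values)

  if (method == "chi2_approx") {
    p <- pchisq(q_obs, df = k - 1, lower.tail = FALSE)
    p <- min(max(p, .Machine$double.xmin), 1)
  } else {
    ranks <- t(apply(values, 1, rank))
    perms <- .permutations(k)          # k! x k index matrix
    n_total <- nrow(perms)^b
    if (n_total <= enumerate_limit) {
      # walk the mixed-radix counter over blocks
      idx <- rep(1L, b)
      hits <- 0L
      repeat {
        qp <- .friedman_q_ranks(
          do.call(rbind, lapply(seq_len(b), function(bb) ranks[bb, perms[idx[bb], ]])),
          b, k)
        if (qp >= q_obs - 1e-12) hits <- hits + 1L
        pos <- 1L
        while (pos <= b) {
          idx[pos] <- idx[pos] + 1L
          if (idx[pos] <= nrow(perms)) break
          idx[pos] <- 1L
          pos <- pos + 1L
        }
        if (pos > b) break
      }
      p <- hits / n_total
    } else {
      hits <- 0L
      for (s in seq_len(n_perm)) {
        choice <- sample.int(nrow(perms), b, replace = TRUE)
        permuted <- do.call(rbind, lapply(seq_len(b),
                                          function(bb) ranks[bb, perms[choice[bb], ]]))
        if (.friedman_q_ranks(permuted, b, k) >= q_obs - 1e-12) hits <- hits + 1L
      }
      p <- (hits + 1) / (n_perm + 1)
    }
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  tibble(statistic = q_obs, df = k - 1, p_value = p, method = method,
         n_blocks = b, n_treatments = k)
}

# Q from an already-ranked matrix (tie term recomputed; permuting a block's
# ranks never changes its tie multiset, but recomputing keeps this honest).
.friedman_q_ranks <- function(ranks, b, k) {
  tie_term <- sum(apply(ranks, 1, function(u) {
    tab <- table(u)
    sum(tab^3 - tab)
  }))
  denom <- b * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) return(0)
  12 * sum((colSums(ranks) - b * (k + 1) / 2)^2) / denom
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (pos in seq_len(k)) {
    for (r in seq_len(nrow(sub))) {
      v <- integer(k)
      v[pos] <- k
      v[-pos] <- sub[r, ]
      out[row, ] <- v
      row <- row + 1L
    }
  }
  out
}

#' Assemble a group-profile matrix of pooled PRRs
#'
#' One column per group (each pooled against the rest of the cube's
#' universe via [pool_group_prr()]), one row per event. Undefined PRRs are
#' imputed as 0 for ranking, with a warning.
#'
#' @param cube A `contingency_cube`.
#' @param groups Named list of drug character vectors.
#' @return Events x groups numeric matrix.
#' @export
group_profile_matrix <- function(cube, groups) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  values <- vapply(groups, function(g) pool_group_prr(cube, g),
                   numeric(length(cube$events)))
  if (anyNA(values)) {
    warning(sum(is.na(values)), " undefined pooled PRR(s) imputed as 0")
    values[is.na(values)] <- 0
  }
  rownames(values) <- cube$events
  values
}

#' The eight group comparisons of the ACEI/ARB analysis
#'
#' Builds the published comparison set over the four groups ACEIs-beta
#' (ACEIs excluding quinapril and trandolapril), ARBs, quinapril and
#' trandolapril — the 4-group omnibus, ACEIs-beta vs ARBs, all ACEIs vs
#' ARBs, ACEIs-beta vs each singled-out drug, ARBs vs each, and quinapril
#' vs trandolapril — as Friedman tests over pooled group PRRs blocked by
#' the cube's events. Raw p-values are reported; a Bonferroni column
#' (times the number of rows) is emitted alongside.
#'
#' @param cube A `contingency_cube` whose drugs include quinapril and
#'   trandolapril.
#' @param class_of Named character vector mapping each drug to "ACEI" or
#'   "ARB" (default from [default_drug_dictionary()]).
#' @param method Passed to [friedman_test()].
#' @return Tibble with `comparison`, `statistic`, `df`, `p_value`,
#'   `p_bonferroni`, `method`.
#' @export
run_group_comparisons <- function(cube, class_of = NULL,
                                  method = c("chi2_approx", "exact_permutation")) {
  method <- match.arg(method)
  if (is.null(class_of)) {
    dict <- default_drug_dictionary()
    cls <- unique(as_tibble(dict)[c("ingredient", "class")])
    class_of <- setNames(cls$class, cls$ingredient)
  }
  unl <- setdiff(cube$drugs, names(class_of))
  if (length(unl) > 0) {
    stop("no class label for drug(s): ", paste(unl, collapse = ", "))
  }
  for (d in c("quinapril", "trandolapril")) {
    if (!d %in% cube$drugs) stop("required drug absent from cube: ", d)
  }
  aceis <- cube$drugs[class_of[cube$drugs] == "ACEI"]
  arbs <- cube$drugs[class_of[cube$drugs] == "ARB"]
  aceis_beta <- setdiff(aceis, c("quinapril", "trandolapril"))
  if (length(aceis_beta) == 0 || length(arbs) == 0) {
    stop("need at least one ACEI (besides quinapril/trandolapril) and one ARB")
  }
  groups <- list(
    "ACEIs-beta" = aceis_beta, "ARBs" = arbs, "ACEIs" = aceis,
    "quinapril" = "quinapril", "trandolapril" = "trandolapril"
  )
  comparisons <- list(
    "ACEIs-beta vs ARBs vs quinapril vs trandolapril" =
      c("ACEIs-beta", "ARBs", "quinapril", "trandolapril"),
    "ACEIs-beta vs ARBs" = c("ACEIs-beta", "ARBs"),
    "ACEIs vs ARBs" = c("ACEIs", "ARBs"),
    "ACEIs-beta vs quinapril" = c("ACEIs-beta", "quinapril"),
    "ACEIs-beta vs trandolapril" = c("ACEIs-beta", "trandolapril"),
    "ARBs vs quinapril" = c("ARBs", "quinapril"),
    "ARBs vs trandolapril" = c("ARBs", "trandolapril"),
    "Quinapril vs trandolapril" = c("quinapril", "trandolapril")
  )
  rows <- lapply(names(comparisons), function(label) {
    values <- group_profile_matrix(cube, groups[comparisons[[label]]])
    res <- friedman_test(values, method = method)
    tibble(comparison = label, statistic = res$statistic, df = res$df,
           p_value = res$p_value, method = res$method)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out[c("comparison", "statistic", "df", "p_value", "p_bonferroni", "method")]
}
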