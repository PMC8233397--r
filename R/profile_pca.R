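# Principal component analysis of the drugs x events PRR matrix, with
# biplot coordinates (drug scores, event loading arrows).

#' PCA of a drug x event PRR matrix
#'
#' Centers the event columns (and optionally unit-scales them), runs a
#' singular value decomposition via [stats::prcomp()], and keeps
#' `min(drugs - 1, events)` components. For reproducibility across linear
#' algebra backends, each loading vector is oriented so its
#' largest-magnitude element is positive.
#'
#' @param prr_matrix Numeric drugs x events matrix with dimnames and no
#'   missing values (impute undefined PRRs as 0 upstream).
#' @param scale Unit-scale columns? Default `FALSE` (centering only).
#'   Zero-variance columns are dropped with a warning when `scale = TRUE`.
#'
#' @return A `pca_prr` object: list with `scores` (drugs x components),
#'   `loadings` (events x components), `variance_explained` (fractions,
#'   non-increasing, summing to 1), `sdev`, `centered_means`, `scaled`.
#' @export
pca_prr <- function(prr_matrix, scale = FALSE) {
  x <- as.matrix(prr_matrix)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 drugs and 2 events")
  if (anyNA(x)) stop("PRR matrix has missing values; impute upstream")
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance event column(s): ",
              paste(colnames(x)[sds == 0], collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
      if (ncol(x) < 2) stop("fewer than 2 events left after dropping")
    }
  }
  fit <- prcomp(x, center = TRUE, scale. = scale)
  ncomp <- min(nrow(x) - 1, ncol(x))
  scores <- fit$x[, seq_len(ncomp), drop = FALSE]
  loadings <- fit$rotation[, seq_len(ncomp), drop = FALSE]
  sdev <- fit$sdev[seq_len(ncomp)]
  # orient each component: largest |loading| element positive
  for (c in seq_len(ncomp)) {
    peak <- which.max(abs(loadings[, c]))
    if (loadings[peak, c] < 0) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  ve <- sdev^2 / sum(fit$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve, sdev = sdev,
                 centered_means = fit$center,
                 scale_factors = if (scale) fit$scale else NULL,
                 scaled = scale),
            class = "pca_prr")
}

#' @export
print.pca_prr <- function(x, ...) {
  cat("<pca_prr> ", nrow(x$scores), " drugs, ", nrow(x$loadings),
      " events, ", length(x$sdev), " components\n", sep = "")
  cat("variance explained: ",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Biplot coordinates for a PCA of PRR profiles
#'
#' Drug points are the score columns for the chosen components; event
#' arrows are the loading vectors scaled by the component standard
#' deviations (correlation-biplot convention). Axis labels carry the
#' variance percentages.
#'
#' @param result A [pca_prr()] object.
#' @param pc_x,pc_y Component indices for the two axes (default 1 and 2).
#'
#' @return List with `points` (tibble: drug, x, y), `arrows`
#'   (tibble: event, x, y) and `labels` (axis labels).
#' @export
biplot_coordinates <- function(result, pc_x = 1, pc_y = 2) {
  ncomp <- length(result$sdev)
  if (pc_x < 1 || pc_x > ncomp || pc_y < 1 || pc_y > ncomp) {
    stop("component index out of range (1..", ncomp, ")")
  }
  points <- tibble(drug = rownames(result$scores),
                   x = result$scores[, pc_x],
                   y = result$scores[, pc_y])
  arrows <- tibble(event = rownames(result$loadings),
                   x = result$loadings[, pc_x] * result$sdev[pc_x],
                   y = result$loadings[, pc_y] * result$sdev[pc_y])
  labels <- c(
    x = sprintf("PC%d (%.2f%%)", pc_x, 100 * result$variance_explained[pc_x]),
    y = sprintf("PC%d (%.2f%%)", pc_y, 100 * result$variance_explained[pc_y])
  )
  list(points = points, arrows = arrows, labels = labels)
}

#' Plot a PRR biplot
#'
#' Renders [biplot_coordinates()] with ggplot2 (drug points, event arrows).
#'
#' @param result A [pca_prr()] object.
#' @param pc_x,pc_y Component indices.
#' @param arrow_scale Multiplier applied to arrows so they share the score
#'   scale (default: auto).
#' @return A ggplot object.
#' @export
plot_biplot <- function(result, pc_x = 1, pc_y = 2, arrow_scale = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_biplot needs the ggplot2 package")
  }
  bc <- biplot_coordinates(result, pc_x, pc_y)
  if (is.null(arrow_scale)) {
    span_p <- max(abs(c(bc$points$x, bc$points$y)))
    span_a <- max(abs(c(bc$arrows$x, bc$arrows$y)))
    arrow_scale <- if (span_a > 0) 0.8 * span_p / span_a else 1
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = bc$arrows,
      ggplot2::aes(x = 0, y = 0, xend = .data$x * arrow_scale,
                   yend = .data$y * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey50") +
    ggplot2::geom_text(
      data = bc$arrows,
      ggplot2::aes(x = .data$x * arrow_scale, y = .data$y * arrow_scale,
                   label = .data$event),
      size = 3, colour = "grey30", vjust = -0.5) +
    ggplot2::geom_point(data = bc$points,
                        ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(data = bc$points,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$drug),
                       size = 3, vjust = 1.5) +
    ggplot2::labs(x = bc$labels["x"], y = bc$labels["y"]) +
    ggplot2::theme_minimal()
}
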