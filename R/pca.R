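#' PCA score compression on a selected band subset
#'
#' Second-stage dimension reduction after wavelength selection: PCA is fitted
#' on the calibration rows of the selected bands only (mean-centered, not
#' scaled), and both sets are projected with the calibration loadings.
#'
#' @param cal_X,pred_X calibration and prediction matrices on the full grid.
#' @param subset non-empty integer band indices (e.g. a selection result's
#'   `$indices`).
#' @param max_pcs number of score columns to retain; at most
#'   `min(n_cal - 1, length(subset))`.
#' @return list with `cal_scores`, `pred_scores` and `model` (class
#'   `tea_pca`: subset, center, rotation, sdev, explained variance,
#'   n_components).
#' @export
pca_reduce <- function(cal_X, pred_X, subset, max_pcs) {
  cal_X <- as.matrix(cal_X); pred_X <- as.matrix(pred_X)
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0) stop("`subset` must be non-empty.", call. = FALSE)
  limit <- min(nrow(cal_X) - 1, length(subset))
  if (max_pcs > limit) {
    stop(sprintf("`max_pcs` must be <= %d for this data.", limit), call. = FALSE)
  }
  pr <- stats::prcomp(cal_X[, subset, drop = FALSE], center = TRUE, scale. = FALSE)
  keep <- seq_len(max_pcs)
  model <- structure(
    list(subset = subset, center = pr$center,
         rotation = pr$rotation[, keep, drop = FALSE],
         sdev = pr$sdev, explained_variance = pr$sdev^2,
         n_components = max_pcs),
    class = "tea_pca"
  )
  list(
    cal_scores = pr$x[, keep, drop = FALSE],
    pred_scores = project_pca(model, pred_X),
    model = model
  )
}

# project full-grid spectra with a fitted tea_pca
project_pca <- function(model, X) {
  Xs <- X[, model$subset, drop = FALSE]
  sweep(Xs, 2, model$center) %*% model$rotation
}

#' @export
print.tea_pca <- function(x, ...) {
  ev <- x$explained_variance / sum(x$explained_variance)
  cat(sprintf("<tea_pca> %d bands -> %d PCs (%.1f%% variance)\n",
              length(x$subset), x$n_components,
              100 * sum(ev[seq_len(x$n_components)])))
  invisible(x)
}
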