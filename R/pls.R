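#' Partial least squares regression (univariate NIPALS)
#'
#' NIPALS PLS1 on mean-centered data. For a single response each latent
#' variable needs one pass: weights from the X'y covariance, scores, loadings
#' and deflation. Score vectors are mutually orthogonal; at full rank the
#' fitted coefficients coincide with ordinary least squares.
#'
#' @param X calibration matrix (PCA scores or band subset), samples x features.
#' @param y calibration response; must have positive variance.
#' @param n_lv number of latent variables, at most `min(samples - 1, features)`.
#' @return object of class `tea_pls` with weights, loadings, scores, the
#'   regression vector and centering offsets.
#' @export
pls_train <- function(X, y, n_lv) {
  X <- as.matrix(X)
  if (stats::sd(y) == 0) stop("`y` has zero variance.", call. = FALSE)
  if (n_lv < 1 || n_lv > min(nrow(X) - 1, ncol(X))) {
    stop("`n_lv` must lie in 1..min(samples - 1, features).", call. = FALSE)
  }
  fit <- pls_core_fit(X, y, n_lv)
  if (fit$ncomp == 0) stop("no usable latent variables (degenerate X).", call. = FALSE)
  coef <- fit$R %*% fit$q
  structure(
    list(n_lv = fit$ncomp, weights = fit$W, loadings = fit$P, q = fit$q,
         scores = fit$scores, coefficients = as.vector(coef),
         x_center = fit$xm, y_center = fit$ym),
    class = "tea_pls"
  )
}

#' @export
predict.tea_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.vector(sweep(newdata, 2, object$x_center) %*% object$coefficients) +
    object$y_center
}

#' @export
print.tea_pls <- function(x, ...) {
  cat(sprintf("<tea_pls> %d latent variables over %d features\n",
              x$n_lv, length(x$coefficients)))
  invisible(x)
}

#' @export
tidy.tea_pls <- function(x, ...) {
  tibble::tibble(
    feature = rep(seq_along(x$coefficients), x$n_lv),
    latent_variable = rep(seq_len(x$n_lv), each = length(x$coefficients)),
    weight = as.vector(x$weights),
    loading = as.vector(x$loadings)
  )
}

#' @export
glance.tea_pls <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, n_features = length(x$coefficients))
}
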