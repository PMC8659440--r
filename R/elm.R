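#' Extreme learning machine regression
#'
#' Single-hidden-layer feedforward network whose input weights and biases are
#' drawn once from Uniform(-1, 1) and never updated; only the output weights
#' are estimated, by a ridge-regularized least-squares solve on the hidden
#' activations (logistic sigmoid). Inputs are standardized with training
#' statistics so the sigmoid operates in its active range. Deterministic for
#' a fixed seed.
#'
#' @param X training matrix (typically PCA scores).
#' @param y training response.
#' @param hidden hidden-layer width (default 50).
#' @param seed integer seed for the random projection.
#' @param ridge ridge penalty on the output weights (default 1e-8).
#' @return object of class `tea_elm`.
#' @export
elm_train <- function(X, y, hidden = 50, seed = 1, ridge = 1e-8) {
  X <- as.matrix(X)
  if (hidden < 1) stop("`hidden` must be >= 1.", call. = FALSE)
  mu <- colMeans(X)
  sc <- apply(X, 2, stats::sd); sc[sc == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sc, "/")
  withr::with_seed(seed, {
    W <- matrix(stats::runif(ncol(X) * hidden, -1, 1), ncol(X), hidden)
    b <- stats::runif(hidden, -1, 1)
  })
  H <- stats::plogis(sweep(Xs %*% W, 2, b, "+"))
  if (!all(is.finite(H))) stop("non-finite hidden activations.", call. = FALSE)
  beta <- solve(crossprod(H) + diag(ridge, hidden), crossprod(H, y))
  structure(
    list(hidden = hidden, W = W, b = b, beta = as.vector(beta),
         x_center = mu, x_scale = sc, seed = seed, ridge = ridge),
    class = "tea_elm"
  )
}

#' @export
predict.tea_elm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  H <- stats::plogis(sweep(Xs %*% object$W, 2, object$b, "+"))
  as.vector(H %*% object$beta)
}

#' @export
print.tea_elm <- function(x, ...) {
  cat(sprintf("<tea_elm> %d inputs -> %d sigmoid units (seed %d)\n",
              nrow(x$W), x$hidden, x$seed))
  invisible(x)
}

#' @export
glance.tea_elm <- function(x, ...) {
  tibble::tibble(hidden = x$hidden, ridge = x$ridge, seed = x$seed)
}
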