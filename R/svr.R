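#' Grid-tuned epsilon-SVR with RBF kernel
#'
#' Support vector regression (radial basis kernel) with the penalty `c` and
#' kernel width `g` tuned by grid search on k-fold CV RMSE. The default grids
#' run c = 2^-5..2^15 and g = 2^-15..2^3 in steps of 2^0.5, covering the
#' commonly reported optima (c = 2.83 = 2^1.5, g = 0.5, ...). Ties prefer the
#' smaller c, then the smaller g. Epsilon is 0.01 on the standardized
#' response. A constant response yields a degenerate model that predicts the
#' constant.
#'
#' @param X training matrix (typically PCA scores).
#' @param y training response.
#' @param c_grid,g_grid positive tuning grids.
#' @param folds CV folds (default 5).
#' @param seed seed for the fold shuffle.
#' @param epsilon epsilon-tube width on the standardized response.
#' @return list with `model` (class `tea_svr`), `best_c`, `best_g` and
#'   `cv_rmse` (the minimal CV RMSE).
#' @export
svr_train_tuned <- function(X, y, c_grid = 2^seq(-5, 15, by = 0.5),
                            g_grid = 2^seq(-15, 3, by = 0.5), folds = 5,
                            seed = 1, epsilon = 0.01) {
  X <- as.matrix(X)
  if (length(c_grid) == 0 || length(g_grid) == 0 ||
      any(c_grid <= 0) || any(g_grid <= 0)) {
    stop("tuning grids must be non-empty and positive.", call. = FALSE)
  }
  if (anyNA(y) || !all(is.finite(y))) stop("degenerate `y`.", call. = FALSE)
  if (stats::sd(y) == 0) {
    model <- structure(list(constant = y[1], fit = NULL,
                            c = min(c_grid), g = min(g_grid)),
                       class = "tea_svr")
    return(list(model = model, best_c = min(c_grid), best_g = min(g_grid),
                cv_rmse = 0))
  }
  fold_id <- make_fold_id(nrow(X), folds, seed)
  best <- list(rmse = Inf, c = NA, g = NA)
  for (cc in sort(c_grid)) {
    for (gg in sort(g_grid)) {
      sse <- 0
      for (f in seq_len(folds)) {
        te <- fold_id == f
        fit <- e1071::svm(X[!te, , drop = FALSE], y[!te],
                          type = "eps-regression", kernel = "radial",
                          cost = cc, gamma = gg, epsilon = epsilon,
                          scale = TRUE)
        sse <- sse + sum((stats::predict(fit, X[te, , drop = FALSE]) - y[te])^2)
      }
      rmse <- sqrt(sse / nrow(X))
      if (rmse < best$rmse) best <- list(rmse = rmse, c = cc, g = gg)
    }
  }
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    cost = best$c, gamma = best$g, epsilon = epsilon,
                    scale = TRUE)
  model <- structure(list(constant = NULL, fit = fit, c = best$c, g = best$g),
                     class = "tea_svr")
  list(model = model, best_c = best$c, best_g = best$g, cv_rmse = best$rmse)
}

#' @export
predict.tea_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$constant)) return(rep(object$constant, nrow(newdata)))
  as.vector(stats::predict(object$fit, newdata))
}

#' @export
print.tea_svr <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("<tea_svr> degenerate constant model (%.4g)\n", x$constant))
  } else {
    cat(sprintf("<tea_svr> RBF eps-SVR, c = %.4g, g = %.4g, %d SVs\n",
                x$c, x$g, x$fit$tot.nSV))
  }
  invisible(x)
}

#' @export
glance.tea_svr <- function(x, ...) {
  tibble::tibble(c = x$c, g = x$g,
                 n_sv = if (is.null(x$fit)) 0L else x$fit$tot.nSV)
}
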