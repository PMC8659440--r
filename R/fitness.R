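# Shared cross-validated objective for the wavelength selectors, plus the fast
# univariate NIPALS core it relies on. For a single response NIPALS needs one
# pass per latent variable, and predictions for all 1..k component counts fall
# out of one fit, so 5-fold CV over a candidate subset costs five fits.

# One NIPALS fit; returns what is needed to predict with any number of LVs.
pls_core_fit <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1, p)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  a <- 0
  for (k in seq_len(ncomp)) {
    w <- crossprod(E, f)[, 1]
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- crossprod(E, t)[, 1] / tt
    qk <- sum(f * t) / tt
    E <- E - tcrossprod(t, pv)
    f <- f - qk * t
    a <- k
    W[, k] <- w; P[, k] <- pv; Tm[, k] <- t; q[k] <- qk
  }
  if (a == 0) return(list(ncomp = 0, xm = xm, ym = ym))
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  # R maps centered X to scores: T = Xc R ; R = W (P'W)^-1
  R <- W %*% solve(crossprod(P, W))
  list(ncomp = a, xm = xm, ym = ym, W = W, P = P, q = q, R = R,
       scores = Tm[, seq_len(a), drop = FALSE])
}

# predictions for all component counts 1..fit$ncomp: n_new x ncomp matrix
pls_core_predict_all <- function(fit, Xnew) {
  if (fit$ncomp == 0) {
    return(matrix(fit$ym, nrow(Xnew), 1))
  }
  Tn <- sweep(Xnew, 2, fit$xm) %*% fit$R
  S <- sweep(Tn, 2, fit$q, "*")
  cum <- if (ncol(S) == 1) S else t(apply(S, 1, cumsum))
  fit$ym + matrix(cum, nrow(Xnew), ncol(S))
}

# CV RMSE per number of latent variables (vector of length <= ncomp_max)
cv_rmse_pls <- function(X, y, fold_id, ncomp_max) {
  k <- max(fold_id)
  sse <- numeric(ncomp_max); cnt <- numeric(ncomp_max)
  for (fold in seq_len(k)) {
    te <- fold_id == fold
    fit <- pls_core_fit(X[!te, , drop = FALSE], y[!te], ncomp_max)
    pred <- pls_core_predict_all(fit, X[te, , drop = FALSE])
    nc <- ncol(pred)
    if (nc < ncomp_max) {  # rank-limited fold: reuse the deepest model
      pred <- cbind(pred, matrix(pred[, nc], sum(te), ncomp_max - nc))
    }
    err2 <- (pred - y[te])^2
    sse <- sse + colSums(err2)
    cnt <- cnt + sum(te)
  }
  sqrt(sse / cnt)
}

# rank-tolerant multiple linear regression via pivoted QR
mlr_fit <- function(X, y) {
  qx <- qr(cbind(1, X))
  co <- qr.coef(qx, y)
  co[is.na(co)] <- 0
  co
}

mlr_predict <- function(coef, Xnew) as.vector(cbind(1, Xnew) %*% coef)

cv_rmse_mlr <- function(X, y, fold_id) {
  k <- max(fold_id)
  sse <- 0; cnt <- 0
  for (fold in seq_len(k)) {
    te <- fold_id == fold
    co <- mlr_fit(X[!te, , drop = FALSE], y[!te])
    pred <- mlr_predict(co, X[te, , drop = FALSE])
    sse <- sse + sum((pred - y[te])^2)
    cnt <- cnt + sum(te)
  }
  sqrt(sse / cnt)
}

make_fold_id <- function(n, folds, seed) {
  if (folds < 2) stop("`folds` must be >= 2.", call. = FALSE)
  if (folds > n) stop("more folds than samples.", call. = FALSE)
  withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
}

#' Cross-validated fitness of a wavelength subset
#'
#' The shared objective the metaheuristic selectors minimize: k-fold CV RMSE
#' of an inner regressor on the candidate band subset. Small subsets (up to
#' `mlr_max` bands) use multiple linear regression; larger ones use PLS with
#' the best 1..`max_comp` latent variables. Fold assignment is drawn once from
#' `seed`, so the same subset always maps to the same fitness; evaluations are
#' memoized.
#'
#' @param X calibration matrix (samples x bands).
#' @param y calibration response.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @param max_comp PLS latent-variable cap (default 10).
#' @param mlr_max largest subset size fitted by MLR (default 10).
#' @return object of class `subset_fitness`; call it via [fitness_eval()].
#' @export
subset_fitness <- function(X, y, folds = 5, seed = 1, max_comp = 10,
                           mlr_max = 10) {
  X <- as.matrix(X)
  fold_id <- make_fold_id(nrow(X), folds, seed)
  cache <- new.env(parent = emptyenv())
  structure(
    list(X = X, y = y, fold_id = fold_id, folds = folds, seed = seed,
         max_comp = max_comp, mlr_max = mlr_max, cache = cache),
    class = "subset_fitness"
  )
}

#' @rdname subset_fitness
#' @param fitness a `subset_fitness` object.
#' @param idx integer band indices (non-empty).
#' @export
fitness_eval <- function(fitness, idx) {
  stopifnot(inherits(fitness, "subset_fitness"))
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0) stop("empty subset.", call. = FALSE)
  key <- paste(idx, collapse = ",")
  hit <- fitness$cache[[key]]
  if (!is.null(hit)) return(hit)
  Xs <- fitness$X[, idx, drop = FALSE]
  val <- if (length(idx) <= fitness$mlr_max) {
    cv_rmse_mlr(Xs, fitness$y, fitness$fold_id)
  } else {
    min(cv_rmse_pls(Xs, fitness$y, fitness$fold_id, fitness$max_comp))
  }
  fitness$cache[[key]] <- val
  val
}
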