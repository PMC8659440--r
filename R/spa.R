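#' Successive projections algorithm (SPA) wavelength selection
#'
#' From every starting band a chain is grown by repeatedly projecting the
#' remaining band columns onto the orthogonal complement of the span of the
#' already-selected columns and taking the column with the largest projection
#' norm (minimal collinearity with the chain). Each chain prefix of length
#' `kmin..kmax` is scored by the validation RMSE of a multiple linear
#' regression fitted on an internal deterministic Kennard-Stone split of the
#' calibration set; the best (start, length) wins, with ties going to the
#' shorter chain.
#'
#' @param Xcal calibration matrix (samples x bands).
#' @param ycal calibration response.
#' @param kmin,kmax chain length bounds; `kmax` at most
#'   `min(bands, samples - 1)`.
#' @param wavelengths_nm optional band wavelengths (defaults to band index).
#' @param val_fraction internal validation fraction (default 0.25).
#' @return a [selection_result()] with algorithm "SPA". The fitness trace
#'   holds, for each chain length, the best validation RMSE across starts.
#' @export
spa_select <- function(Xcal, ycal, kmin = 1, kmax = NULL,
                       wavelengths_nm = NULL, val_fraction = 0.25) {
  X <- as.matrix(Xcal)
  n <- nrow(X); p <- ncol(X)
  if (is.null(kmax)) kmax <- min(p, n - 2, 25)
  if (kmax < kmin) stop("`kmax` must be >= `kmin`.", call. = FALSE)
  if (kmin < 1 || kmax > min(p, n - 1)) {
    stop("chain lengths must satisfy 1 <= kmin <= kmax <= min(bands, n - 1).",
         call. = FALSE)
  }
  if (is.null(wavelengths_nm)) wavelengths_nm <- seq_len(p)

  split <- kennard_stone(X, cal_fraction = 1 - val_fraction)
  tr <- split$calibration; va <- split$prediction
  Xtr <- X[tr, , drop = FALSE]; ytr <- ycal[tr]
  Xva <- X[va, , drop = FALSE]; yva <- ycal[va]

  chains <- spa_chains(Xtr, kmax)
  best <- list(rmse = Inf, start = NA, k = NA)
  trace <- rep(Inf, kmax - kmin + 1)
  for (s in seq_len(p)) {
    chain <- chains[[s]]
    if (length(chain) < kmin) next
    for (k in kmin:min(kmax, length(chain))) {
      idx <- chain[seq_len(k)]
      co <- mlr_fit(Xtr[, idx, drop = FALSE], ytr)
      rmse <- sqrt(mean((mlr_predict(co, Xva[, idx, drop = FALSE]) - yva)^2))
      ti <- k - kmin + 1
      if (rmse < trace[ti]) trace[ti] <- rmse
      better <- rmse < best$rmse ||
        (rmse == best$rmse && !is.na(best$k) && k < best$k)
      if (better) best <- list(rmse = rmse, start = s, k = k)
    }
  }
  idx <- chains[[best$start]][seq_len(best$k)]
  selection_result("SPA", idx, wavelengths_nm, best$rmse,
                   fitness_trace = trace, n_bands = p)
}

# grow a projection chain from every starting column; returns list of integer
# chains. Columns whose residual norm vanishes (collinear with the chain) are
# never picked.
spa_chains <- function(X, kmax) {
  p <- ncol(X)
  lapply(seq_len(p), function(s) {
    R <- X
    chain <- s
    for (step in seq_len(kmax - 1)) {
      v <- R[, chain[length(chain)]]
      vv <- sum(v^2)
      if (vv < 1e-12) break
      R <- R - v %*% (crossprod(v, R) / vv)
      norms <- colSums(R^2)
      norms[chain] <- -1
      nxt <- which.max(norms)
      if (norms[nxt] < 1e-10) break
      chain <- c(chain, nxt)
    }
    chain
  })
}

# single greedy step: explicit projection norms of the remaining columns on
# the orthogonal complement of the selected span (used as an oracle hook and
# exported for transparency)
#' Projection norms underlying one SPA step
#'
#' Returns the squared norms of every column of `X` after projecting out the
#' span of the columns in `selected` (those columns score 0). The next SPA
#' pick is the argmax.
#' @param X matrix.
#' @param selected chain so far (integer indices).
#' @return numeric vector of squared residual norms.
#' @export
spa_projection_norms <- function(X, selected) {
  Q <- qr.Q(qr(X[, selected, drop = FALSE]))
  R <- X - Q %*% crossprod(Q, X)
  ns <- colSums(R^2)
  ns[selected] <- 0
  ns
}
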