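#' Choose the number of principal components by minimal RMSECV
#'
#' Evaluates models on the first 1..max PCA score columns by k-fold
#' cross-validated RMSE and returns the count minimizing it (ties go to the
#' fewer components). For PLS the latent-variable count equals the score
#' count; ELM and SVR are refit per candidate count with fixed default
#' hyperparameters (final SVR tuning happens afterwards on the chosen count).
#'
#' @param cal_scores calibration PCA scores (samples x PCs).
#' @param ycal calibration response.
#' @param model_kind "pls", "elm" or "svr".
#' @param folds CV folds (default 10).
#' @param seed seed for the fold shuffle.
#' @param max_pcs optional cap (default: all score columns).
#' @param hidden,ridge ELM parameters used during the scan.
#' @return list with `best_pcs`, `rmsecv` (at the optimum) and `trace`
#'   (RMSECV for every candidate count).
#' @export
choose_pcs_by_rmsecv <- function(cal_scores, ycal,
                                 model_kind = c("pls", "elm", "svr"),
                                 folds = 10, seed = 1, max_pcs = NULL,
                                 hidden = 50, ridge = 1e-8) {
  model_kind <- match.arg(model_kind)
  X <- as.matrix(cal_scores)
  n <- nrow(X)
  if (folds > n) stop("more folds than samples.", call. = FALSE)
  if (is.null(max_pcs)) max_pcs <- ncol(X)
  max_pcs <- min(max_pcs, ncol(X), n - 1)
  fold_id <- make_fold_id(n, folds, seed)

  trace <- if (model_kind == "pls") {
    # npc score columns, full-rank PLS (npc latent variables)
    vapply(seq_len(max_pcs), function(npc) {
      cv <- cv_rmse_pls(X[, seq_len(npc), drop = FALSE], ycal, fold_id, npc)
      cv[length(cv)]
    }, numeric(1))
  } else {
    vapply(seq_len(max_pcs), function(npc) {
      Xp <- X[, seq_len(npc), drop = FALSE]
      sse <- 0
      for (f in seq_len(folds)) {
        te <- fold_id == f
        pred <- if (model_kind == "elm") {
          m <- elm_train(Xp[!te, , drop = FALSE], ycal[!te], hidden = hidden,
                         seed = seed, ridge = ridge)
          predict(m, Xp[te, , drop = FALSE])
        } else {
          m <- e1071::svm(Xp[!te, , drop = FALSE], ycal[!te],
                          type = "eps-regression", kernel = "radial",
                          cost = 1, gamma = 1 / npc, epsilon = 0.01,
                          scale = TRUE)
          as.vector(stats::predict(m, Xp[te, , drop = FALSE]))
        }
        sse <- sse + sum((pred - ycal[te])^2)
      }
      sqrt(sse / n)
    }, numeric(1))
  }
  # fewest components on (numerical) ties: RMSECVs within a relative hair of
  # the minimum, or both indistinguishable from zero on the response scale
  tol <- max(1e-10, 1e-8 * min(trace), 1e-8 * stats::sd(ycal))
  best <- which(trace <= min(trace) + tol)[1]
  list(best_pcs = best, rmsecv = trace[best], trace = trace)
}
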