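test_that("PCA reduction conserves variance and reconstructs at full rank", {
  withr::with_seed(41, {
    cal <- matrix(rnorm(30 * 8), 30, 8)
    pred <- matrix(rnorm(10 * 8), 10, 8)
  })
  red <- pca_reduce(cal, pred, subset = 1:8, max_pcs = 8)
  m <- red$model
  expect_lt(max(abs(crossprod(m.rot <- m$rotation) - diag(8))), 1e-8)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  expect_equal(sum(m$explained_variance), sum(apply(cal, 2, var)),
               tolerance = 1e-8)
  recon <- red$cal_scores %*% t(m$rotation)
  recon <- sweep(recon, 2, m$center, "+")
  expect_lt(max(abs(recon - cal)), 1e-8)
  # rank-2 data: third PC variance vanishes
  withr::with_seed(42, {
    A <- matrix(rnorm(30 * 2), 30, 2)
    low <- A %*% matrix(rnorm(2 * 6), 2, 6)
  })
  r2 <- pca_reduce(low, low, 1:6, 4)
  expect_lt(r2$model$explained_variance[3], 1e-20)
  expect_error(pca_reduce(cal, pred, 1:8, max_pcs = 9), "<=")
})

test_that("NIPALS PLS matches OLS at full rank with orthogonal scores", {
  withr::with_seed(43, {
    X <- matrix(rnorm(40 * 5), 40, 5)
    y <- X %*% runif(5) + rnorm(40, sd = 0.1)
  })
  fit <- pls_train(X, y, 5)
  ols <- lm.fit(cbind(1, X), y)
  pred_ols <- cbind(1, X) %*% ols$coefficients
  expect_lt(max(abs(predict(fit, X) - pred_ols)), 1e-6)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # noiseless single-latent-variable data: one LV fits exactly
  withr::with_seed(55, {
    t0 <- rnorm(40)
    X1 <- outer(t0, runif(5, -1, 1))
  })
  f1 <- pls_train(X1, t0, 1)
  expect_lt(sqrt(mean((predict(f1, X1) - t0)^2)) / sd(t0), 1e-8)
  expect_error(pls_train(X, rep(2, 40), 2), "zero variance")
  expect_error(pls_train(X, drop(y), 50), "n_lv")
})

test_that("ELM interpolates, is seed-stable and learns a nonlinearity", {
  withr::with_seed(44, {
    X <- matrix(rnorm(30 * 3), 30, 3)
    y <- rnorm(30)
  })
  fit <- elm_train(X, y, hidden = 100, seed = 1, ridge = 1e-12)
  expect_lt(sqrt(mean((predict(fit, X) - y)^2)), 1e-6)
  fit2 <- elm_train(X, y, hidden = 100, seed = 1, ridge = 1e-12)
  expect_identical(predict(fit, X), predict(fit2, X))
  withr::with_seed(45, {
    x <- matrix(runif(150, -3, 3), ncol = 1)
    ysin <- sin(x[, 1]) + rnorm(150, sd = 0.01)
  })
  tr <- 1:100; te <- 101:150
  m <- elm_train(x[tr, , drop = FALSE], ysin[tr], hidden = 50, seed = 2)
  expect_gt(cor(predict(m, x[te, , drop = FALSE]), ysin[te]), 0.95)
})

test_that("tuned SVR covers the canonical grid and is self-consistent", {
  defaults <- formals(svr_train_tuned)
  c_grid <- eval(defaults$c_grid); g_grid <- eval(defaults$g_grid)
  expect_true(any(abs(c_grid - 2^1.5) < 1e-9))  # c = 2.83
  expect_true(any(g_grid == 0.5))
  withr::with_seed(46, {
    X <- matrix(rnorm(50 * 3), 50, 3)
    y <- sin(X[, 1]) + rnorm(50, sd = 0.05)
  })
  cg <- 2^c(-1, 1, 3); gg <- 2^c(-3, -1, 1)
  res <- svr_train_tuned(X, y, cg, gg, folds = 4, seed = 3)
  # re-running the CV at the returned (c, g) reproduces the reported minimum
  redo <- svr_train_tuned(X, y, res$best_c, res$best_g, folds = 4, seed = 3)
  expect_equal(redo$cv_rmse, res$cv_rmse, tolerance = 1e-12)
  expect_true(res$best_c %in% cg && res$best_g %in% gg)
  # constant response: degenerate model predicts the constant
  resc <- svr_train_tuned(X, rep(3, 50), cg, gg, folds = 4, seed = 3)
  expect_equal(predict(resc$model, X), rep(3, 50))
  expect_error(svr_train_tuned(X, y, numeric(0), gg), "non-empty")
})

test_that("RMSECV picks the true dimensionality and reports honestly", {
  withr::with_seed(47, {
    t1 <- rnorm(60)
    scores <- cbind(t1, matrix(rnorm(60 * 4, sd = 1), 60, 4))
    y <- 2 * t1  # noiseless single-factor response
  })
  res <- choose_pcs_by_rmsecv(scores, y, "pls", folds = 5, seed = 1)
  expect_equal(res$best_pcs, 1)
  expect_lt(res$rmsecv, 1e-8)
  expect_equal(res$rmsecv, res$trace[res$best_pcs])
  # pure-noise response: the optimum cannot beat sd(y) by much
  withr::with_seed(48, ynoise <- rnorm(60))
  resn <- choose_pcs_by_rmsecv(scores, ynoise, "pls", folds = 5, seed = 1)
  expect_lt(abs(resn$rmsecv - sd(ynoise)) / sd(ynoise), 0.2)
  expect_error(choose_pcs_by_rmsecv(scores, y, "pls", folds = 100), "folds")
})

test_that("model evaluation reports the RPD identity and grades", {
  withr::with_seed(49, {
    X <- matrix(rnorm(40 * 3), 40, 3)
    y <- X[, 1] + rnorm(40, sd = 0.2)
  })
  fit <- pls_train(X[1:30, ], y[1:30], 3)
  ev <- evaluate_model(fit, X[1:30, ], y[1:30], X[31:40, ], y[31:40],
                       rmsecv = 0.2, pcs = 3)
  expect_equal(ev$rpd * ev$rmsep, sd(y[31:40]), tolerance = 1e-9)
  expect_true(abs(ev$rc) <= 1 && abs(ev$rp) <= 1)
  # a reference sd of 1.1375 with RMSEP 0.175 is exactly RPD 6.5
  expect_equal(1.1375 / 0.175, 6.5)
  expect_equal(rpd_grade(6.5), "accurate")
  expect_equal(rpd_grade(1.9), "inadequate")
  expect_equal(rpd_grade(1.5), "rough")
  expect_equal(rpd_grade(1.2), "inadequate")
  # predicting the reference exactly: warning, infinite RPD, accurate
  ident <- structure(list(), class = "identity_model")
  assign("predict.identity_model",
         function(object, newdata, ...) newdata[, 1], envir = globalenv())
  on.exit(rm("predict.identity_model", envir = globalenv()), add = TRUE)
  Xp <- matrix(y[31:40], ncol = 1)
  expect_warning(
    evi <- evaluate_model(ident, matrix(y[1:30], ncol = 1), y[1:30], Xp,
                          y[31:40]),
    "infinite")
  expect_equal(evi$rp, 1)
  expect_equal(evi$rmsep, 0)
  expect_equal(evi$grade, "accurate")
  expect_error(evaluate_model(fit, X, y, X[0, , drop = FALSE], numeric(0)),
               "non-empty")
})
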