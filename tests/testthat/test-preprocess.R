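test_that("black/white calibration maps references to 0/1", {
  dark <- rep(100, 10); white <- rep(900, 10)
  raw <- rbind(white, dark, (dark + white) / 2)
  r <- calibrate_reflectance(raw, dark, white)
  expect_equal(unname(r[1, ]), rep(1, 10))
  expect_equal(unname(r[2, ]), rep(0, 10))
  expect_equal(unname(r[3, ]), rep(0.5, 10))
  expect_error(calibrate_reflectance(raw, dark, dark), "exceed")
})

test_that("SNV standardizes every row and is idempotent", {
  expect_equal(as.vector(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))
  withr::with_seed(1, x <- matrix(rnorm(20 * 50), 20, 50))
  s <- snv(x)
  expect_lt(max(abs(rowMeans(s))), 1e-10)
  expect_lt(max(abs(apply(s, 1, sd) - 1)), 1e-10)
  expect_lt(max(abs(snv(s) - s)), 1e-10)
  x[3, ] <- 7
  expect_error(snv(x), "row\\(s\\): 3")
})

test_that("MSC inverts affine scatter against the reference", {
  withr::with_seed(2, {
    ref <- sin(seq(0, 3, length.out = 60)) + 2
    slopes <- runif(15, 0.5, 2); offs <- rnorm(15, sd = 0.3)
    x <- outer(slopes, ref) + offs
  })
  out <- msc(x, reference = ref)
  # every corrected row refits on the reference with slope 1, intercept 0
  for (i in seq_len(nrow(out))) {
    co <- coef(lm(out[i, ] ~ ref))
    expect_lt(abs(co[2] - 1), 1e-8)
    expect_lt(abs(co[1]), 1e-8)
  }
  expect_equal(msc(matrix(ref, 1), reference = ref)[1, ], ref)
  expect_equal(msc(matrix(2 * ref + 1, 1), reference = ref)[1, ], ref)
  # reference = own mean leaves the mean spectrum essentially invariant
  # (exactly so for the reference row itself; the set mean to first order)
  withr::with_seed(3, y <- matrix(rnorm(10 * 30, sd = 0.1), 10, 30) +
                     rep(ref[1:30], each = 10))
  expect_lt(max(abs(colMeans(msc(y)) - colMeans(y))), 0.02)
})

test_that("Savitzky-Golay second derivative is exact on polynomials", {
  i <- 1:80
  quad <- matrix(0.5 * i^2 - 3 * i + 2, 1)
  d2 <- second_derivative(quad, window = 7, polyorder = 2)
  expect_lt(max(abs(d2 - 1)), 1e-9)  # d2/di2 of 0.5 i^2 = 1, edges included
  lin <- matrix(2 * i + 1, 1)
  expect_lt(max(abs(second_derivative(lin))), 1e-9)
  # smooth sinusoid vs central finite differences at interior points
  s <- matrix(sin(i / 14), 1)
  d2s <- second_derivative(s, window = 7, polyorder = 2)
  fd <- (s[1, 3:80] - 2 * s[1, 2:79] + s[1, 1:78])
  interior <- 10:70
  expect_lt(max(abs(d2s[1, interior] - fd[interior - 1]) / abs(fd[interior - 1])),
            0.01)
  expect_error(second_derivative(quad, window = 6), "odd")
  expect_error(second_derivative(quad, window = 3, polyorder = 3), "polyorder")
})

test_that("moving-average smoothing behaves at interior and edges", {
  const <- matrix(5, 2, 30)
  expect_equal(smooth_spectra(const, 5), const)
  imp <- matrix(0, 1, 21); imp[1, 11] <- 1
  sm <- smooth_spectra(imp, 5)
  expect_equal(sm[1, 9:13], rep(0.2, 5))
  # iid noise variance shrinks by ~ the window size
  withr::with_seed(4, z <- matrix(rnorm(500), 1))
  v <- var(smooth_spectra(z, 5)[1, 50:450])
  expect_gt(v, 0.7 / 5)
  expect_lt(v, 1.3 / 5)
  expect_error(smooth_spectra(imp, 23), "exceeds")
})

test_that("column standardization uses calibration statistics only", {
  withr::with_seed(5, {
    cal <- matrix(rnorm(40 * 12, mean = 3), 40, 12)
    pred <- matrix(rnorm(15 * 12, mean = 4), 15, 12)
  })
  z <- column_standardize(cal, pred, "zscore")
  expect_lt(max(abs(colMeans(z$cal))), 1e-10)
  expect_lt(max(abs(apply(z$cal, 2, sd) - 1)), 1e-10)
  expect_identical(z$stats$provenance, "calibration")
  # leakage guard: changing prediction rows never changes the statistics or
  # the transformed calibration set
  z2 <- column_standardize(cal, pred * 10 + 5, "zscore")
  expect_identical(z2$stats, z$stats)
  expect_identical(z2$cal, z$cal)

  mm <- column_standardize(cal, pred, "minmax")
  expect_true(all(mm$cal >= 0 & mm$cal <= 1))
  pred_at_min <- matrix(apply(cal, 2, min), 1, 12)
  expect_equal(as.vector(column_standardize(cal, pred_at_min, "minmax")$pred),
               rep(0, 12))

  ce <- column_standardize(cal, pred, "center")
  expect_lt(max(abs(colMeans(ce$cal))), 1e-10)
  expect_gt(max(abs(colMeans(ce$pred))), 0.1)  # pred means generally shift

  cal_bad <- cal; cal_bad[, 4] <- 2
  expect_error(column_standardize(cal_bad, pred, "zscore"), "4")
  expect_error(column_standardize(cal_bad, pred, "minmax"), "4")
})

test_that("all pretreatments preserve the sample x band shape", {
  withr::with_seed(6, x <- matrix(runif(18 * 25, 0.2, 0.9), 18, 25))
  for (f in list(snv, msc, function(m) second_derivative(m, 5, 2),
                 function(m) smooth_spectra(m, 3))) {
    expect_equal(dim(f(x)), dim(x))
  }
  fitted <- fit_preproc_chain(x, c("absorbance", "snv", "zscore"))
  expect_equal(dim(fitted$cal), dim(x))
  expect_equal(dim(apply_preproc_chain(x, fitted$chain)), dim(x))
  # replaying the chain on the calibration set reproduces the fitted output
  expect_equal(apply_preproc_chain(x, fitted$chain), fitted$cal)
})
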