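test_that("wavelength grids are uniform and validated", {
  g <- make_wavelength_grid(400, 960, 8)
  expect_equal(as.numeric(g[2] - g[1]), 80)
  expect_equal(as.numeric(g[1]), 400)
  expect_equal(as.numeric(g[length(g)]), 960)
  expect_equal(diff(make_wavelength_grid(400, 960, 401))[1], 1.4)
  expect_error(make_wavelength_grid(500, 400, 100), "less than")
  expect_error(make_wavelength_grid(400, 960, 7), "at least 8")
})

test_that("default kinetics reproduce the printed endpoint decreases", {
  chem <- fx_chem()
  expect_equal(percent_decrease(fx_mean_series(chem, "ec")), 96.28,
               tolerance = 1e-9)
  expect_equal(percent_decrease(fx_mean_series(chem, "egc")), 4.5,
               tolerance = 1e-9)
  others <- c("total", "c", "ec", "egcg", "ecg")
  decs <- vapply(others, function(cc) percent_decrease(fx_mean_series(chem, cc)),
                 numeric(1))
  expect_true(all(decs > 72.06))
})

test_that("contents follow the closed-form decay model", {
  p <- kinetic_params()
  chem <- simulate_kinetics(p)
  # recompute one cell by hand: EC, lower layer, t = 3 h
  f <- p$reactive_fraction[["ec"]]; d <- p$decrease[["ec"]]
  mods <- p$layer_modifiers
  i5 <- mods[, "fast"] * 2 + mods[, "slow"] * 3
  k <- uniroot(function(k) mean(exp(-k * i5)) - (f - d) / f, c(0, 10),
               tol = 1e-14)$root
  it <- mods["lower", "fast"] * 2 + mods["lower", "slow"] * 1
  manual <- p$c0[["ec"]] * ((1 - f) + f * exp(-k * it))
  got <- chem$ec[chem$time_h == 3 & chem$layer == "lower"]
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("kinetics are non-increasing with a faster 0-2 h phase", {
  chem <- fx_chem()
  for (cc in catechin_components()) {
    for (l in c("upper", "middle", "lower")) {
      v <- chem[[cc]][chem$layer == l][order(chem$time_h[chem$layer == l])]
      expect_true(all(diff(v) <= 1e-12))
    }
    m <- fx_mean_series(chem, cc)
    expect_gt(m[1] - m[3], m[3] - m[6])  # 0-2 h drop beats 2-5 h drop
  }
})

test_that("zero decrease gives a constant series and bad fractions error", {
  d0 <- c(total = 0, egc = 0, c = 0, ec = 0, egcg = 0, ecg = 0)
  chem <- simulate_kinetics(kinetic_params(decrease = d0))
  expect_equal(diff(range(chem$ec)), 0)
  bad <- c(total = 0.78, egc = 0.045, c = 0.85, ec = 1.0, egcg = 0.8,
           ecg = 0.75)
  expect_error(kinetic_params(decrease = bad), "\\[0, 1\\)")
  expect_error(kinetic_params(times = 1:4), "0 and 5")
})

test_that("layer contrast switches from middle (2 h) to lower (3-5 h)", {
  lc <- layer_contrast(fx_chem())
  top_at <- function(t, cc) {
    lc$top$top_layer[lc$top$time_h == t & lc$top$component == cc]
  }
  for (cc in catechin_components()) {
    expect_equal(top_at(2, cc), "middle")
    for (t in 3:5) expect_equal(top_at(t, cc), "lower")
  }
})

test_that("chemistry table keeps totals consistent with the monomers", {
  chem <- fx_chem()
  monomers <- c("egc", "c", "ec", "egcg", "ecg")
  expect_true(all(as.matrix(chem[monomers]) >= 0))
  for (m in monomers) expect_true(all(chem$total >= chem[[m]]))
  ratio <- rowSums(chem[monomers]) / chem$total
  expect_true(all(ratio > 0.9 & ratio < 1.1))
})
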