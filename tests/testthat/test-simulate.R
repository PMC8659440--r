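test_that("absorbance forward model is linear in contents (noise off)", {
  lib <- fx_lib_small()
  a1 <- teaspec:::forward_absorbance(list(ec = 1), lib)
  a2 <- teaspec:::forward_absorbance(list(ec = 2), lib)
  expect_equal(a2, 2 * a1)
  ab <- teaspec:::forward_absorbance(list(ec = 1, egcg = 2), lib)
  expect_equal(ab, a1 + teaspec:::forward_absorbance(list(egcg = 2), lib))
  expect_error(teaspec:::forward_absorbance(list(nope = 1), lib), "missing")
})

test_that("spectra simulation is seed-deterministic and correctly sized", {
  chem <- fx_chem()
  lib <- fx_lib_small()
  s1 <- simulate_spectra(chem, lib, noise_model(seed = 7), replicates = 10)
  s2 <- simulate_spectra(chem, lib, noise_model(seed = 7), replicates = 10)
  expect_identical(s1$values, s2$values)
  expect_equal(nrow(s1$values), 180)  # 6 times x 3 layers x 10 replicates
  expect_equal(nrow(simulate_spectra(chem, lib, noise_model(seed = 7),
                                     replicates = 9)$values), 162)
  expect_true(all(s1$values > 0 & s1$values <= 1.5))
  s3 <- simulate_spectra(chem, lib, noise_model(seed = 8), replicates = 10)
  expect_false(identical(s1$values, s3$values))
})

test_that("noise-off replicates of one sample are identical spectra", {
  chem <- fx_chem()[1, ]
  s <- simulate_spectra(chem, fx_lib_small(), noise_off(), replicates = 4)
  expect_equal(max(apply(s$values, 2, function(col) diff(range(col)))), 0)
})

test_that("cube simulation honors dimensions, mask and ground truth", {
  chem <- fx_chem()
  lib <- fx_lib_small(12)
  sim <- simulate_cube(chem[8, ], lib, noise_off(), height = 24, width = 30,
                       jitter_sd = 0, time_jitter_sd = 0)
  expect_equal(dim(sim$cube$values)[1:2], c(24, 30))
  # background truth exactly zero, tea truth equals the sample contents
  for (cc in dimnames(sim$truth)[[3]]) {
    tr <- sim$truth[, , cc]
    expect_true(all(tr[!sim$mask] == 0))
    expect_equal(unique(tr[sim$mask]), chem[[cc]][8])
  }
  # zero jitter + zero noise: all tea pixels share one spectrum
  flat <- matrix(sim$cube$values, ncol = length(lib$grid))
  tea <- flat[which(sim$mask), ]
  expect_equal(max(apply(tea, 2, function(v) diff(range(v)))), 0)
  # the full-size ROI request of the imaging protocol
  sim200 <- simulate_cube(chem[8, ], component_library(fx_grid_small(8)),
                          noise_off(), height = 200, width = 200,
                          jitter_sd = 0, time_jitter_sd = 0)
  expect_equal(dim(sim200$cube$values)[1:2], c(200, 200))
  expect_error(simulate_cube(chem[8, ], lib, noise_off(), height = 8,
                             width = 8), ">= 16")
  expect_error(
    simulate_cube(chem[8, ], lib, noise_off(), height = 20, width = 20,
                  tea_mask_shape = list(shape = "rect", height = 30,
                                        width = 10)),
    "larger than the frame")
})

test_that("trajectory jitter keeps truth on the kinetic covariance", {
  chem <- fx_chem()
  kp <- kinetic_params()
  sim <- simulate_cube(chem[8, ], fx_lib_small(12), noise_off(), 20, 20,
                       jitter_sd = 0, params = kp, time_jitter_sd = 0.3)
  tea_ec <- sim$truth[, , "ec"][sim$mask]
  tea_total <- sim$truth[, , "total"][sim$mask]
  expect_gt(stats::sd(tea_ec), 0)          # pixels do vary
  expect_gt(stats::cor(tea_ec, tea_total), 0.99)  # and co-vary kinetically
})
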