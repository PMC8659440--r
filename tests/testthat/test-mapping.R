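test_that("ROI spectra are pixel means plus a grand-mean sample spectrum", {
  two <- fx_two_level_cube()
  roi <- extract_roi_spectra(two$cube, cbind(c(8, 10, 12), c(8, 10, 12)), 3)
  expect_equal(nrow(roi$values), 4)
  # uniform tea region: every ROI spectrum equals the pixel spectrum
  expect_equal(unname(roi$values[1, ]), rep(0.4, 8))
  expect_equal(roi$values[4, ], colMeans(roi$values[1:3, ]), tolerance = 1e-12)
  # the acquisition protocol's 10 symmetric ROIs give 10 + 1 spectra
  centers <- cbind(rep(c(7, 9, 11, 13, 10), 2), c(7, 9, 11, 13, 10,
                                                  13, 11, 9, 7, 10))
  roi10 <- extract_roi_spectra(two$cube, centers, 3)
  expect_equal(nrow(roi10$values), 11)
  expect_equal(sum(roi10$meta$kind == "roi"), 10)
  expect_error(extract_roi_spectra(two$cube, cbind(1, 1), 5), "ROI 1")
})

test_that("Otsu masking recovers the exact tea region on a two-level cube", {
  two <- fx_two_level_cube()
  m <- background_mask(two$cube)
  expect_identical(m, two$mask)
  # partition property
  expect_true(all(xor(m, !m)))
  # all-background cube: empty mask with a warning
  flat <- hyper_cube(array(0.9, dim = c(20, 20, 8)), fx_grid_small(8))
  expect_warning(me <- background_mask(flat, contrast_band = 4), "unimodal")
  expect_false(any(me))
})

test_that("pixel maps agree with sample predictions and zero the background", {
  chem <- fx_chem()
  lib <- fx_lib_small(30)
  grid <- as.numeric(lib$grid)
  sp <- simulate_spectra(chem, lib, noise_model(seed = 5), replicates = 6)
  y <- chem$ec[match(sp$meta$sample_id, chem$sample_id)]
  split <- kennard_stone(-log10(sp$values), 0.75)
  cal <- split$calibration
  fitted <- fit_preproc_chain(sp$values[cal, ], c("absorbance", "snv"))
  sel <- selection_result("manual", 1:30, grid, fitness = NA_real_)
  red <- pca_reduce(fitted$cal, fitted$cal, sel$indices, 8)
  model <- pls_train(red$cal_scores, y[cal], 8)

  kp <- kinetic_params()
  sim <- simulate_cube(chem[8, ], lib, noise_model(seed = 11), 24, 24,
                       jitter_sd = 0.01, params = kp)
  pm <- predict_map(sim$cube, sim$mask, fitted$chain, sel, red$model, model,
                    component = "ec")
  expect_true(all(pm$values[!sim$mask] == 0))
  expect_equal(dim(pm$values), dim(sim$mask))
  # pixel/sample consistency: a pixel spectrum predicted directly equals its
  # map entry
  px <- which(sim$mask)[5]
  spec <- matrix(matrix(sim$cube$values, ncol = 30)[px, ], nrow = 1)
  direct <- predict(model,
                    teaspec:::project_pca(red$model,
                                          apply_preproc_chain(spec,
                                                              fitted$chain)))
  expect_equal(unname(pm$values[px]), unname(max(direct, 0)),
               tolerance = 1e-9)
  # noise-free uniform cube: every tea pixel recovers the known content
  sim0 <- simulate_cube(chem[8, ], lib, noise_off(), 24, 24, jitter_sd = 0,
                        time_jitter_sd = 0)
  pm0 <- predict_map(sim0$cube, sim0$mask, fitted$chain, sel, red$model,
                     model)
  tea0 <- pm0$values[sim0$mask]
  expect_lt(max(abs(tea0 - chem$ec[8])), 0.15)  # model tolerance
  expect_equal(diff(range(tea0)), 0)
  # grid mismatch is refused
  off <- sim$cube; off$grid <- structure(grid + 5, class = "wavelength_grid")
  expect_error(predict_map(off, sim$mask, fitted$chain, sel, red$model,
                           model), "grid")
  # nonzero-map conservation: nonzero entries = mask popcount
  if (all(pm$values[sim$mask] > 0)) {
    expect_equal(sum(pm$values != 0), sum(sim$mask))
  }
})

test_that("map rendering is deterministic with correct geometry", {
  vals <- matrix(0, 12, 15)
  mask <- matrix(FALSE, 12, 15); mask[3:9, 4:12] <- TRUE
  vals[mask] <- seq_len(sum(mask)) / sum(mask)
  pm <- structure(list(values = vals, mask = mask, component = "ec",
                       n_clipped = 0L), class = "pixel_map")
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_map(pm, p1); render_map(pm, p2)
  img <- png::readPNG(p1)
  expect_equal(dim(img)[1:2], c(12, 15))
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # constant map: one tea color
  vals2 <- vals; vals2[mask] <- 0.7
  pm2 <- structure(list(values = vals2, mask = mask, component = "ec",
                        n_clipped = 0L), class = "pixel_map")
  p3 <- withr::local_tempfile(fileext = ".png")
  render_map(pm2, p3)
  img3 <- png::readPNG(p3)
  rgb_tea <- apply(img3, 3, function(ch) unique(ch[mask]))
  expect_equal(lengths(rgb_tea), c(1, 1, 1), ignore_attr = TRUE)
})

test_that("file formats round-trip: ENVI, chemistry CSV, spectra CSV, JSON", {
  two <- fx_two_level_cube()
  for (il in c("bsq", "bil")) {
    base <- withr::local_tempfile()
    write_envi(two$cube, base, il)
    back <- read_envi(paste0(base, ".hdr"))
    expect_equal(back$values, two$cube$values, tolerance = 1e-6)
    expect_equal(as.numeric(back$grid), as.numeric(two$cube$grid),
                 tolerance = 1e-6)
  }
  chem <- fx_chem()
  p <- withr::local_tempfile(fileext = ".csv")
  write_chem_csv(chem, p)
  expect_equal(as.data.frame(read_chem_csv(p)), as.data.frame(chem),
               tolerance = 1e-12)
  sp <- simulate_spectra(chem[1:2, ], fx_lib_small(10), noise_off(),
                         replicates = 2)
  ps <- withr::local_tempfile(fileext = ".csv")
  pw <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(sp, ps, pw)
  back <- read_spectra_csv(ps, pw)
  expect_equal(unname(back$values), unname(sp$values), tolerance = 1e-12)
  expect_equal(as.numeric(back$grid), as.numeric(sp$grid))
  sel <- selection_result("SPA", c(3, 7, 9), as.numeric(fx_grid_small(10)),
                          fitness = 0.12, fitness_trace = c(0.3, 0.12))
  pj <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sel, pj)
  sel2 <- read_selection_json(pj, as.numeric(fx_grid_small(10)))
  expect_equal(sel2$indices, sel$indices)
  expect_equal(sel2$selected_nm, sel$selected_nm)
  expect_equal(sel2$fitness, sel$fitness)
})
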