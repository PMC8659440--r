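# Shared fixtures, built in code at test time.

# small grid + library for fast spectral tests
fx_grid_small <- function(n_bands = 40) make_wavelength_grid(400, 960, n_bands)

fx_lib_small <- function(n_bands = 40) component_library(fx_grid_small(n_bands))

fx_chem <- function() simulate_kinetics(kinetic_params())

# layer-mean time series for one component
fx_mean_series <- function(chem, component) {
  chem |>
    dplyr::group_by(time_h) |>
    dplyr::summarise(v = mean(.data[[component]]), .groups = "drop") |>
    dplyr::arrange(time_h) |>
    dplyr::pull(v)
}

# planted-signal regression fixture: smooth-ish random spectra with three
# high-variance informative bands driving y
fx_planted <- function(seed, n = 150, p = 200,
                       bands = round(p * c(0.2, 0.55, 0.85)),
                       noise_sd = 0.05) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    X <- t(apply(X, 1, function(r) {
      stats::filter(c(r[1], r, r[p]), rep(1 / 3, 3))[2:(p + 1)]
    }))
    X[, bands] <- 3 * X[, bands]
    y <- X[, bands[1]] - 0.8 * X[, bands[2]] + 0.6 * X[, bands[3]] +
      stats::rnorm(n, sd = noise_sd)
    list(X = X, y = y, bands = bands)
  })
}

# independent greedy max-min oracle for Kennard-Stone, plain distance loops
ks_oracle <- function(X, n_cal) {
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  best <- c(NA, NA); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] > bestd) { bestd <- d[i, j]; best <- c(i, j) }
  }
  picks <- best
  while (length(picks) < n_cal) {
    cand <- setdiff(seq_len(n), picks)
    md <- vapply(cand, function(i) min(d[i, picks]), numeric(1))
    picks <- c(picks, cand[which.max(md)])
  }
  picks
}

# uniform small hypercube with a rectangular tea patch of constant reflectance
fx_two_level_cube <- function(n_bands = 8, h = 20, w = 20,
                              tea = 0.4, bg = 0.9) {
  grid <- fx_grid_small(n_bands)
  arr <- array(bg, dim = c(h, w, n_bands))
  mask <- matrix(FALSE, h, w)
  mask[6:15, 6:15] <- TRUE
  for (b in seq_len(n_bands)) {
    plane <- arr[, , b]
    plane[mask] <- tea
    arr[, , b] <- plane
  }
  list(cube = hyper_cube(arr, grid), mask = mask)
}
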