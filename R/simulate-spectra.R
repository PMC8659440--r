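# Beer-Lambert forward model: contents (% dry mass) -> absorbance -> reflectance.

# optional saturation nonlinearity in the content-absorbance link
saturate_absorbance <- function(a, cap = 1.2) cap * (1 - exp(-a / cap))

forward_absorbance <- function(contents, lib, nonlinear = FALSE) {
  comps <- names(contents)
  missing <- setdiff(comps, colnames(lib$profiles))
  if (length(missing) > 0) {
    stop("components missing from library: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  a <- as.vector(lib$profiles[, comps, drop = FALSE] %*% unlist(contents))
  if (nonlinear) a <- saturate_absorbance(a) else a
}

# smooth per-spectrum baseline drift in absorbance units
random_baseline <- function(n_bands, amplitude) {
  if (amplitude <= 0) return(rep(0, n_bands))
  x <- seq(-1, 1, length.out = n_bands)
  co <- stats::rnorm(3, sd = c(1, 0.7, 0.4))
  amplitude * (co[1] + co[2] * x + co[3] * (2 * x^2 - 1)) / 2
}

pathlength_factor <- function(noise) {
  if (noise$pathlength_sd <= 0) return(1)
  max(0.1, 1 + stats::rnorm(1, sd = noise$pathlength_sd))
}

distort_reflectance <- function(r, noise) {
  slope <- 1 + stats::rnorm(1, sd = noise$scatter_slope_sd)
  offset <- stats::rnorm(1, sd = noise$scatter_offset_sd)
  r <- slope * r + offset
  r <- r + stats::rnorm(length(r), sd = noise$additive_sd)
  pmin(pmax(r, 1e-6), 1.5)
}

#' Simulate replicate reflectance spectra for a chemistry table
#'
#' Forward model: absorbance is the content-weighted sum of the library
#' profiles plus a random baseline drift; reflectance is `10^(-A)`, distorted
#' per spectrum by multiplicative scatter and additive noise, clipped to
#' (0, 1.5]. With the default chemistry (6 time points x 3 layers) and 10
#' replicates this yields the standard 180-spectrum data set; 9 replicates
#' yield the alternative 162-sample count.
#'
#' @param chem chemistry tibble from [simulate_kinetics()] (or with the same
#'   columns).
#' @param lib a [component_library()]; must cover every content column of
#'   `chem`.
#' @param noise a [noise_model()].
#' @param replicates spectra per chemistry row (>= 1).
#' @param nonlinear apply a saturating content-absorbance link (used to study
#'   nonlinear-model advantages); default off.
#' @return a `spectra_set` of reflectance spectra with metadata columns
#'   spectrum_id, sample_id, time_h, layer, replicate.
#' @export
simulate_spectra <- function(chem, lib = component_library(),
                             noise = noise_model(), replicates = 10,
                             nonlinear = FALSE) {
  stopifnot(inherits(lib, "component_library"), inherits(noise, "noise_model"))
  if (replicates < 1) stop("`replicates` must be >= 1.", call. = FALSE)
  chem <- tibble::as_tibble(chem)
  comps <- intersect(catechin_components(), names(chem))
  if (length(comps) == 0) stop("`chem` has no content columns.", call. = FALSE)

  withr::with_seed(noise$seed, {
    rows <- tidyr::expand_grid(row = seq_len(nrow(chem)),
                               replicate = seq_len(replicates))
    values <- matrix(0, nrow(rows), length(lib$grid))
    for (i in seq_len(nrow(rows))) {
      ch <- chem[rows$row[i], comps]
      a <- forward_absorbance(as.list(ch), lib, nonlinear = nonlinear) +
        random_baseline(length(lib$grid), noise$drift_amplitude)
      a <- a * pathlength_factor(noise)
      values[i, ] <- distort_reflectance(10^(-a), noise)
    }
    meta <- tibble::tibble(
      spectrum_id = sprintf("%s_r%02d", chem$sample_id[rows$row], rows$replicate),
      sample_id = chem$sample_id[rows$row],
      time_h = chem$time_h[rows$row],
      layer = chem$layer[rows$row],
      replicate = rows$replicate
    )
    spectra_set(values, lib$grid, meta, quantity = "reflectance")
  })
}

#' Simulate a hyperspectral cube with a tea region on a distinct background
#'
#' Tea pixels carry forward-model spectra for one chemistry row with mild
#' per-pixel content jitter; background pixels carry a spectrally flat bright
#' profile. The per-pixel ground-truth content map (background exactly 0) is
#' returned alongside.
#'
#' @param chem_row single-row chemistry tibble.
#' @param lib a [component_library()].
#' @param noise a [noise_model()].
#' @param height,width spatial dimensions in pixels (>= 16).
#' @param tea_mask_shape `"disc"` or a list `list(shape = "rect", height =, width =)`
#'   giving the tea rectangle size (must fit the frame).
#' @param jitter_sd relative per-pixel independent content jitter sd
#'   (0 = uniform tea, together with `time_jitter_sd = 0`).
#' @param params optional [kinetic_params()]: when given (and `chem_row` has
#'   `time_h`/`layer`), each pixel's contents are drawn from the kinetic
#'   trajectory at a normally perturbed local fermentation time
#'   (`time_jitter_sd` hours), so pixel-to-pixel variation co-varies across
#'   components the way fermentation chemistry does; the independent jitter is
#'   applied on top.
#' @param time_jitter_sd per-pixel fermentation-time jitter sd in hours
#'   (used only with `params`).
#' @param background_level background reflectance (flat), default 0.9.
#' @param nonlinear see [simulate_spectra()].
#' @return list with `cube` (a `hyper_cube`), `truth` (height x width x
#'   components array, background 0) and `mask` (logical tea mask).
#' @export
simulate_cube <- function(chem_row, lib = component_library(),
                          noise = noise_model(), height = 64, width = 64,
                          tea_mask_shape = "disc", jitter_sd = 0.02,
                          params = NULL, time_jitter_sd = 0.3,
                          background_level = 0.9, nonlinear = FALSE) {
  if (height < 16 || width < 16) {
    stop("`height` and `width` must be >= 16.", call. = FALSE)
  }
  chem_row <- tibble::as_tibble(chem_row)
  stopifnot(nrow(chem_row) == 1)
  comps <- intersect(catechin_components(), names(chem_row))

  mask <- make_tea_mask(height, width, tea_mask_shape)
  n_bands <- length(lib$grid)
  contents0 <- unlist(chem_row[, comps])

  withr::with_seed(noise$seed, {
    cube <- array(0, dim = c(height, width, n_bands))
    truth <- array(0, dim = c(height, width, length(comps)),
                   dimnames = list(NULL, NULL, comps))
    idx <- which(mask, arr.ind = TRUE)
    use_traj <- !is.null(params) &&
      all(c("time_h", "layer") %in% names(chem_row))
    if (use_traj && time_jitter_sd > 0) {
      t_pix <- pmax(0, chem_row$time_h +
                      stats::rnorm(nrow(idx), sd = time_jitter_sd))
      traj <- kinetic_content(params, t_pix,
                              rep(chem_row$layer, nrow(idx)))[, comps,
                                                             drop = FALSE]
    }
    for (j in seq_len(nrow(idx))) {
      base <- if (use_traj && time_jitter_sd > 0) traj[j, ] else contents0
      jit <- if (jitter_sd > 0) {
        pmax(0, 1 + stats::rnorm(length(comps), sd = jitter_sd))
      } else rep(1, length(comps))
      contents <- base * jit
      a <- forward_absorbance(as.list(contents), lib, nonlinear = nonlinear) +
        random_baseline(n_bands, noise$drift_amplitude)
      a <- a * pathlength_factor(noise)
      cube[idx[j, 1], idx[j, 2], ] <- distort_reflectance(10^(-a), noise)
      truth[idx[j, 1], idx[j, 2], ] <- contents
    }
    bg <- which(!mask, arr.ind = TRUE)
    for (j in seq_len(nrow(bg))) {
      r <- rep(background_level, n_bands)
      cube[bg[j, 1], bg[j, 2], ] <- distort_reflectance(r, noise)
    }
    list(cube = hyper_cube(cube, lib$grid), truth = truth, mask = mask)
  })
}

make_tea_mask <- function(height, width, shape) {
  if (identical(shape, "disc")) {
    r <- 0.35 * min(height, width)
    cy <- (height + 1) / 2; cx <- (width + 1) / 2
    outer(seq_len(height), seq_len(width),
          function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
  } else if (is.list(shape) && identical(shape$shape, "rect")) {
    if (shape$height > height || shape$width > width) {
      stop("tea mask is larger than the frame.", call. = FALSE)
    }
    m <- matrix(FALSE, height, width)
    i0 <- floor((height - shape$height) / 2) + 1
    j0 <- floor((width - shape$width) / 2) + 1
    m[i0:(i0 + shape$height - 1), j0:(j0 + shape$width - 1)] <- TRUE
    m
  } else {
    stop("unknown `tea_mask_shape`.", call. = FALSE)
  }
}

#' Construct a hyperspectral cube
#'
#' @param values height x width x bands array of finite reflectance values.
#' @param grid `wavelength_grid` matching the third dimension.
#' @return object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, grid) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  assert_grid(grid)
  if (dim(values)[3] != length(grid)) {
    stop("third cube dimension must match the grid.", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("cube values must be finite.", call. = FALSE)
  structure(list(values = values, grid = grid), class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %d x %d pixels x %d bands, %.6g-%.6g nm\n",
              d[1], d[2], d[3], min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)
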