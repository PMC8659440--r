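#' Pure-component absorptivity library
#'
#' Beer-Lambert forward model basis: each catechin component contributes a
#' non-negative absorptivity profile (a mixture of Gaussian peaks) per unit
#' content (% dry mass). Default peaks sit inside 406-957 nm so informative
#' bands fall within the selection span.
#'
#' @param grid a `wavelength_grid`.
#' @param peaks named list (one entry per component) of data frames with
#'   columns `center` (nm), `width` (nm, Gaussian sd), `height` (absorbance per
#'   unit % content). Defaults cover all six components with distinct peaks.
#' @return object of class `component_library` with a bands x components
#'   `profiles` matrix.
#' @export
component_library <- function(grid = default_grid(), peaks = default_peaks()) {
  assert_grid(grid)
  comps <- names(peaks)
  if (length(comps) == 0) stop("`peaks` must be a named list.", call. = FALSE)
  profiles <- vapply(peaks, function(pk) {
    pk <- as.data.frame(pk)
    stopifnot(all(c("center", "width", "height") %in% names(pk)))
    if (any(pk$height < 0) || any(pk$width <= 0)) {
      stop("peak heights must be >= 0 and widths > 0.", call. = FALSE)
    }
    if (!any(pk$center >= min(grid) & pk$center <= max(grid))) {
      stop("every component needs at least one peak inside the grid span.",
           call. = FALSE)
    }
    rowSums(vapply(seq_len(nrow(pk)), function(i) {
      pk$height[i] * exp(-0.5 * ((as.numeric(grid) - pk$center[i]) / pk$width[i])^2)
    }, numeric(length(grid))))
  }, numeric(length(grid)))
  colnames(profiles) <- comps
  structure(list(grid = grid, profiles = profiles, peaks = peaks),
            class = "component_library")
}

#' @rdname component_library
#' @export
default_peaks <- function() {
  list(
    total = data.frame(center = 700, width = 120, height = 0.004),
    egc   = data.frame(center = c(450, 840), width = c(30, 40),
                       height = c(0.050, 0.040)),
    c     = data.frame(center = c(520, 905), width = c(25, 35),
                       height = c(0.060, 0.050)),
    ec    = data.frame(center = c(610, 740), width = c(30, 30),
                       height = c(0.050, 0.035)),
    egcg  = data.frame(center = c(480, 660), width = c(40, 35),
                       height = c(0.020, 0.025)),
    ecg   = data.frame(center = c(560, 870), width = c(30, 45),
                       height = c(0.012, 0.015))
  )
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library> %d components on %d bands: %s\n",
              ncol(x$profiles), nrow(x$profiles),
              paste(colnames(x$profiles), collapse = ", ")))
  invisible(x)
}

#' Spectral noise model
#'
#' Instrument and sample-presentation artifacts applied by the forward model:
#' additive Gaussian noise and per-spectrum multiplicative scatter (slope and
#' offset) on reflectance, plus a smooth random baseline drift added in
#' absorbance. The same seed always reproduces the same spectra.
#'
#' @param additive_sd Gaussian noise sd (reflectance units).
#' @param scatter_slope_sd per-spectrum multiplicative slope sd (around 1).
#' @param scatter_offset_sd per-spectrum additive offset sd (reflectance units).
#' @param drift_amplitude baseline drift amplitude (absorbance units).
#' @param pathlength_sd per-spectrum optical path-length factor sd (around 1):
#'   an uneven sample surface scales the whole absorbance multiplicatively
#'   (R' = R^l), the artifact SNV/MSC are designed to remove.
#' @param seed integer RNG seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.002, scatter_slope_sd = 0.02,
                        scatter_offset_sd = 0.005, drift_amplitude = 0.02,
                        pathlength_sd = 0.03, seed = 42L) {
  vals <- c(additive_sd, scatter_slope_sd, scatter_offset_sd, drift_amplitude,
            pathlength_sd)
  if (any(vals < 0)) stop("noise standard deviations must be >= 0.", call. = FALSE)
  structure(list(additive_sd = additive_sd,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 drift_amplitude = drift_amplitude,
                 pathlength_sd = pathlength_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
noise_off <- function(seed = 42L) {
  noise_model(0, 0, 0, 0, 0, seed = seed)
}
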