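#' Build a uniform wavelength grid
#'
#' Band centers shared by spectra and hypercubes. The default working grid in
#' this package spans 400-960 nm with 401 bands (1.4 nm spacing), a desk-scale
#' stand-in for instrument-resolution sampling that keeps the visible/NIR span
#' used for characteristic-wavelength selection.
#'
#' @param start_nm,end_nm span endpoints in nm (inclusive), `start_nm < end_nm`.
#' @param n_bands number of bands, at least 8.
#' @return a numeric vector of class `wavelength_grid`, strictly increasing and
#'   uniformly spaced.
#' @examples
#' make_wavelength_grid(400, 960, 8)
#' @export
make_wavelength_grid <- function(start_nm, end_nm, n_bands) {
  if (!is.numeric(start_nm) || !is.numeric(end_nm) || start_nm >= end_nm) {
    stop("`start_nm` must be strictly less than `end_nm`.", call. = FALSE)
  }
  if (n_bands < 8) {
    stop("`n_bands` must be at least 8.", call. = FALSE)
  }
  grid <- seq(start_nm, end_nm, length.out = n_bands)
  structure(grid, class = "wavelength_grid")
}

#' Default 400-960 nm, 401-band grid
#' @return a `wavelength_grid`
#' @export
default_grid <- function() make_wavelength_grid(400, 960, 401)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d bands, %.6g-%.6g nm, spacing %.6g nm\n",
    length(x), x[1], x[length(x)], x[2] - x[1]
  ))
  invisible(x)
}

grid_spacing <- function(grid) as.numeric(grid[2] - grid[1])

assert_grid <- function(grid) {
  stopifnot(is.numeric(grid), length(grid) >= 8)
  d <- diff(grid)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-9) {
    stop("wavelength grid must be strictly increasing and uniform.", call. = FALSE)
  }
  invisible(grid)
}
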