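# Spectral pretreatments. All operate row-wise or with calibration-anchored
# column statistics, preserve the sample x band shape, and return spectra_set
# objects tagged "preprocessed" (calibrate_reflectance returns reflectance).

values_of <- function(x) if (inherits(x, "spectra_set")) x$values else as.matrix(x)

#' Black/white reference calibration to reflectance
#'
#' R = (raw - dark) / (white - dark), elementwise. `dark` and `white` may be
#' per-band vectors or matrices conformable with `raw`.
#'
#' @param raw `spectra_set` or matrix of raw intensities.
#' @param dark,white dark- and white-reference intensities (vector per band or
#'   matrix); must satisfy `white > dark` at every band.
#' @return reflectance with the shape of `raw` (a `spectra_set` if `raw` was).
#' @export
calibrate_reflectance <- function(raw, dark, white) {
  rawm <- values_of(raw)
  expand <- function(v) if (is.matrix(v)) v else matrix(v, nrow(rawm), ncol(rawm), byrow = TRUE)
  darkm <- expand(dark); whitem <- expand(white)
  denom <- whitem - darkm
  if (any(denom <= 0)) {
    stop("white reference must exceed dark reference at every band.", call. = FALSE)
  }
  out <- (rawm - darkm) / denom
  if (inherits(raw, "spectra_set")) {
    spectra_set(out, raw$grid, raw$meta, quantity = "reflectance")
  } else out
}

#' Standard normal variate (SNV)
#'
#' Each spectrum is centered and scaled to unit standard deviation (divisor
#' n - 1), removing per-spectrum multiplicative scatter. Idempotent.
#'
#' @param set a `spectra_set` (or matrix).
#' @return transformed set.
#' @export
snv <- function(set) {
  x <- values_of(set)
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  bad <- which(sd <= 0 | !is.finite(sd))
  if (length(bad) > 0) {
    stop("constant (degenerate) spectrum in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- (x - mu) / sd
  if (inherits(set, "spectra_set")) set_values(set, out) else out
}

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum x is regressed on a reference spectrum (x = a * ref + b, least
#' squares) and corrected to (x - b) / a. The reference defaults to the mean
#' spectrum of the input, which should be the calibration set when correcting
#' prediction spectra (pass the stored calibration reference).
#'
#' @param set a `spectra_set` (or matrix).
#' @param reference numeric reference spectrum; default column means of `set`.
#' @return transformed set with the reference stored in attribute
#'   `"msc_reference"`.
#' @export
msc <- function(set, reference = NULL) {
  x <- values_of(set)
  if (is.null(reference)) reference <- colMeans(x)
  stopifnot(length(reference) == ncol(x))
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  a <- as.vector((x - rowMeans(x)) %*% rc) / denom
  if (any(abs(a) < 1e-12)) {
    stop("degenerate MSC fit (slope ~ 0) in row(s): ",
         paste(which(abs(a) < 1e-12), collapse = ", "), call. = FALSE)
  }
  b <- rowMeans(x) - a * mean(reference)
  out <- (x - b) / a
  res <- if (inherits(set, "spectra_set")) set_values(set, out) else out
  attr(res, "msc_reference") <- reference
  res
}

#' Savitzky-Golay second derivative
#'
#' Second derivative per spectrum with respect to band index, computed with a
#' Savitzky-Golay polynomial filter. The output has the same width as the
#' input: edge values come from the filter's one-sided polynomial fits, so
#' band indices stay aligned with the wavelength grid.
#'
#' @param set a `spectra_set` (or matrix).
#' @param window odd filter length (> `polyorder`), default 7.
#' @param polyorder polynomial order (>= 2), default 2.
#' @return transformed set.
#' @export
second_derivative <- function(set, window = 7, polyorder = 2) {
  x <- values_of(set)
  if (window %% 2 == 0) stop("`window` must be odd.", call. = FALSE)
  if (polyorder < 2 || window <= polyorder) {
    stop("need `window` > `polyorder` >= 2.", call. = FALSE)
  }
  if (ncol(x) < window) stop("fewer bands than `window`.", call. = FALSE)
  out <- t(apply(x, 1, function(row) {
    signal::sgolayfilt(row, p = polyorder, n = window, m = 2, ts = 1)
  }))
  if (inherits(set, "spectra_set")) set_values(set, out) else out
}

#' Moving-average smoothing
#'
#' Centered moving average per spectrum; edge positions use symmetrically
#' shrunken windows so no bands are dropped.
#'
#' @param set a `spectra_set` (or matrix).
#' @param window odd window length >= 3 and <= number of bands.
#' @return transformed set.
#' @export
smooth_spectra <- function(set, window = 5) {
  x <- values_of(set)
  if (window %% 2 == 0 || window < 3) stop("`window` must be odd >= 3.", call. = FALSE)
  if (window > ncol(x)) stop("`window` exceeds the number of bands.", call. = FALSE)
  h <- (window - 1) / 2
  p <- ncol(x)
  out <- vapply(seq_len(p), function(j) {
    hw <- min(h, j - 1, p - j)  # shrink symmetrically at the edges
    rowMeans(x[, (j - hw):(j + hw), drop = FALSE])
  }, numeric(nrow(x)))
  out <- matrix(out, nrow(x), p)
  if (inherits(set, "spectra_set")) set_values(set, out) else out
}

#' Column-wise standardization with calibration-anchored statistics
#'
#' Center, z-score or min-max scaling per wavelength. Statistics are learned
#' on the calibration rows only and applied to both sets, preventing
#' information leakage from the prediction set; the returned stats carry a
#' provenance tag asserting this.
#'
#' @param cal_set,pred_set `spectra_set`s (or matrices) sharing bands.
#' @param mode "center", "zscore" or "minmax".
#' @return list with elements `cal`, `pred` and `stats` (class
#'   `preproc_stats`, fields mode, center/scale or min/max, provenance).
#' @export
column_standardize <- function(cal_set, pred_set,
                               mode = c("center", "zscore", "minmax")) {
  mode <- match.arg(mode)
  stats <- fit_column_stats(values_of(cal_set), mode)
  list(
    cal = apply_column_stats_set(cal_set, stats),
    pred = apply_column_stats_set(pred_set, stats),
    stats = stats
  )
}

fit_column_stats <- function(xc, mode) {
  st <- switch(mode,
    center = list(center = colMeans(xc)),
    zscore = {
      sd <- apply(xc, 2, stats::sd)
      bad <- which(sd <= 0)
      if (length(bad) > 0) {
        stop("zero-variance band(s) under zscore: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      list(center = colMeans(xc), scale = sd)
    },
    minmax = {
      mn <- apply(xc, 2, min); mx <- apply(xc, 2, max)
      bad <- which(mx <= mn)
      if (length(bad) > 0) {
        stop("min = max in band(s) under minmax: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      list(min = mn, max = mx)
    }
  )
  structure(c(list(mode = mode, provenance = "calibration"), st),
            class = "preproc_stats")
}

apply_column_stats <- function(x, stats) {
  switch(stats$mode,
    center = sweep(x, 2, stats$center),
    zscore = sweep(sweep(x, 2, stats$center), 2, stats$scale, "/"),
    minmax = sweep(sweep(x, 2, stats$min), 2, stats$max - stats$min, "/")
  )
}

apply_column_stats_set <- function(set, stats) {
  out <- apply_column_stats(values_of(set), stats)
  if (inherits(set, "spectra_set")) set_values(set, out) else out
}
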