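#' Construct a spectra set
#'
#' A samples x bands matrix with per-sample metadata and its wavelength grid.
#' `quantity` records what the values are ("reflectance", "absorbance" or
#' "preprocessed").
#'
#' @param values numeric matrix, samples x bands, finite.
#' @param grid `wavelength_grid` with `ncol(values)` bands.
#' @param meta tibble with one row per spectrum (at least a `spectrum_id`
#'   column; generator output carries sample_id, time_h, layer, replicate).
#' @param quantity one of "reflectance", "absorbance", "preprocessed".
#' @return object of class `spectra_set`.
#' @export
spectra_set <- function(values, grid, meta = NULL,
                        quantity = c("reflectance", "absorbance", "preprocessed")) {
  quantity <- match.arg(quantity)
  values <- as.matrix(values)
  assert_grid(grid)
  if (ncol(values) != length(grid)) {
    stop("`values` must have one column per grid band.", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("spectra must be finite.", call. = FALSE)
  if (is.null(meta)) {
    meta <- tibble::tibble(spectrum_id = sprintf("s%03d", seq_len(nrow(values))))
  }
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) != nrow(values)) {
    stop("`meta` must have one row per spectrum.", call. = FALSE)
  }
  structure(list(values = values, grid = grid, meta = meta, quantity = quantity),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d bands (%s), %.6g-%.6g nm\n",
              nrow(x$values), ncol(x$values), x$quantity,
              min(x$grid), max(x$grid)))
  print(utils::head(x$meta, 4))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$values)

#' Long-format view of a spectra set
#'
#' @param x a `spectra_set`.
#' @param ... unused.
#' @return tibble with metadata columns plus `wavelength_nm` and `value`.
#' @export
as_tibble.spectra_set <- function(x, ...) {
  wide <- dplyr::bind_cols(
    x$meta,
    tibble::as_tibble(x$values, .name_repair = ~ sprintf("b%04d", seq_along(.x)))
  )
  long <- tidyr::pivot_longer(wide, dplyr::matches("^b\\d{4}$"),
                              names_to = "band", values_to = "value")
  long$wavelength_nm <- as.numeric(x$grid)[as.integer(sub("^b", "", long$band))]
  dplyr::select(long, -"band")
}

#' Plot spectra colored by fermentation time
#'
#' @param object a `spectra_set`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spectra_set <- function(object, ...) {
  df <- as_tibble.spectra_set(object)
  if (!"spectrum_id" %in% names(df)) df$spectrum_id <- seq_len(nrow(df))
  colour_var <- if ("time_h" %in% names(df)) "time_h" else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$wavelength_nm, y = .data$value,
    group = .data$spectrum_id
  ))
  p <- if (is.null(colour_var)) {
    p + ggplot2::geom_line(alpha = 0.4)
  } else {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$time_h), alpha = 0.6) +
      ggplot2::scale_colour_viridis_c(name = "time (h)")
  }
  p + ggplot2::labs(x = "wavelength (nm)", y = object$quantity)
}

# replace the value matrix, tagging the result as preprocessed
set_values <- function(set, values, quantity = "preprocessed") {
  spectra_set(values, set$grid, set$meta, quantity = quantity)
}

#' Convert reflectance spectra to absorbance
#'
#' Absorbance is log10(1/R). Calibration models in this package consume
#' absorbance by default.
#'
#' @param set a `spectra_set` of reflectance values (> 0).
#' @return a `spectra_set` tagged "absorbance".
#' @export
to_absorbance <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  if (set$quantity == "absorbance") return(set)
  if (any(set$values <= 0)) {
    stop("reflectance must be > 0 to take absorbance.", call. = FALSE)
  }
  set_values(set, -log10(set$values), quantity = "absorbance")
}
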