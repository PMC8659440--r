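#' Construct a selection result
#'
#' Common return type of the wavelength selectors: the algorithm name, the
#' sorted selected band indices, their wavelengths, the achieved fitness and
#' the fitness trace across iterations.
#'
#' @param algorithm label, e.g. "SPA", "SFLA", "VCPA", "VCPA-GA", "VCPA-IRIV".
#' @param indices selected band indices (made sorted/unique).
#' @param wavelengths_nm wavelengths for the full grid the indices refer to.
#' @param fitness achieved objective value (validation or CV RMSE).
#' @param fitness_trace numeric vector, best objective per iteration.
#' @param survivors optional surviving-band pool (VCPA), indices into the grid.
#' @param n_bands total band count of the source grid.
#' @param repairs number of empty-subset repairs performed (metaheuristics).
#' @return object of class `selection_result`.
#' @export
selection_result <- function(algorithm, indices, wavelengths_nm, fitness,
                             fitness_trace = numeric(), survivors = NULL,
                             n_bands = length(wavelengths_nm), repairs = 0L) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0) stop("selection must be non-empty.", call. = FALSE)
  if (any(indices < 1) || any(indices > n_bands)) {
    stop("selected indices fall outside the grid.", call. = FALSE)
  }
  structure(
    list(algorithm = algorithm, indices = indices,
         wavelengths_nm = as.numeric(wavelengths_nm),
         selected_nm = as.numeric(wavelengths_nm)[indices],
         fitness = fitness, fitness_trace = fitness_trace,
         survivors = survivors, n_bands = n_bands, repairs = repairs,
         reduction_ratio = 1 - length(indices) / n_bands),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %s: %d / %d bands (reduction %.2f%%), fitness %.4g\n",
    x$algorithm, length(x$indices), x$n_bands, 100 * x$reduction_ratio,
    x$fitness
  ))
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(band = x$indices, wavelength_nm = x$selected_nm)
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm, n_selected = length(x$indices),
    n_bands = x$n_bands, reduction_ratio = x$reduction_ratio,
    fitness = x$fitness
  )
}

#' Plot a selection result: fitness trace and selected wavelengths
#' @param object a `selection_result`.
#' @param ... unused.
#' @export
autoplot.selection_result <- function(object, ...) {
  tr <- tibble::tibble(iteration = seq_along(object$fitness_trace),
                       fitness = object$fitness_trace)
  if (nrow(tr) == 0) {
    df <- tidy.selection_result(object)
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm)) +
             ggplot2::geom_rug() +
             ggplot2::labs(x = "selected wavelength (nm)",
                           title = object$algorithm))
  }
  ggplot2::ggplot(tr, ggplot2::aes(.data$iteration, .data$fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "best CV RMSE", title = object$algorithm)
}

#' Write / read a selection result as JSON
#' @param x a `selection_result`.
#' @param path file path.
#' @export
write_selection_json <- function(x, path) {
  jsonlite::write_json(
    list(algorithm = x$algorithm, indices = x$indices,
         wavelengths_nm = x$selected_nm, fitness = x$fitness,
         fitness_trace = x$fitness_trace, n_bands = x$n_bands),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_selection_json
#' @param grid_nm wavelengths of the full grid (needed to rebuild the result).
#' @export
read_selection_json <- function(path, grid_nm) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  selection_result(j$algorithm, j$indices, grid_nm, j$fitness,
                   fitness_trace = j$fitness_trace, n_bands = j$n_bands)
}
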