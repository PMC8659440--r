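# Fitted preprocessing chains: an ordered list of pretreatment steps with any
# calibration-anchored statistics frozen in, so the exact same transform can be
# replayed on prediction spectra and on flattened cube pixels.

#' Fit a preprocessing chain on calibration spectra
#'
#' Supported methods: "absorbance", "none", "smooth", "snv", "msc", "d2",
#' "center", "zscore", "minmax". Row-wise steps are stateless; "msc" stores the
#' calibration mean spectrum as reference and the column standardizations
#' store calibration statistics.
#'
#' @param cal_mat calibration matrix (samples x bands).
#' @param methods character vector of step names, applied in order.
#' @param window,polyorder parameters for "smooth"/"d2".
#' @return list with `chain` (class `preproc_chain`) and `cal` (transformed
#'   calibration matrix).
#' @export
fit_preproc_chain <- function(cal_mat, methods, window = 7, polyorder = 2) {
  x <- as.matrix(cal_mat)
  steps <- list()
  for (m in methods) {
    step <- switch(m,
      none = list(method = "none"),
      absorbance = list(method = "absorbance"),
      smooth = list(method = "smooth", window = 5),
      snv = list(method = "snv"),
      d2 = list(method = "d2", window = window, polyorder = polyorder),
      msc = list(method = "msc", reference = NULL),
      center = , zscore = , minmax = list(method = m, stats = NULL),
      stop("unknown pretreatment: ", m, call. = FALSE)
    )
    if (step$method == "msc") step$reference <- colMeans(x)
    if (step$method %in% c("center", "zscore", "minmax")) {
      step$stats <- fit_column_stats(x, step$method)
    }
    x <- apply_chain_step(x, step)
    steps[[length(steps) + 1]] <- step
  }
  list(chain = structure(list(steps = steps), class = "preproc_chain"), cal = x)
}

apply_chain_step <- function(x, step) {
  switch(step$method,
    none = x,
    absorbance = {
      if (any(x <= 0)) stop("reflectance must be > 0 for absorbance.", call. = FALSE)
      -log10(x)
    },
    smooth = smooth_spectra(x, window = step$window),
    snv = snv(x),
    d2 = second_derivative(x, window = step$window, polyorder = step$polyorder),
    msc = {
      out <- msc(x, reference = step$reference)
      attr(out, "msc_reference") <- NULL
      out
    },
    center = , zscore = , minmax = apply_column_stats(x, step$stats)
  )
}

#' Replay a fitted preprocessing chain
#'
#' @param mat matrix of spectra on the training grid (rows may be prediction
#'   samples or flattened cube pixels).
#' @param chain a fitted `preproc_chain`.
#' @return transformed matrix.
#' @export
apply_preproc_chain <- function(mat, chain) {
  stopifnot(inherits(chain, "preproc_chain"))
  x <- as.matrix(mat)
  for (step in chain$steps) x <- apply_chain_step(x, step)
  x
}

#' @export
print.preproc_chain <- function(x, ...) {
  cat("<preproc_chain> ",
      paste(vapply(x$steps, `[[`, "", "method"), collapse = " -> "), "\n")
  invisible(x)
}
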