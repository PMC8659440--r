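#' Kennard-Stone calibration/prediction partition
#'
#' Deterministic max-min-distance sample selection: the first two calibration
#' picks are the pair at maximal Euclidean distance; each subsequent pick
#' maximizes its minimum distance to the already-picked samples (ties resolved
#' by the smaller row index). The standard 3:1 split uses
#' `cal_fraction = 0.75` with `round(0.75 * n)` calibration samples.
#'
#' @param X samples x features matrix (or `spectra_set`).
#' @param cal_fraction calibration fraction in (0, 1).
#' @return object of class `cal_split`: list with sorted integer vectors
#'   `calibration` and `prediction`; the pick order is kept in
#'   `attr(, "pick_order")`.
#' @export
kennard_stone <- function(X, cal_fraction = 0.75) {
  X <- values_of(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples.", call. = FALSE)
  if (cal_fraction <= 0 || cal_fraction >= 1) {
    stop("`cal_fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  n_cal <- round(cal_fraction * n)
  if (n_cal < 2) n_cal <- 2
  if (n_cal >= n) {
    stop("calibration fraction leaves an empty prediction set.", call. = FALSE)
  }
  d <- as.matrix(stats::dist(X))
  # maximal-distance pair, smallest indices on ties
  far <- which(d == max(d), arr.ind = TRUE)
  far <- far[order(far[, 1], far[, 2]), , drop = FALSE]
  picks <- sort(far[1, ])
  min_d <- pmin(d[, picks[1]], d[, picks[2]])
  while (length(picks) < n_cal) {
    min_d[picks] <- -Inf
    nxt <- which.max(min_d)  # first index on ties
    picks <- c(picks, nxt)
    min_d <- pmin(min_d, d[, nxt])
  }
  out <- list(calibration = sort(picks),
              prediction = setdiff(seq_len(n), picks))
  attr(out, "pick_order") <- picks
  class(out) <- "cal_split"
  out
}

#' @export
print.cal_split <- function(x, ...) {
  cat(sprintf("<cal_split> %d calibration / %d prediction samples\n",
              length(x$calibration), length(x$prediction)))
  invisible(x)
}
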