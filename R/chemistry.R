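#' Catechin content from HPLC peak areas
#'
#' content (%) = (A * V * C) / (A1 * m * 10^3 * m1) * 100, where A and A1 are
#' the peak areas of the test liquid and the standard, V the test-liquid
#' volume (mL), C the standard concentration (mg/mL), m the dry-matter
#' *fraction* of the sample (dimensionless, in (0, 1]) and m1 the sample mass
#' (g). Linear in A; homogeneous of degree -1 in A1, m and m1.
#'
#' @param measurements data frame with columns `a`, `a1`, `v`, `c`, `m`, `m1`
#'   (one row per measurement). `a >= 0`; all other columns must be > 0.
#' @return the input as a tibble with a `content` column (% dry mass) appended.
#' @examples
#' catechin_content(data.frame(a = 10, a1 = 10, v = 10, c = 1, m = 1, m1 = 0.2))
#' @export
catechin_content <- function(measurements) {
  df <- tibble::as_tibble(measurements)
  need <- c("a", "a1", "v", "c", "m", "m1")
  if (!all(need %in% names(df))) {
    stop("`measurements` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$a < 0)) stop("peak area `a` must be >= 0.", call. = FALSE)
  pos <- c("a1", "v", "c", "m", "m1")
  for (col in pos) {
    if (any(df[[col]] <= 0)) {
      stop("`", col, "` must be strictly positive.", call. = FALSE)
    }
  }
  dplyr::mutate(df,
    content = (.data$a * .data$v * .data$c) /
      (.data$a1 * .data$m * 1e3 * .data$m1) * 100)
}

#' Percentage decrease over a time-ordered series
#'
#' 100 * (first - last) / first. For a non-increasing positive series the
#' result lies in [0, 100).
#'
#' @param series numeric vector ordered by time; `series[1]` must be > 0.
#' @return percentage decrease (a single number).
#' @export
percent_decrease <- function(series) {
  if (length(series) == 0) stop("`series` is empty.", call. = FALSE)
  if (!is.finite(series[1]) || series[1] <= 0) {
    stop("first value of `series` must be > 0.", call. = FALSE)
  }
  100 * (series[1] - series[length(series)]) / series[1]
}

#' Layer-wise fermentation contrasts
#'
#' Mean content per (time, layer) cell and the content-maximal layer per time
#' point for every component; exact ties are flagged. With the default
#' generator kinetics the middle layer is maximal at 2 h and the lower layer
#' from 3 h on.
#'
#' @param chem chemistry tibble (columns time_h, layer, and content columns).
#' @return object of class `layer_summary`: list with `means` (time_h, layer,
#'   component, mean_content) and `top` (time_h, component, top_layer, tie).
#' @export
layer_contrast <- function(chem) {
  chem <- tibble::as_tibble(chem)
  comps <- intersect(catechin_components(), names(chem))
  if (length(comps) == 0) stop("no content columns found.", call. = FALSE)
  layers <- unique(chem$layer)
  cells <- tidyr::expand_grid(time_h = unique(chem$time_h), layer = layers)
  have <- dplyr::distinct(chem, .data$time_h, .data$layer)
  missing <- dplyr::anti_join(cells, have, by = c("time_h", "layer"))
  if (nrow(missing) > 0) {
    stop("missing (time, layer) cells: ",
         paste(sprintf("(%g h, %s)", missing$time_h, missing$layer),
               collapse = ", "), call. = FALSE)
  }
  means <- chem |>
    tidyr::pivot_longer(dplyr::all_of(comps), names_to = "component",
                        values_to = "content") |>
    dplyr::group_by(.data$time_h, .data$layer, .data$component) |>
    dplyr::summarise(mean_content = mean(.data$content), .groups = "drop")
  top <- means |>
    dplyr::group_by(.data$time_h, .data$component) |>
    dplyr::summarise(
      top_layer = .data$layer[which.max(.data$mean_content)],
      tie = sum(.data$mean_content == max(.data$mean_content)) > 1,
      .groups = "drop"
    )
  structure(list(means = means, top = top), class = "layer_summary")
}

#' @export
print.layer_summary <- function(x, ...) {
  cat("<layer_summary> content-maximal layer per time point:\n")
  print(tidyr::pivot_wider(x$top, id_cols = "time_h",
                           names_from = "component", values_from = "top_layer"))
  invisible(x)
}

#' @export
tidy.layer_summary <- function(x, ...) x$means

#' Plot layer-wise mean contents over fermentation time
#' @param object a `layer_summary`.
#' @param ... unused.
#' @export
autoplot.layer_summary <- function(object, ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(.data$time_h, .data$mean_content,
                               colour = .data$layer)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "fermentation time (h)", y = "content (% dry mass)")
}
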