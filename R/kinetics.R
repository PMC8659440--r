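#' Catechin component names used throughout the package
#'
#' Total catechins plus the five monomers, in the column order of chemistry
#' tables: total, egc, c, ec, egcg, ecg.
#' @export
catechin_components <- function() c("total", "egc", "c", "ec", "egcg", "ecg")

#' Fermentation kinetic parameters
#'
#' Describes the first-order catechin decay used by the synthetic generator.
#' Each component starts at `c0` (% dry mass) and decays with a non-reactive
#' residual: content(t) = c0 * ((1 - f) + f * exp(-k * I(t))), where f is the
#' reactive fraction and I(t) integrates a per-layer, per-phase rate modifier
#' (a fast 0-2 h phase and a slow 2-5 h phase). The rate constant k is solved
#' per component so that the layer-mean content drops by exactly
#' `decrease` x 100 percent between 0 h and 5 h.
#'
#' Default decrease fractions anchor the reported fermentation chemistry:
#' EC 0.9628, EGC 0.045, and Total/C/EGCG/ECG all above 0.7206. Default layer
#' modifiers give the middle layer a slow fast-phase (oxygen/temperature
#' limited) and the lower layer a slow late phase, so that the middle layer is
#' content-maximal at 2 h and the lower layer from 3 h onward.
#'
#' @param c0 named numeric, initial contents (% dry mass) for
#'   `catechin_components()`.
#' @param decrease named numeric in `[0, 1)`, total fractional decrease over
#'   the 0-5 h course.
#' @param reactive_fraction named numeric in `(decrease, 1]`; reactive pool
#'   size f. Default `pmin(0.995, decrease + 0.03)`.
#' @param layer_modifiers 3 x 2 numeric matrix (rows upper/middle/lower,
#'   columns fast/slow phase), strictly positive rate multipliers.
#' @param times numeric vector of sampling times in hours; must contain 0 and 5.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(c0 = c(total = 14.2, egc = 0.5, c = 0.7,
                                  ec = 1.2, egcg = 9.0, ecg = 2.5),
                           decrease = c(total = 0.78, egc = 0.045, c = 0.85,
                                        ec = 0.9628, egcg = 0.80, ecg = 0.75),
                           reactive_fraction = NULL,
                           layer_modifiers = default_layer_modifiers(),
                           times = 0:5) {
  comps <- catechin_components()
  c0 <- c0[comps]; decrease <- decrease[comps]
  if (anyNA(c0) || anyNA(decrease)) {
    stop("`c0` and `decrease` must be named for all of: ",
         paste(comps, collapse = ", "), call. = FALSE)
  }
  if (any(c0 <= 0)) stop("all initial contents must be > 0.", call. = FALSE)
  if (any(decrease < 0) || any(decrease >= 1)) {
    stop("decrease fractions must lie in [0, 1).", call. = FALSE)
  }
  if (is.null(reactive_fraction)) {
    reactive_fraction <- pmin(decrease + 0.03, 0.995)  # keeps names
  }
  reactive_fraction <- reactive_fraction[comps]
  if (any(reactive_fraction <= decrease & decrease > 0)) {
    stop("`reactive_fraction` must exceed `decrease` for reacting components.",
         call. = FALSE)
  }
  layer_modifiers <- as.matrix(layer_modifiers)
  if (!all(dim(layer_modifiers) == c(3, 2)) || any(layer_modifiers <= 0)) {
    stop("`layer_modifiers` must be a positive 3 x 2 matrix.", call. = FALSE)
  }
  rownames(layer_modifiers) <- c("upper", "middle", "lower")
  colnames(layer_modifiers) <- c("fast", "slow")
  if (!(0 %in% times) || !(5 %in% times)) {
    stop("`times` must include both 0 and 5 h.", call. = FALSE)
  }
  structure(
    list(c0 = c0, decrease = decrease, reactive_fraction = reactive_fraction,
         layer_modifiers = layer_modifiers, times = sort(unique(times))),
    class = "kinetic_params"
  )
}

#' @rdname kinetic_params
#' @export
default_layer_modifiers <- function() {
  matrix(c(1.3, 0.4,   # upper: fast start, moderate tail
           0.6, 1.2,   # middle: slow start (low O2/temp), catches up late
           1.0, 0.2),  # lower: ordinary start, slow late oxidation
         nrow = 3, byrow = TRUE,
         dimnames = list(c("upper", "middle", "lower"), c("fast", "slow")))
}

# integral of the per-phase rate modifier from 0 to t (fast phase = 0-2 h)
phase_integral <- function(t, mods) {
  outer(mods[, "fast"], pmin(t, 2)) + outer(mods[, "slow"], pmax(t - 2, 0))
}

# solve k so that mean_layers exp(-k I(5)) = (f - d) / f
solve_rate <- function(d, f, i5) {
  if (d <= 0) return(0)
  target <- (f - d) / f
  g <- function(k) mean(exp(-k * i5)) - target
  upper <- 1
  while (g(upper) > 0) upper <- upper * 2
  stats::uniroot(g, c(0, upper), tol = 1e-14)$root
}

#' Simulate a fermentation chemistry time-course
#'
#' Generates the reference chemistry table for the default experiment: one
#' sample per time point and stack layer, with contents following the decay
#' model of [kinetic_params()]. Deterministic (no noise): sampling noise enters
#' downstream through the spectral forward model.
#'
#' @param params a [kinetic_params()] object.
#' @return tibble with columns sample_id, time_h, layer and one content column
#'   (% dry mass) per catechin component.
#' @examples
#' chem <- simulate_kinetics(kinetic_params())
#' percent_decrease(dplyr::group_by(chem, time_h) |>
#'   dplyr::summarise(ec = mean(ec)) |> dplyr::pull(ec))
# per-component rate constants solved against the 0-5 h layer-mean anchor
kin_solve <- function(params) {
  i5 <- phase_integral(5, params$layer_modifiers)[, 1]
  comps <- catechin_components()
  k <- vapply(comps, function(cc) {
    solve_rate(params$decrease[[cc]], params$reactive_fraction[[cc]], i5)
  }, numeric(1))
  names(k) <- comps
  k
}

# contents (one row per t/layer pair, one column per component) anywhere on
# the kinetic trajectory
kinetic_content <- function(params, time_h, layer) {
  k <- kin_solve(params)
  mods <- params$layer_modifiers
  it <- unname(mods[layer, "fast"]) * pmin(time_h, 2) +
    unname(mods[layer, "slow"]) * pmax(time_h - 2, 0)
  out <- vapply(catechin_components(), function(cc) {
    f <- params$reactive_fraction[[cc]]
    params$c0[[cc]] * ((1 - f) + f * exp(-k[[cc]] * it))
  }, numeric(length(time_h)))
  if (length(time_h) == 1) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, names(out)))
  out
}

#' @export
simulate_kinetics <- function(params = kinetic_params()) {
  stopifnot(inherits(params, "kinetic_params"))
  comps <- catechin_components()
  layers <- c("upper", "middle", "lower")
  base <- tidyr::expand_grid(time_h = params$times, layer = layers)
  cmat <- kinetic_content(params, base$time_h, base$layer)
  content_cols <- purrr::map(comps, function(cc) cmat[, cc])
  names(content_cols) <- comps
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("t%gh_%s", base$time_h, base$layer),
      time_h = base$time_h, layer = base$layer
    ),
    tibble::as_tibble(content_cols)
  )
}
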