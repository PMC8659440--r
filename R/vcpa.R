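# Variable combination population analysis (binary matrix sampling + EDF
# shrinkage) and its GA / IRIV refinement stage.

#' Exponentially decreasing band-count schedule used by VCPA
#'
#' `round(p * (final_size / p)^(k / loops))` for loops `k = 1..loops`:
#' non-increasing from `p` down to exactly `final_size`.
#' @param p initial band count.
#' @param final_size surviving count after the last loop.
#' @param loops number of EDF loops.
#' @return integer vector of length `loops`.
#' @export
edf_schedule <- function(p, final_size, loops) {
  round(p * (final_size / p)^(seq_len(loops) / loops))
}

draw_bms <- function(n_rows, n_cols, env) {
  M <- matrix(stats::runif(n_rows * n_cols) < 0.5, n_rows, n_cols)
  for (i in seq_len(n_rows)) M[i, ] <- repair_empty(M[i, ], env)
  M
}

#' Variable combination population analysis (VCPA)
#'
#' Each EDF loop draws `n_bms` random binary subsets (inclusion probability
#' 0.5) of the surviving bands, evaluates their CV fitness, keeps the best
#' `keep_top_fraction`, scores every band by its frequency among the kept
#' subsets, and shrinks the surviving pool along the exponentially decreasing
#' schedule of [edf_schedule()] until `final_size` bands remain. The returned
#' selection is the best subset sampled in the last loop; the surviving pool
#' (for refinement with [refine_subset()]) is kept in `$survivors`.
#'
#' @inheritParams sfla_select
#' @param n_bms subsets drawn per loop (default 500).
#' @param edf_loops number of loops (>= 2, default 10).
#' @param keep_top_fraction fraction of subsets retained for frequency scoring
#'   (default 0.1).
#' @param final_size surviving band count after the last loop (default 100,
#'   must be smaller than the band count).
#' @return a [selection_result()] with algorithm "VCPA".
#' @export
vcpa_select <- function(Xcal, ycal, fitness = NULL, n_bms = 500,
                        edf_loops = 10, keep_top_fraction = 0.1,
                        final_size = 100, seed = 1, wavelengths_nm = NULL) {
  X <- as.matrix(Xcal)
  p <- ncol(X)
  if (edf_loops < 2) stop("`edf_loops` must be >= 2.", call. = FALSE)
  if (final_size >= p) {
    stop("`final_size` must be smaller than the starting band count.",
         call. = FALSE)
  }
  if (is.null(fitness)) fitness <- subset_fitness(X, ycal, seed = seed)
  if (is.null(wavelengths_nm)) wavelengths_nm <- seq_len(p)
  env <- new.env(); env$repairs <- 0L
  schedule <- edf_schedule(p, final_size, edf_loops)

  withr::with_seed(seed, {
    survivors <- seq_len(p)
    trace <- numeric(edf_loops)
    best_subset <- NULL; best_fit <- Inf
    for (k in seq_len(edf_loops)) {
      M <- draw_bms(n_bms, length(survivors), env)
      fits <- apply(M, 1, function(b) fitness_eval(fitness, survivors[b]))
      n_keep <- max(1L, ceiling(keep_top_fraction * n_bms))
      kept <- order(fits)[seq_len(n_keep)]
      freq <- colSums(M[kept, , drop = FALSE])
      trace[k] <- min(fits)
      if (k == edf_loops) {
        b <- which.min(fits)
        best_subset <- survivors[M[b, ]]
        best_fit <- fits[b]
      }
      keep_n <- min(schedule[k], length(survivors))
      survivors <- sort(survivors[order(-freq, seq_along(survivors))[seq_len(keep_n)]])
    }
    selection_result("VCPA", best_subset, wavelengths_nm, best_fit,
                     fitness_trace = trace, survivors = survivors,
                     n_bands = p, repairs = env$repairs)
  })
}

#' Refine a VCPA survivor pool with a genetic algorithm or IRIV
#'
#' GA mode evolves binary chromosomes over the survivors with tournament
#' selection, uniform crossover, bit-flip mutation and elitism; the initial
#' population contains the full survivor set, so the refined fitness can never
#' be worse than the pool's. IRIV mode (iteratively retains informative
#' variables) repeatedly draws random binary inclusion matrices over the
#' current pool and, for every band, compares the fitness distributions of the
#' sampled subsets containing it against those without it (Mann-Whitney,
#' alpha 0.05): bands whose inclusion helps are strongly (significant) or
#' weakly informative and are retained; bands whose inclusion harms are
#' interfering (significant) or uninformative and are dropped, round after
#' round, until none remain harmful. A backward-elimination pass finishes the
#' subset; if a proposed round would worsen the pool's fitness it is not
#' applied.
#'
#' @param Xcal,ycal calibration data.
#' @param survivors integer band indices (e.g. `$survivors` of
#'   [vcpa_select()]).
#' @param mode "GA" or "IRIV".
#' @param fitness optional [subset_fitness()].
#' @param params named list of mode parameters. GA: pop_size (30),
#'   generations (100), crossover (0.9), mutation (0.05), elitism (1),
#'   tournament (3). IRIV: n_rows (max(40, 2 x pool)), max_rounds (10),
#'   alpha (0.05).
#' @param seed integer seed.
#' @param wavelengths_nm optional band wavelengths.
#' @return a [selection_result()] with algorithm "VCPA-GA" or "VCPA-IRIV".
#' @export
refine_subset <- function(Xcal, ycal, survivors, mode = c("GA", "IRIV"),
                          fitness = NULL, params = list(), seed = 1,
                          wavelengths_nm = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(Xcal)
  survivors <- sort(unique(as.integer(survivors)))
  if (length(survivors) == 0) stop("`survivors` is empty.", call. = FALSE)
  if (is.null(fitness)) fitness <- subset_fitness(X, ycal, seed = seed)
  if (is.null(wavelengths_nm)) wavelengths_nm <- seq_len(ncol(X))
  if (mode == "GA") {
    refine_ga(survivors, fitness, params, seed, wavelengths_nm, ncol(X))
  } else {
    refine_iriv(survivors, fitness, params, seed, wavelengths_nm, ncol(X))
  }
}

refine_ga <- function(survivors, fitness, params, seed, wavelengths_nm, p_all) {
  pr <- utils::modifyList(
    list(pop_size = 30, generations = 100, crossover = 0.9, mutation = 0.05,
         elitism = 1, tournament = 3),
    params
  )
  ns <- length(survivors)
  env <- new.env(); env$repairs <- 0L
  withr::with_seed(seed + 1L, {
    pop <- matrix(stats::runif(pr$pop_size * ns) < 0.5, pr$pop_size, ns)
    pop[1, ] <- TRUE  # seed the full pool
    for (i in seq_len(pr$pop_size)) pop[i, ] <- repair_empty(pop[i, ], env)
    fit <- apply(pop, 1, function(b) fitness_eval(fitness, survivors[b]))
    trace <- numeric(pr$generations)
    pick <- function() {
      cand <- sample.int(pr$pop_size, min(pr$tournament, pr$pop_size))
      cand[which.min(fit[cand])]
    }
    for (g in seq_len(pr$generations)) {
      elite <- order(fit)[seq_len(pr$elitism)]
      newpop <- pop[elite, , drop = FALSE]
      while (nrow(newpop) < pr$pop_size) {
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        child <- if (stats::runif(1) < pr$crossover) {
          ifelse(stats::runif(ns) < 0.5, p1, p2)
        } else p1
        flip <- stats::runif(ns) < pr$mutation
        child[flip] <- !child[flip]
        newpop <- rbind(newpop, repair_empty(child, env))
      }
      pop <- newpop
      fit <- apply(pop, 1, function(b) fitness_eval(fitness, survivors[b]))
      trace[g] <- min(fit)
    }
    b <- which.min(fit)
    selection_result("VCPA-GA", survivors[pop[b, ]], wavelengths_nm, fit[b],
                     fitness_trace = cummin(trace), n_bands = p_all,
                     repairs = env$repairs)
  })
}

refine_iriv <- function(survivors, fitness, params, seed, wavelengths_nm, p_all) {
  pr <- utils::modifyList(
    list(n_rows = max(40L, 2L * length(survivors)), max_rounds = 10,
         alpha = 0.05),
    params
  )
  env <- new.env(); env$repairs <- 0L
  withr::with_seed(seed + 2L, {
    current <- survivors
    cur_fit <- fitness_eval(fitness, current)
    trace <- cur_fit
    for (round in seq_len(pr$max_rounds)) {
      if (length(current) <= 2) break
      M <- draw_bms(pr$n_rows, length(current), env)
      fits <- apply(M, 1, function(b) fitness_eval(fitness, current[b]))
      harmful <- vapply(seq_along(current), function(j) {
        w <- fits[M[, j]]; wo <- fits[!M[, j]]
        if (length(w) < 2 || length(wo) < 2) return(FALSE)
        mean(w) > mean(wo)  # inclusion raises CV error
      }, logical(1))
      if (!any(harmful)) break
      proposal <- current[!harmful]
      if (length(proposal) == 0) {
        # keep the single most helpful band rather than emptying the pool
        deltas <- vapply(seq_along(current), function(j) {
          mean(fits[M[, j]]) - mean(fits[!M[, j]])
        }, numeric(1))
        proposal <- current[which.min(deltas)]
      }
      prop_fit <- fitness_eval(fitness, proposal)
      if (prop_fit > cur_fit) {
        # only drop the significantly interfering bands
        signif <- vapply(seq_along(current), function(j) {
          w <- fits[M[, j]]; wo <- fits[!M[, j]]
          if (length(w) < 2 || length(wo) < 2) return(FALSE)
          mean(w) > mean(wo) &&
            suppressWarnings(stats::wilcox.test(w, wo)$p.value) < pr$alpha
        }, logical(1))
        if (!any(signif)) break
        proposal <- current[!signif]
        if (length(proposal) == 0) break
        prop_fit <- fitness_eval(fitness, proposal)
        if (prop_fit > cur_fit) break
      }
      current <- proposal; cur_fit <- prop_fit
      trace <- c(trace, cur_fit)
    }
    # backward elimination: drop bands while it improves the CV fitness
    repeat {
      if (length(current) <= 1) break
      drops <- vapply(seq_along(current), function(j) {
        fitness_eval(fitness, current[-j])
      }, numeric(1))
      if (min(drops) < cur_fit) {
        j <- which.min(drops)
        current <- current[-j]; cur_fit <- drops[j]
        trace <- c(trace, cur_fit)
      } else break
    }
    selection_result("VCPA-IRIV", current, wavelengths_nm, cur_fit,
                     fitness_trace = trace, n_bands = p_all,
                     repairs = env$repairs)
  })
}
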