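# Shuffled frog leaping algorithm over binary band subsets.

repair_empty <- function(bits, env) {
  if (!any(bits)) {
    bits[sample.int(length(bits), 1)] <- TRUE
    env$repairs <- env$repairs + 1L
  }
  bits
}

#' Shuffled frog leaping algorithm (SFLA) wavelength selection
#'
#' A memetic search over binary-encoded band subsets. Frogs (subsets) are
#' ranked by CV fitness and dealt round-robin into memeplexes; in each
#' memeplex the worst frog first attempts a move toward the memeplex best
#' (each differing bit adopts the best frog's value with probability 1/2),
#' then toward the global best, and is otherwise re-drawn at random. Memeplexes
#' are re-shuffled every iteration and the best-ever frog is kept, so the
#' fitness trace is non-increasing. Fully reproducible under a fixed seed.
#'
#' @param Xcal,ycal calibration data.
#' @param fitness optional [subset_fitness()]; built from `Xcal`/`ycal` and
#'   `seed` when missing.
#' @param memeplexes,frogs_per memeplex count and size (population
#'   `memeplexes * frogs_per` >= 4). Defaults 5 x 10.
#' @param iterations shuffling iterations (default 50).
#' @param seed integer seed.
#' @param inclusion_prob per-band inclusion probability of the initial
#'   population (default 0.5).
#' @param wavelengths_nm optional band wavelengths.
#' @return a [selection_result()] with algorithm "SFLA".
#' @export
sfla_select <- function(Xcal, ycal, fitness = NULL, memeplexes = 5,
                        frogs_per = 10, iterations = 50, seed = 1,
                        inclusion_prob = 0.5, wavelengths_nm = NULL) {
  X <- as.matrix(Xcal)
  p <- ncol(X)
  pop_size <- memeplexes * frogs_per
  if (pop_size < 4) stop("population must be at least 4 frogs.", call. = FALSE)
  if (is.null(fitness)) fitness <- subset_fitness(X, ycal, seed = seed)
  if (is.null(wavelengths_nm)) wavelengths_nm <- seq_len(p)
  env <- new.env(); env$repairs <- 0L

  withr::with_seed(seed, {
    pop <- matrix(stats::runif(pop_size * p) < inclusion_prob, pop_size, p)
    for (i in seq_len(pop_size)) pop[i, ] <- repair_empty(pop[i, ], env)
    fit <- apply(pop, 1, function(b) fitness_eval(fitness, which(b)))
    best_bits <- pop[which.min(fit), ]; best_fit <- min(fit)
    trace <- numeric(iterations)

    move_toward <- function(worst, target) {
      cand <- worst
      diff <- which(worst != target)
      if (length(diff) > 0) {
        take <- diff[stats::runif(length(diff)) < 0.5]
        cand[take] <- target[take]
      }
      repair_empty(cand, env)
    }

    for (it in seq_len(iterations)) {
      ord <- order(fit)
      mem_of <- integer(pop_size)
      mem_of[ord] <- rep(seq_len(memeplexes), length.out = pop_size)
      for (m in seq_len(memeplexes)) {
        rows <- which(mem_of == m)
        w <- rows[which.max(fit[rows])]
        lb <- rows[which.min(fit[rows])]
        cand <- move_toward(pop[w, ], pop[lb, ])
        cf <- fitness_eval(fitness, which(cand))
        if (cf >= fit[w]) {
          cand <- move_toward(pop[w, ], best_bits)
          cf <- fitness_eval(fitness, which(cand))
        }
        if (cf >= fit[w]) {
          cand <- repair_empty(stats::runif(p) < inclusion_prob, env)
          cf <- fitness_eval(fitness, which(cand))
        }
        pop[w, ] <- cand; fit[w] <- cf
        if (cf < best_fit) { best_fit <- cf; best_bits <- cand }
      }
      trace[it] <- best_fit
    }

    selection_result("SFLA", which(best_bits), wavelengths_nm, best_fit,
                     fitness_trace = trace, n_bands = p,
                     repairs = env$repairs)
  })
}
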