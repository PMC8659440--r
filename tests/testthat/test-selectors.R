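# SFLA / VCPA / GA / IRIV behavior on small fixtures. The multi-seed
# planted-band recovery study lives in the acceptance suite.

test_that("subset fitness is deterministic, cached and reproducible", {
  d <- fx_planted(21, n = 60, p = 30)
  f1 <- subset_fitness(d$X, d$y, seed = 5)
  f2 <- subset_fitness(d$X, d$y, seed = 5)
  idx <- c(3, 7, 20)
  expect_identical(fitness_eval(f1, idx), fitness_eval(f2, idx))
  expect_identical(fitness_eval(f1, idx), fitness_eval(f1, idx))
  expect_gte(fitness_eval(f1, idx), 0)
  expect_error(fitness_eval(f1, integer(0)), "empty")
})

test_that("SFLA is seed-reproducible with a non-increasing trace", {
  d <- fx_planted(22, n = 60, p = 40)
  a <- sfla_select(d$X, d$y, memeplexes = 3, frogs_per = 5, iterations = 10,
                   seed = 9)
  b <- sfla_select(d$X, d$y, memeplexes = 3, frogs_per = 5, iterations = 10,
                   seed = 9)
  expect_identical(a$indices, b$indices)
  expect_identical(a$fitness, b$fitness)
  expect_true(all(diff(a$fitness_trace) <= 0))
  expect_true(all(d$bands %in% a$indices))
  # re-evaluating the returned subset reproduces the reported fitness
  f <- subset_fitness(d$X, d$y, seed = 9)
  expect_equal(fitness_eval(f, a$indices), a$fitness)
})

test_that("the EDF schedule matches its closed form", {
  sch <- edf_schedule(100, 10, 10)
  expect_equal(sch, round(100 * 0.1^((1:10) / 10)))
  expect_true(all(diff(sch) <= 0))
  expect_equal(sch[10], 10)
})

test_that("binary matrix sampling includes each band about half the time", {
  env <- new.env(); env$repairs <- 0L
  withr::with_seed(30, M <- teaspec:::draw_bms(500, 100, env))
  freq <- colMeans(M)
  sigma <- sqrt(0.25 / 500)
  expect_true(all(abs(freq - 0.5) < 3.5 * sigma + 1 / 500))
})

test_that("VCPA shrinks to the schedule and keeps the planted bands", {
  d <- fx_planted(23, n = 80, p = 60)
  res <- vcpa_select(d$X, d$y, n_bms = 60, edf_loops = 4, final_size = 12,
                     seed = 3)
  expect_equal(length(res$survivors), 12)
  expect_true(all(d$bands %in% res$survivors))
  expect_true(all(res$indices %in% seq_len(60)))
  f <- subset_fitness(d$X, d$y, seed = 3)
  expect_equal(fitness_eval(f, res$indices), res$fitness)
  expect_error(vcpa_select(d$X, d$y, final_size = 60, seed = 1), "smaller")
  expect_error(vcpa_select(d$X, d$y, edf_loops = 1, final_size = 10,
                           seed = 1), "edf_loops")
})

test_that("a GA with no variation returns its only chromosome", {
  d <- fx_planted(24, n = 50, p = 20)
  f <- subset_fitness(d$X, d$y, seed = 2)
  res <- refine_subset(d$X, d$y, survivors = 1:20, mode = "GA", fitness = f,
                       params = list(pop_size = 6, generations = 5,
                                     crossover = 0, mutation = 0),
                       seed = 4)
  # with crossover 0 and mutation 0, children copy parents; the population
  # collapses to clones of the initial chromosomes and the best one wins
  expect_equal(fitness_eval(f, res$indices), res$fitness)
  full <- fitness_eval(f, 1:20)
  expect_lte(res$fitness, full)
})

test_that("refinement never does worse than the full survivor pool", {
  d <- fx_planted(25, n = 70, p = 50)
  f <- subset_fitness(d$X, d$y, seed = 6)
  survivors <- sort(unique(c(d$bands, 5, 12, 19, 27, 33, 41, 48)))
  full <- fitness_eval(f, survivors)
  ga <- refine_subset(d$X, d$y, survivors, "GA", f,
                      params = list(pop_size = 12, generations = 15), seed = 6)
  ir <- refine_subset(d$X, d$y, survivors, "IRIV", f, seed = 6)
  expect_lte(ga$fitness, full)
  expect_lte(ir$fitness, full)
  expect_true(all(d$bands %in% ga$indices))
  expect_true(all(d$bands %in% ir$indices))
  expect_error(refine_subset(d$X, d$y, integer(0), "GA", f), "empty")
})

test_that("IRIV drops a harmful noise band in the first round", {
  removed <- 0
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 40
      X <- matrix(rnorm(n * 6), n, 6)
      X[, 4] <- rnorm(n, sd = 5)  # pure high-amplitude interference
      y <- X[, 1] + X[, 2] + 0.5 * X[, 3] + rnorm(n, sd = 0.05)
    })
    f <- subset_fitness(X, y, seed = seed)
    res <- refine_subset(X, y, 1:6, "IRIV", f,
                         params = list(max_rounds = 1), seed = seed)
    if (!(4 %in% res$indices)) removed <- removed + 1
  }
  expect_gte(removed, 4)
})
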