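test_that("the cooling ratio maps t_init to t_final exactly", {
  expect_equal(cooling_ratio(100, 1e-10, 13), 0.1)
  sched <- cooling_schedule(100, 1e-10, 13)
  expect_equal(sched$temperatures[1:3], c(100, 10, 1))
  expect_equal(cooling_ratio(5, 2, 2), 2 / 5)
  set.seed(3)
  for (i in 1:25) {
    t_i <- runif(1, 1, 1000)
    t_f <- t_i * runif(1, 1e-12, 0.9)
    n_m <- sample(2:40, 1)
    C <- cooling_ratio(t_i, t_f, n_m)
    expect_equal(t_i * C^(n_m - 1), t_f, tolerance = 1e-9)
  }
  expect_error(cooling_ratio(10, 1, 1), ">= 2")
  expect_error(cooling_ratio(1, 10, 5), "t_final < t_init")
})

test_that("the temperature ladder is strictly decreasing and geometric", {
  sched <- cooling_schedule(50, 1e-6, 9)
  expect_true(all(diff(sched$temperatures) < 0))
  ratios <- sched$temperatures[-1] / sched$temperatures[-9]
  expect_equal(ratios, rep(sched$ratio, 8))
})

test_that("moves respect the distance bound and the activation rule", {
  set.seed(14)
  cfg <- move_config(move_distance_max = 4)
  current <- sample(0:1, 30, replace = TRUE)
  best <- sample(0:1, 30, replace = TRUE)
  for (i in 1:200) {
    prop <- propose_move(current, best, cfg)
    expect_lte(hamming_distance(current, prop), 4)
  }
  ## chosen inactive coordinates always activate
  all_zero <- rep(0L, 10)
  prop <- propose_move(all_zero, rep(1L, 10), move_config(10))
  expect_true(all(prop >= all_zero))
  expect_gte(sum(prop), 1)
})

test_that("the inactivation floor keeps 1-to-0 flips possible from all-ones", {
  ## best = all-ones means nz = 0; the floor (1/nc = 0.05) must still allow
  ## flips at that rate
  set.seed(15)
  nc <- 20
  ones <- rep(1L, nc)
  cfg <- move_config(move_distance_max = 1)
  flips <- replicate(1e4, hamming_distance(ones, propose_move(ones, ones,
                                                              cfg)))
  rate <- mean(flips)
  se <- sqrt(0.05 * 0.95 / 1e4)
  expect_lt(abs(rate - 1 / nc), 4 * se)
})

test_that("Tsallis acceptance behaves as the generalized Metropolis rule", {
  expect_equal(tsallis_probability(0, 1, 1, 0.25), 1)
  expect_equal(tsallis_probability(-3, 1, 1, 0.25), 1)
  ## large worsening with q < 1 clamps at zero
  expect_equal(tsallis_probability(100, 1, 0.1, 0.25), 0)
  expect_error(tsallis_probability(1, 1, 1, 1), "Metropolis")
  ## q -> 1 recovers the exponential form
  q <- 0.999999
  for (delta in c(0.1, 0.5, 1, 3)) for (dbar in c(0.5, 1, 2)) {
    for (t in c(0.2, 1, 5)) {
      expect_equal(tsallis_probability(delta, dbar, t, q),
                   exp(-delta / (dbar * t)), tolerance = 1e-4)
    }
  }
  ## monotone: non-increasing in the worsening, non-decreasing in t
  deltas <- seq(0.1, 5, 0.1)
  ps <- vapply(deltas, tsallis_probability, numeric(1), delta_bar = 1,
               t = 1, q = 0.25)
  expect_true(all(diff(ps) <= 0))
  ts <- seq(0.1, 5, 0.1)
  pt <- vapply(ts, function(t) tsallis_probability(1, 1, t, 0.25), numeric(1))
  expect_true(all(diff(pt) >= 0))
})

test_that("an SA batch is reproducible and only cools between chains", {
  spec <- landscape_spec(12, bad = c(3, 7), penalty = 20)
  run <- function(seed) {
    ctx <- eval_context(landscape = spec, seed = 4)
    run_sa_batch(ctx, cooling_schedule(10, 1e-4, 6), n_clients = 3,
                 chain_length = 20, seed = seed)
  }
  r1 <- run(11)
  r2 <- run(11)
  expect_identical(vapply(r1$history, `[[`, character(1), "word"),
                   vapply(r2$history, `[[`, character(1), "word"))
  expect_identical(r1$best$word, r2$best$word)
  ## one temperature per chain
  by_chain <- tapply(r1$trace$temperature, r1$trace$chain,
                     function(x) length(unique(x)))
  expect_true(all(by_chain == 1))
  ## batch best at least as good as the mandated all-ones start
  start <- landscape_fitness(spec, rep(1L, 12))$score
  expect_gte(r1$best$score, start)
})

test_that("near zero temperature the chain only accepts improvements", {
  spec <- landscape_spec(10, bad = 2, penalty = 30)
  ctx <- eval_context(landscape = spec, seed = 5)
  res <- run_sa_batch(ctx, cooling_schedule(1e-7, 1e-9, 3), n_clients = 1,
                      chain_length = 60, seed = 5)
  acc <- res$trace[res$trace$status == "accepted", ]
  ## replay the accepted path: scores never decrease
  expect_true(all(diff(c(100 * 0 + landscape_fitness(spec,
                                                     rep(1L, 10))$score,
                         acc$score)) >= -1e-12))
})

test_that("greedy descent reaches a single-flip local optimum", {
  spec <- landscape_spec(12, bad = c(3, 7), penalty = 20)
  opt <- landscape_optimum(spec)
  ctx <- eval_context(landscape = spec, seed = 6)
  ## starting at the optimum returns it unchanged
  at_opt <- greedy_descent(opt$bits, ctx)
  expect_identical(at_opt$word, opt$word)
  ## from arbitrary starts: no single flip can improve the result
  set.seed(16)
  for (i in 1:5) {
    start <- sample(0:1, 12, replace = TRUE)
    if (sum(start) == 0) start[1] <- 1L
    out <- greedy_descent(start, ctx)
    expect_gte(out$score, landscape_fitness(spec, start)$score)
    for (j in 1:12) {
      nb <- out$bits
      nb[j] <- 1L - nb[j]
      if (sum(nb) == 0) next
      expect_lte(landscape_fitness(spec, nb)$score, out$score)
    }
  }
})

test_that("benchmark functions have their known minima", {
  expect_equal(benchmark_function("three_hump_camel", c(0, 0)), 0)
  expect_equal(benchmark_function("booth", c(1, 3)), 0)
  expect_equal(benchmark_function("levi", c(1, 1)), 0, tolerance = 1e-12)
  expect_error(benchmark_function("rosenbrock", c(0, 0)), "unknown")
})

test_that("continuous SA with greedy descent minimizes the camel function", {
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    run_sa_continuous("three_hump_camel", x0 = runif(2, -4, 4))$value < 1e-2
  })
  expect_gte(sum(hits), 8)
})
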