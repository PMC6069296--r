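test_that("inertia weight decreases linearly from 0.9 to 0.4", {
  expect_equal(inertia_weight(0, 100), 0.9)
  expect_equal(inertia_weight(100, 100), 0.4)
  expect_equal(inertia_weight(50, 100), 0.65)
  expect_error(inertia_weight(5, 0), "max_iter")
})

test_that("the constriction coefficient matches its closed form", {
  expect_equal(constriction_coefficient(1), 2 / abs(2 - 4.1 - sqrt(0.41)))
  expect_equal(constriction_coefficient(1), 0.72984, tolerance = 1e-5)
  expect_equal(constriction_coefficient(0), 0)
  ## linear in k at fixed C
  ks <- seq(0, 1, 0.1)
  xs <- vapply(ks, constriction_coefficient, numeric(1))
  expect_equal(xs, ks * constriction_coefficient(1))
  expect_error(constriction_coefficient(0.5, c1 = 1, c2 = 1), ">= 4")
})

test_that("velocity rules reproduce the stated arithmetic", {
  ## inertia: w v + phi1 (pb - x) + phi2 (gb - x), both differences 1
  expect_equal(velocity_inertia(0.5, 0, 1, 1, w = 0.9, phi1 = 0.3,
                                phi2 = 0.2), 0.95)
  ## constriction with v = 0: coef * (C1 + C2) * d
  d <- 0.7
  expect_equal(velocity_constriction(0, 0, d, d, coef = 0.73, c1 = 2.05,
                                     c2 = 2.05), 0.73 * 4.1 * d)
  ## at a consensus point nothing moves, either variant
  cfg1 <- swarm_config(variant = 1)
  cfg2 <- swarm_config(variant = 2)
  set.seed(2)
  x <- c(1L, 0L, 1L)
  expect_equal(update_velocity(numeric(3), x, x, x, cfg1, 1, 10), numeric(3))
  expect_equal(update_velocity(numeric(3), x, x, x, cfg2, 1, 10), numeric(3))
})

test_that("velocity components are clamped", {
  cfg <- swarm_config(variant = 1, v_clamp = 6)
  set.seed(1)
  v <- update_velocity(rep(100, 4), rep(0L, 4), rep(1L, 4), rep(1L, 4),
                       cfg, 1, 10)
  expect_true(all(abs(v) <= 6))
})

test_that("the sigmoid position rule activates bits at the expected rate", {
  set.seed(6)
  hits <- mean(replicate(200, update_position(rep(0, 50))))
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(hits - 0.5), max(0.02, 4 * se))
  expect_identical(update_position(rep(20, 6)), rep(1L, 6))
  ## strongly negative velocities: the empty word is forbidden, one bit is
  ## forced on
  set.seed(7)
  w <- update_position(rep(-20, 6))
  expect_equal(sum(w), 1L)
})

test_that("swarm initialization starts near the whole core genome", {
  spec <- landscape_spec(100, bad = 1, penalty = 10)
  set.seed(10)
  fracs <- replicate(20, {
    ctx <- eval_context(landscape = spec, seed = 1)
    sw <- init_swarm(ctx, swarm_config(n_particles = 5))
    mean(vapply(sw$positions, mean, numeric(1)))
  })
  expect_lt(abs(mean(fracs) - 0.9), 0.02)
  ## velocities start at zero; global best dominates personal bests
  ctx <- eval_context(landscape = spec, seed = 2)
  set.seed(11)
  sw <- init_swarm(ctx, swarm_config(n_particles = 4))
  expect_true(all(vapply(sw$velocities, function(v) all(v == 0), logical(1))))
  expect_true(all(sw$gbest$score >=
                    vapply(sw$pbest, `[[`, numeric(1), "score")))
})

test_that("the global best never decreases within a swarm", {
  spec <- landscape_spec(12, bad = c(3, 7), penalty = 20)
  for (variant in 1:2) {
    ctx <- eval_context(landscape = spec, seed = 3)
    res <- run_bpso(ctx, swarm_config(n_particles = 6, variant = variant,
                                      max_iterations = 30, stop_score = 100),
                    seed = 3)
    trace <- res$per_swarm[[1L]]$gbest_trace
    expect_true(all(diff(trace) >= 0))
  }
})

test_that("runs are reproducible and the variants differ", {
  spec <- landscape_spec(12, bad = c(3, 7), penalty = 20)
  run <- function(variant, seed) {
    ctx <- eval_context(landscape = spec, seed = 7)
    res <- run_bpso(ctx, swarm_config(n_particles = 5, variant = variant,
                                      max_iterations = 15, stop_score = 100),
                    seed = seed)
    vapply(res$history, `[[`, character(1), "word")
  }
  expect_identical(run(1, 42), run(1, 42))
  expect_identical(run(2, 42), run(2, 42))
  expect_false(identical(run(1, 42), run(2, 42)))
})

test_that("a 10-swarm configuration with 10 particles runs and merges", {
  spec <- landscape_spec(12, bad = c(3, 7), penalty = 20)
  ctx <- eval_context(landscape = spec, seed = 9)
  res <- run_bpso(ctx, swarm_config(n_particles = 10, n_swarms = 10,
                                    max_iterations = 3, stop_score = 100),
                  seed = 9)
  expect_length(res$per_swarm, 10L)
  expect_true(all(vapply(res$per_swarm,
                         function(s) s$best$score <= res$best$score ||
                           isTRUE(all.equal(s$best$score, res$best$score)),
                         logical(1))))
  rep <- topology_report(res$history)
  expect_equal(sum(rep$n_trees), length(res$history))
})
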