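test_that("single-predictor fits match the soft-threshold closed form", {
  set.seed(31)
  for (i in 1:100) {
    m <- sample(20:60, 1)
    x <- rnorm(m)
    x <- x - mean(x)
    x <- x / sqrt(sum(x^2))
    y <- rnorm(m, sd = sample(c(0.5, 1, 3), 1))
    lam <- runif(1, 0, 3)
    z <- sum(x * (y - mean(y)))
    oracle <- sign(z) * max(abs(z) - lam / 2, 0)
    fit <- lasso_fit(list(W = matrix(x, ncol = 1), Y = y), lambda = lam)
    expect_equal(unname(fit$beta), oracle, tolerance = 1e-6)
  }
})

test_that("with no penalty the fit equals ordinary least squares", {
  set.seed(32)
  W <- matrix(rbinom(200, 1, 0.5), 40, 5)
  Y <- rnorm(40, 70, 10)
  fit <- lasso_fit(list(W = W, Y = Y), lambda = 0)
  ols <- stats::coef(stats::lm(I(Y - mean(Y)) ~
                                 scale(W, scale = FALSE) - 1))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-6)
})

test_that("degenerate designs are handled", {
  W <- matrix(rbinom(60, 1, 0.5), 20, 3)
  ## constant response: centered Y is zero, all coefficients vanish
  fit <- lasso_fit(list(W = W, Y = rep(88, 20)), lambda = 1)
  expect_true(all(fit$beta == 0))
  ## all-constant design is rejected
  expect_error(lasso_fit(list(W = matrix(1, 20, 3), Y = rnorm(20)),
                         lambda = 1), "constant")
})

test_that("the fitted objective beats the null and shrinks with lambda", {
  set.seed(33)
  W <- matrix(rbinom(300, 1, 0.5), 50, 6)
  Y <- 80 + W %*% c(3, -4, 0, 1, 0, -2) + rnorm(50)
  objective <- function(beta, lam) {
    Wc <- scale(W, scale = FALSE)
    sum((Y - mean(Y) - Wc %*% beta)^2) + lam * sum(abs(beta))
  }
  l1 <- c()
  for (lam in c(0.1, 1, 5, 20, 80, 300)) {
    fit <- lasso_fit(list(W = W, Y = Y), lambda = lam)
    expect_lte(objective(fit$beta, lam),
               objective(numeric(6), lam) + 1e-8)
    l1 <- c(l1, sum(abs(fit$beta)))
  }
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("negative coefficients identify support-breaking genes", {
  fake <- structure(list(beta = c(gA = 0.3, gB = -0.2, gC = 0)),
                    class = "lasso_fit")
  expect_identical(problematic_genes(fake), "gB")
  expect_identical(problematic_genes(structure(list(beta = c(a = 1, b = 0)),
                                               class = "lasso_fit")),
                   character(0))
  ## simulation: a gene dropping the support by 10 points is recovered
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    m <- 60
    W <- matrix(rbinom(m * 8, 1, 0.5), m, 8)
    Y <- 90 - 10 * W[, 4] + rnorm(m, 0, 1)
    fit <- lasso_fit(list(W = W, Y = Y))
    "g4" %in% problematic_genes(fit)
  })
  expect_gte(sum(hits), 9)
})

test_that("frequent topologies are thresholded on their share of trees", {
  h <- fake_history(c(rep("A", 27), rep("B", 2)))
  expect_identical(frequent_topologies(h), "A")
  h2 <- fake_history(c(rep("A", 6), rep("B", 43), rep("C", 315)))
  expect_identical(frequent_topologies(h2), c("C", "B"))
  expect_identical(frequent_topologies(fake_history("X")), "X")
  expect_error(frequent_topologies(list()), "length")
})

test_that("regression data is assembled per topology with variance flags", {
  spec <- landscape_spec(6, bad = 2, penalty = 30)
  ctx <- eval_context(landscape = spec, seed = 41)
  set.seed(41)
  for (i in 1:30) {
    w <- c(1L, rbinom(5, 1, 0.5))   # gene 1 always active
    if (sum(w) == 0) w[1] <- 1L
    evaluate_word(ctx, w)
  }
  h <- run_history(ctx)
  key <- frequent_topologies(h)[1]
  rd <- regression_data(h, key, "landscape")
  expect_gte(nrow(rd$W), 2L)
  expect_true(1L %in% rd$zero_variance)        # always-active gene flagged
  expect_true(all(rd$Y >= 0 & rd$Y <= 100))
  expect_error(regression_data(h, key, "no-such-branch"), "absent")
  ## history scope uses every word
  rd_all <- regression_data(h, key, "landscape", scope = "history")
  expect_equal(nrow(rd_all$W), length(h))
})

test_that("refinement prunes the planted landscape gene and keeps the best", {
  spec <- landscape_spec(10, bad = 3, penalty = 20)
  ctx <- eval_context(landscape = spec, seed = 42)
  res <- run_ga(ctx, ga_config(max_iterations = 5, stop_score = 100,
                               n_random_init = 60), seed = 42)
  pre_best <- res$best$score
  refined <- hybrid_refine(res, ga_config(max_iterations = 5,
                                          stop_score = 100), seed = 43,
                           scope = "history")
  expect_true("gene003" %in% refined$refinement$pruned)
  ## the planted gene is zeroed in every population word
  expect_true(all(vapply(refined$population,
                         function(r) r$bits[3] == 0L, logical(1))))
  expect_gte(refined$best$score, pre_best)
})

test_that("refinement without problematic branches is a plain continuation", {
  spec <- landscape_spec(8, bad = integer(0), penalty = 10)
  ctx <- eval_context(landscape = spec, seed = 44)
  res <- run_ga(ctx, ga_config(max_iterations = 2, stop_score = 100,
                               n_random_init = 30), seed = 44)
  refined <- hybrid_refine(res, ga_config(max_iterations = 2,
                                          stop_score = 100), seed = 45)
  expect_length(refined$refinement$pruned, 0L)
  expect_gte(refined$best$score, res$best$score)
})
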