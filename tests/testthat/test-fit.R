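kp <- keypad_layout("grid3x3")

test_that("maximum likelihood recovers generating parameters on long
           sequences", {
  truth <- model_params("dist2", epsilon = -0.4, delta = -0.3)
  s <- simulate_sequence(truth, 2000, kp, seed = 31)
  est <- fit_mle("dist2", s, kp)
  expect_lt(abs(est$epsilon - -0.4), 0.15)
  expect_lt(abs(est$delta - -0.3), 0.15)
})

test_that("a sequence with no repetitions pins the repetition weight at the
           lower box bound", {
  est <- fit_mle("dist2", rep(1:9, 10), kp)
  expect_equal(est$epsilon, -10)
})

test_that("the MLE beats a brute-force grid search", {
  set.seed(17)
  s <- simulate_sequence(model_params("dist2", epsilon = -0.8, delta = -0.4),
                         50, kp, seed = 23)
  est <- fit_mle("dist2", s, kp)
  grid <- seq(-3, 3, by = 0.05)
  feats <- encode_features(s, kp)
  X <- rngbias:::variant_design("dist2", feats)
  best_grid <- max(outer(grid, grid, Vectorize(function(e, d)
    rngbias:::loglik_from_features(c(e, d), X, feats$y))))
  expect_gte(attr(est, "loglik"), best_grid - 1e-6)
})

test_that("the sampler's objective equals the summed sequence
           log-likelihood", {
  seqs <- simulate_cohort(
    list(a = model_params("cyc3_log", epsilon = -0.4, delta = -0.3,
                          beta = 0.8)),
    reps = 4, length = 60, seed = 51)
  data <- lapply(seqs, function(s) {
    feats <- encode_features(s, kp)
    list(X = rngbias:::variant_design("cyc3_log", feats), y = feats$y)
  })
  set.seed(3)
  for (i in 1:20) {
    th <- runif(3, -2, 2)
    internal <- sum(vapply(data, function(d)
      rngbias:::loglik_from_features(th, d$X, d$y), numeric(1)))
    pars <- rngbias:::params_from_vector("cyc3_log", th)
    direct <- sum(vapply(seqs, function(s)
      sequence_loglik(pars, s, kp), numeric(1)))
    expect_equal(internal, direct, tolerance = 1e-10)
  }
})

test_that("the hierarchical fit runs, is seed-deterministic and shrinks
           individual estimates toward the population mean", {
  set.seed(61)
  truth <- lapply(1:10, function(i)
    model_params("dist2", epsilon = rnorm(1, -0.4, 0.8),
                 delta = rnorm(1, -0.3, 0.4)))
  seqs <- simulate_cohort(truth, reps = 1, length = 150, seed = 62)
  fit <- fit_hierarchical("dist2", seqs, kp, chains = 2, iter = 200,
                          warmup = 200, seed = 7)
  expect_s3_class(fit, "rng_hfit")
  expect_equal(nrow(fit$participants), 10)
  expect_equal(nrow(fit$hyper), 4)
  expect_true(all(is.finite(fit$hyper$rhat)))
  expect_true(all(abs(fit$participants$epsilon) <= 10))

  fit2 <- fit_hierarchical("dist2", seqs, kp, chains = 2, iter = 200,
                           warmup = 200, seed = 7)
  expect_identical(fit$hyper, fit2$hyper)
  expect_identical(fit$participants, fit2$participants)

  # shrinkage: posterior means sit between the per-sequence MLE and the
  # population mean for most participant-parameters
  mles <- t(vapply(seqs, function(s)
    rngbias:::param_vector(fit_mle("dist2", s, kp)), numeric(2)))
  between <- 0
  for (j in c("epsilon", "delta")) {
    mu_hat <- fit$hyper$mean[fit$hyper$hyperparameter == paste0("mu_", j)]
    post <- fit$participants[[j]]
    between <- between +
      sum((post >= pmin(mles[, j], mu_hat) - 0.05) &
          (post <= pmax(mles[, j], mu_hat) + 0.05))
  }
  expect_gte(between / 20, 0.75)
})

test_that("convergence checking flags single chains and honours the
           threshold", {
  seqs <- simulate_cohort(
    list(a = model_params("dist2", epsilon = 0.2, delta = -0.2)),
    reps = 3, length = 80, seed = 71)
  fit <- fit_hierarchical("dist2", seqs, kp, chains = 2, iter = 100,
                          warmup = 100, seed = 8)
  expect_true(check_convergence(fit, rhat_max = Inf)$pass)
  fit$config$chains <- 1L
  expect_error(check_convergence(fit), "2 chains")
})

test_that("split R-hat separates stationary from drifting chains", {
  set.seed(9)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.01)
  drifting <- good + outer(seq(0, 3, length.out = 1000), rep(1, 4))
  expect_gt(split_rhat(drifting), 1.2)
  offset <- good
  offset[, c(2, 4)] <- offset[, c(2, 4)] + 5  # chains stuck at distinct levels
  expect_gt(split_rhat(offset), 1.5)
})
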