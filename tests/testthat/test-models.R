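kp <- keypad_layout("grid3x3")

rand_state <- function(prev, history_len = 6) {
  hist <- c(sample.int(9, history_len, replace = TRUE), prev)
  g <- init_gap(9)
  for (x in hist) g <- update_gap(g, x)
  feature_state(prev, g, kp)
}

test_that("model_params enforces the variant's parameter set", {
  p <- model_params("cyc3_log", epsilon = -0.4, delta = -0.3, beta = 0.8)
  expect_s3_class(p, "rng_model_params")
  expect_error(model_params("dist2", epsilon = 1), "requires parameter 'delta'")
  expect_error(model_params("dist2", epsilon = 1, delta = 0, beta = 1),
               "not part of variant")
  expect_error(model_params("dist2", epsilon = Inf, delta = 0), "finite")
  expect_equal(variant_param_names("yousif2"), c("epsilon", "eta"))
})

test_that("all-zero parameters give the uniform distribution", {
  st <- rand_state(4)
  for (v in model_variants()) {
    pn <- variant_param_names(v)
    p0 <- do.call(model_params,
                  c(list(variant = v), stats::setNames(as.list(rep(0, length(pn))), pn)))
    expect_equal(choice_probabilities(p0, st), rep(1 / 9, 9))
  }
})

test_that("choice probabilities match hand-derived values", {
  # repetition-only: P(prev) = e / (e + 8)
  st <- feature_state(3, update_gap(init_gap(9), 3), kp)
  p <- choice_probabilities(model_params("dist2", epsilon = 1, delta = 0), st)
  expect_equal(p[3], exp(1) / (exp(1) + 8), tolerance = 1e-12)
  expect_equal(p[1], 1 / (exp(1) + 8), tolerance = 1e-12)
  # pure logarithmic cycling with beta = 1 on gap [3,3,2,3,3,3,1,3,3]
  st2 <- list(r = repetition_vector(7, 9), d = rep(0, 9),
              g = c(3, 3, 2, 3, 3, 3, 1, 3, 3))
  p2 <- choice_probabilities(
    model_params("cyc3_log", epsilon = 0, delta = 0, beta = 1), st2)
  denom <- 7 * exp(log(3) / log(2)) + exp(1) + 1
  expect_equal(p2[7], 1 / denom, tolerance = 1e-12)
  expect_equal(which.min(p2), 7L)
})

test_that("probabilities are a proper distribution and stable at extremes", {
  set.seed(7)
  for (i in 1:20) {
    st <- rand_state(sample.int(9, 1), history_len = 30)
    p <- choice_probabilities(
      model_params("cyc3_log", epsilon = runif(1, -10, 10),
                   delta = runif(1, -10, 10), beta = runif(1, -10, 10)), st)
    expect_true(all(p > 0 & p < 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("raising the repetition weight raises the repeat probability", {
  st <- rand_state(6)
  probs <- vapply(c(-2, -1, 0, 1, 2), function(e)
    choice_probabilities(model_params("dist2", epsilon = e, delta = -0.4),
                         st)[6], numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("with positive cycling weight, larger gap means higher probability
           among candidates equal in repetition and distance", {
  # from prev = 5 all corners are equidistant; give them different gaps
  g <- c(7, 2, 3, 2, 1, 2, 4, 2, 9)
  st <- list(r = repetition_vector(5, 9), d = distance_vector(5, kp), g = g)
  for (v in c("cyc3_lin", "cyc3_log")) {
    p <- choice_probabilities(
      model_params(v, epsilon = 0.3, delta = -0.5, beta = 0.8), st)
    corners <- c(1, 3, 7, 9)
    expect_equal(corners[order(p[corners])], corners[order(g[corners])])
    expect_gt(p[9], p[1])
  }
})

test_that("cycling models with beta = 0 reduce exactly to the distance model", {
  set.seed(11)
  for (i in 1:10) {
    st <- rand_state(sample.int(9, 1))
    e <- runif(1, -2, 2); d <- runif(1, -2, 2)
    ref <- choice_probabilities(model_params("dist2", epsilon = e, delta = d), st)
    for (v in c("cyc3_lin", "cyc3_log"))
      expect_equal(choice_probabilities(
        model_params(v, epsilon = e, delta = d, beta = 0), st), ref)
  }
})

test_that("gap entries below one are rejected", {
  st <- rand_state(2)
  st$g[4] <- 0
  expect_error(choice_probabilities(
    model_params("cyc3_log", epsilon = 0, delta = 0, beta = 1), st), ">= 1")
})

test_that("sequence log-likelihood of the uniform model is (T-1) log(1/9)", {
  for (T_len in c(2, 10, 57)) {
    resp <- sample.int(9, T_len, replace = TRUE)
    expect_equal(
      sequence_loglik(model_params("dist2", epsilon = 0, delta = 0), resp, kp),
      (T_len - 1) * log(1 / 9), tolerance = 1e-12)
  }
})

test_that("sequence log-likelihood equals the brute-force oracle", {
  thetas <- list(
    yousif2  = c(epsilon = -0.7, eta = 0.45),
    dist2    = c(epsilon = -0.4, delta = -0.3),
    cyc3_lin = c(epsilon = -0.4, delta = -0.3, beta = 0.15),
    cyc3_log = c(epsilon = -0.41, delta = -0.32, beta = 0.77))
  for (v in names(thetas)) {
    th <- thetas[[v]]
    params <- do.call(model_params, c(list(variant = v), as.list(th)))
    expect_equal(sequence_loglik(params, worked_sequence, kp),
                 oracle_loglik(v, th, worked_sequence),
                 tolerance = 1e-10)
  }
})

test_that("log-likelihood is maximal at the MLE", {
  set.seed(5)
  resp <- simulate_sequence(
    model_params("dist2", epsilon = -0.5, delta = -0.2), 300, kp, seed = 2)
  mle <- fit_mle("dist2", resp, kp)
  ll_hat <- attr(mle, "loglik")
  for (i in 1:10) {
    other <- model_params("dist2", epsilon = runif(1, -3, 3),
                          delta = runif(1, -3, 3))
    expect_lte(sequence_loglik(other, resp, kp), ll_hat + 1e-9)
  }
})

test_that("too-short sequences are rejected", {
  expect_error(sequence_loglik(model_params("dist2", epsilon = 0, delta = 0),
                               5, kp), "length >= 2")
})
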