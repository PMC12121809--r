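#' Maximum-likelihood fit of a choice model to one sequence
#'
#' Box-constrained (each parameter in `[-10, 10]`, the support of the
#' hierarchical hyperprior) maximization of [sequence_loglik()] by
#' L-BFGS-B with an analytic gradient, from a fixed table of five starting
#' points inside `[-2, 2]` so that the result is deterministic.
#'
#' @param variant model variant tag (see [model_params()]).
#' @param seq an [rng_sequence()] or integer response vector.
#' @param layout a [keypad_layout()].
#' @param lower,upper box constraints applied to every parameter.
#' @return An [model_params()] object with attributes `loglik` (the
#'   achieved log-likelihood) and `convergence` (0 = converged for the
#'   best start).
#' @examples
#' p <- model_params("dist2", epsilon = -0.4, delta = -0.3)
#' s <- simulate_sequence(p, 500, seed = 7)
#' fit_mle("dist2", s)
#' @export
fit_mle <- function(variant, seq, layout = keypad_layout("grid3x3"),
                    lower = -10, upper = 10) {
  variant <- match.arg(tolower(variant), model_variants())
  feats <- encode_features(seq, layout)
  X <- variant_design(variant, feats)
  p <- length(X)
  starts <- mle_start_table(p)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn = function(th) -loglik_from_features(th, X, feats$y),
                   gr = function(th) -loglik_gradient(th, X, feats$y),
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    stop("maximum-likelihood optimization failed from every start")
  out <- params_from_vector(variant, best$par)
  attr(out, "loglik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

# fixed multi-start table: origin plus four spread points in [-2, 2]
mle_start_table <- function(p) {
  base <- rbind(rep(0, 3),
                c(-1.5, -1.0, 1.0),
                c(1.5, 1.0, -1.0),
                c(-0.5, 0.5, 0.5),
                c(2.0, -2.0, 2.0))
  base[, seq_len(p), drop = FALSE]
}

#' Hierarchical Bayesian fit of a choice model to a cohort
#'
#' Joint estimation of per-participant bias parameters and their
#' population distribution.  Each participant's parameter (for every
#' parameter of the variant) is assumed normally distributed across the
#' population, `theta_n ~ N(mu, sigma^2)`, with uniform hyperpriors:
#' `mu ~ U(-10, 10)` and `sigma ~ U(0, 10)`.
#'
#' Sampling uses the package's adaptive Metropolis-within-Gibbs scheme:
#' a joint random-walk Metropolis update of each participant's parameter
#' vector (proposal scales adapted during warmup toward an acceptance
#' rate of about 0.3), a conjugate truncated-normal Gibbs draw for each
#' population mean, and a log-scale random-walk update for each
#' population SD.  Split-R-hat and effective sample size are reported for
#' every hyperparameter.
#'
#' @param variant model variant tag (see [model_params()]).
#' @param seqs a list of [rng_sequence()] objects (>= 2).
#' @param layout a [keypad_layout()].
#' @param chains number of independent chains (>= 2 for diagnostics).
#' @param iter posterior draws kept per chain (after warmup).
#' @param warmup adaptation iterations discarded per chain.
#' @param seed integer master seed (one child stream per chain).
#' @param init_range chains are initialized uniformly in this range
#'   (population SDs in `(0.1, 2]`).
#' @param rhat_max convergence threshold; hyperparameters with split-R-hat
#'   above it trigger a warning attached to the result.
#' @return An object of class `rng_hfit`: a list with
#'   \describe{
#'     \item{`participants`}{data frame of per-participant posterior mean
#'       (and SD) estimates, one row per participant.}
#'     \item{`hyper`}{data frame of hyperparameter summaries: posterior
#'       mean, SD, 2.5/97.5 percentiles, split-R-hat, effective sample
#'       size.}
#'     \item{`draws`}{`iter x chains x n_hyper` array of hyperparameter
#'       draws.}
#'     \item{`config`}{sampler configuration record.}
#'     \item{`warnings`}{character vector of convergence warnings.}
#'   }
#' @export
fit_hierarchical <- function(variant, seqs, layout = keypad_layout("grid3x3"),
                             chains = 4L, iter = 1000L, warmup = 1000L,
                             seed = 1L, init_range = c(-2, 2),
                             rhat_max = 1.01) {
  variant <- match.arg(tolower(variant), model_variants())
  if (!is.list(seqs) || length(seqs) < 2L)
    stop("hierarchical fitting needs a list of >= 2 sequences")
  chains <- as.integer(chains); iter <- as.integer(iter)
  warmup <- as.integer(warmup)
  pn <- variant_param_names(variant)
  p <- length(pn)
  N <- length(seqs)
  data <- lapply(seqs, function(s) {
    feats <- encode_features(s, layout)
    list(X = variant_design(variant, feats), y = feats$y)
  })
  ids <- vapply(seqs, function(s)
    if (inherits(s, "rng_sequence")) s$participant_id else NA_character_,
    character(1))
  if (anyNA(ids) || anyDuplicated(ids)) ids <- paste0("s", seq_len(N))

  chain_seeds <- spawn_seeds(seed, chains)
  runs <- lapply(seq_len(chains), function(ch)
    run_mwg_chain(data, p, iter, warmup, chain_seeds[ch], init_range))

  hyper_names <- c(paste0("mu_", pn), paste0("sigma_", pn))
  draws <- array(NA_real_, dim = c(iter, chains, 2L * p),
                 dimnames = list(NULL, NULL, hyper_names))
  for (ch in seq_len(chains)) draws[, ch, ] <- runs[[ch]]$hyper_draws

  hyper <- data.frame(
    hyperparameter = hyper_names,
    mean  = apply(draws, 3L, mean),
    sd    = apply(draws, 3L, stats::sd),
    q2.5  = apply(draws, 3L, stats::quantile, probs = 0.025),
    q97.5 = apply(draws, 3L, stats::quantile, probs = 0.975),
    rhat  = vapply(seq_len(2L * p), function(j) split_rhat(draws[, , j]),
                   numeric(1)),
    ess   = vapply(seq_len(2L * p), function(j) ess_basic(draws[, , j]),
                   numeric(1)),
    row.names = NULL)

  # posterior means/SDs of participant parameters, pooled over chains
  theta_mean <- Reduce(`+`, lapply(runs, `[[`, "theta_sum")) / (chains * iter)
  theta_sq <- Reduce(`+`, lapply(runs, `[[`, "theta_sumsq")) / (chains * iter)
  theta_sd <- sqrt(pmax(theta_sq - theta_mean^2, 0))
  participants <- data.frame(participant_id = ids, theta_mean)
  names(participants)[-1L] <- pn
  sd_df <- as.data.frame(theta_sd)
  names(sd_df) <- paste0(pn, "_sd")
  participants <- cbind(participants, sd_df)

  warn <- character(0)
  viol <- hyper$hyperparameter[hyper$rhat > rhat_max]
  if (length(viol))
    warn <- c(warn, paste0("split-R-hat above ", rhat_max, " for: ",
                           paste(viol, collapse = ", ")))
  structure(
    list(participants = participants, hyper = hyper, draws = draws,
         config = list(variant = variant, chains = chains, iter = iter,
                       warmup = warmup, seed = seed,
                       init_range = init_range, rhat_max = rhat_max,
                       n_participants = N),
         warnings = warn),
    class = "rng_hfit")
}

#' @export
print.rng_hfit <- function(x, ...) {
  cfg <- x$config
  cat("<rng_hfit>", cfg$variant, "-", cfg$n_participants, "participants,",
      cfg$chains, "chains x", cfg$iter, "draws (warmup", cfg$warmup, ")\n")
  print(x$hyper, digits = 3)
  if (length(x$warnings)) cat("warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}

# one Metropolis-within-Gibbs chain; returns hyper draws and theta moments.
# Participant updates are joint random-walk Metropolis with per-coordinate
# proposal SDs tracking the running posterior SD (adapted during warmup);
# population means are truncated-normal Gibbs draws; population SDs are
# exact inverse-chi-square Gibbs draws (the uniform prior on sigma gives
# sigma^2 | theta, mu ~ Inv-Gamma((N-1)/2, SS/2), truncated at sigma = 10).
run_mwg_chain <- function(data, p, iter, warmup, seed, init_range) {
  set.seed(seed)
  N <- length(data)
  theta <- matrix(stats::runif(N * p, init_range[1], init_range[2]), N, p)
  mu <- stats::runif(p, init_range[1], init_range[2])
  sigma <- stats::runif(p, 0.1, 2)
  loglik_n <- vapply(seq_len(N), function(n)
    loglik_from_features(theta[n, ], data[[n]]$X, data[[n]]$y), numeric(1))

  log_scale <- rep(log(2.38 / sqrt(p)), N)  # global factor per participant
  prop_sd <- matrix(0.3, N, p)              # per-coordinate posterior SD est.
  run_mean <- theta; run_m2 <- matrix(0, N, p); run_n <- 0L
  acc <- numeric(N); batch <- 0L

  hyper_draws <- matrix(NA_real_, iter, 2L * p)
  theta_sum <- matrix(0, N, p)
  theta_sumsq <- matrix(0, N, p)

  total <- warmup + iter
  for (it in seq_len(total)) {
    adapting <- it <= warmup
    # --- participant-level joint RW Metropolis (three sweeps) ---
    scl <- exp(log_scale)
    for (sweep in 1:3) {
      noise <- matrix(stats::rnorm(N * p), N, p) * prop_sd * scl
      log_u <- log(stats::runif(N))
      for (n in seq_len(N)) {
        prop <- theta[n, ] + noise[n, ]
        if (all(abs(prop) <= 10)) {
          ll_prop <- loglik_from_features(prop, data[[n]]$X, data[[n]]$y)
          log_r <- (ll_prop - loglik_n[n]) +
            sum(stats::dnorm(prop, mu, sigma, log = TRUE) -
                stats::dnorm(theta[n, ], mu, sigma, log = TRUE))
          if (log_u[n] < log_r) {
            theta[n, ] <- prop
            loglik_n[n] <- ll_prop
            acc[n] <- acc[n] + 1 / 3
          }
        }
      }
    }
    # --- population means: conjugate truncated-normal Gibbs ---
    for (j in seq_len(p)) {
      m <- mean(theta[, j])
      s <- sigma[j] / sqrt(N)
      lo <- stats::pnorm(-10, m, s); hi <- stats::pnorm(10, m, s)
      mu[j] <- stats::qnorm(lo + stats::runif(1) * (hi - lo), m, s)
    }
    # --- population SDs: conjugate scaled-inverse-chi-square Gibbs ---
    for (j in seq_len(p)) {
      ss <- sum((theta[, j] - mu[j])^2)
      for (try in 1:100) {
        s2 <- ss / stats::rchisq(1, df = N - 1)
        if (s2 <= 100) { sigma[j] <- sqrt(s2); break }
      }
    }
    # --- proposal adaptation during warmup ---
    if (adapting) {
      run_n <- run_n + 1L
      d <- theta - run_mean
      run_mean <- run_mean + d / run_n
      run_m2 <- run_m2 + d * (theta - run_mean)
      if (it %% 50L == 0L) {
        batch <- batch + 1L
        step <- min(0.5, 1 / sqrt(batch))
        log_scale <- log_scale + step * (acc / 50 - 0.3)
        if (run_n > 100L)
          prop_sd <- sqrt(run_m2 / (run_n - 1L)) + 1e-3
        acc[] <- 0
      }
    }
    if (!adapting) {
      k <- it - warmup
      hyper_draws[k, ] <- c(mu, sigma)
      theta_sum <- theta_sum + theta
      theta_sumsq <- theta_sumsq + theta^2
    }
  }
  list(hyper_draws = hyper_draws, theta_sum = theta_sum,
       theta_sumsq = theta_sumsq)
}

#' Split-R-hat for a single quantity
#'
#' Classic potential-scale-reduction diagnostic with each chain split in
#' half, so within-chain trends inflate the statistic.
#'
#' @param x an `iterations x chains` matrix of draws.
#' @return The split-R-hat value (near 1 indicates convergence).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- n %/% 2L
  if (half < 2L || ncol(x) < 1L) return(NA_real_)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(ch)
    cbind(x[seq_len(half), ch], x[(n - half + 1L):n, ch])))
  m <- ncol(halves)
  if (m < 2L) return(NA_real_)
  means <- colMeans(halves)
  vars <- apply(halves, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# basic effective sample size from pooled split chains (Geyer initial
# positive sequence on the chain-averaged autocorrelation)
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  max_lag <- min(n - 2L, 200L)
  acov <- matrix(0, max_lag + 1L, m)
  for (ch in seq_len(m)) {
    v <- x[, ch] - mean(x[, ch])
    a <- stats::acf(v, lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = FALSE)$acf[, 1, 1]
    acov[, ch] <- a
  }
  W <- mean(acov[1L, ]) * n / (n - 1)
  var_plus <- W * (n - 1) / n + stats::var(colMeans(x))
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # sum initial positive pairs
  tau <- 0; lag <- 1L
  while (lag + 1L <= max_lag) {
    pair <- rho[lag + 1L] + rho[lag + 2L]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + pair
    lag <- lag + 2L
  }
  max(n * m / (1 + 2 * tau), 1)
}

#' Convergence check for a hierarchical fit
#'
#' @param fit an `rng_hfit` from [fit_hierarchical()].
#' @param rhat_max maximum acceptable split-R-hat.
#' @return A list with `pass` (logical), `violations` (hyperparameter
#'   names with R-hat above the threshold) and the hyperparameter table.
#' @export
check_convergence <- function(fit, rhat_max = 1.01) {
  stopifnot(inherits(fit, "rng_hfit"))
  if (fit$config$chains < 2L)
    stop("split-R-hat requires at least 2 chains")
  viol <- fit$hyper$hyperparameter[fit$hyper$rhat > rhat_max]
  list(pass = length(viol) == 0L, violations = viol, hyper = fit$hyper)
}
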