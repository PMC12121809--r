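#' Per-trial predictive accuracy with tie splitting
#'
#' Scores how well a parameterized model predicts each response of a
#' sequence from the true preceding history (responses `2..T`).  Each
#' trial earns credit 1 if the realized response is the unique modal
#' (highest-probability) prediction, `1/n` if it ties among `n` modal
#' candidates, and 0 otherwise; the score is the mean credit.  Under the
#' all-zero-parameter model every digit ties every trial, so the score is
#' exactly the chance base rate `1/K` (11.1% for nine digits).
#'
#' Ties are detected with a relative tolerance of `1e-9` on the
#' probabilities: the symmetric keypad geometry makes exact ties real, not
#' numerical noise.
#'
#' @param params an [model_params()] object.
#' @param seq an [rng_sequence()] or integer response vector.
#' @param layout a [keypad_layout()].
#' @param tie_tol relative tie tolerance on probabilities.
#' @return A list of class `prediction_score`: `participant_id`,
#'   `mean_hit` (in `[0, 1]`), `n_predictions`, and the per-trial vector
#'   `credits`.
#' @examples
#' p0 <- model_params("dist2", epsilon = 0, delta = 0)
#' predictive_accuracy(p0, c(1, 5, 9, 2, 6))$mean_hit  # exactly 1/9
#' @export
predictive_accuracy <- function(params, seq, layout = keypad_layout("grid3x3"),
                                tie_tol = 1e-9) {
  stopifnot(inherits(params, "rng_model_params"))
  seq <- as_rng_sequence(seq, K = layout$K)
  feats <- encode_features(seq, layout)
  P <- prob_matrix(param_vector(params),
                   variant_design(params$variant, feats))
  n <- length(feats$y)
  credits <- vapply(seq_len(n), function(t) {
    p <- P[t, ]
    top <- max(p)
    modal <- which(p >= top * (1 - tie_tol))
    if (feats$y[t] %in% modal) 1 / length(modal) else 0
  }, numeric(1))
  structure(list(participant_id = seq$participant_id,
                 mean_hit = mean(credits), n_predictions = n,
                 credits = credits),
            class = "prediction_score")
}

#' @export
print.prediction_score <- function(x, ...) {
  cat(sprintf("<prediction_score> %s: mean hit %.2f%% over %d predictions\n",
              x$participant_id, 100 * x$mean_hit, x$n_predictions))
  invisible(x)
}

#' Paired comparison of two models' per-participant accuracies
#'
#' Paired t-test of matched accuracy vectors, with Cohen's d for
#' dependent measures computed as `mean(diff) / S_within` where
#' `S_within = sd(diff) / sqrt(2 (1 - r))` and `r` is the correlation of
#' the two accuracy vectors, plus the percentage of participants for whom
#' model b beats model a.
#'
#' @param acc_a,acc_b equal-length numeric vectors of per-participant
#'   accuracies under models a and b (same participants, same order).
#' @return A list with `t`, `df`, `p`, `cohens_d`, `pct_b_better`, `n`.
#' @export
paired_model_comparison <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b))
    stop("accuracy vectors must be paired (equal length)")
  n <- length(acc_a)
  if (n < 3L) stop("need at least 3 paired observations")
  d <- acc_b - acc_a
  pct <- 100 * mean(acc_b > acc_a)
  if (stats::sd(d) < 1e-10 * max(1, abs(d))) {
    if (max(abs(d)) == 0) {
      warning("identical accuracy vectors: degenerate comparison")
      return(list(t = 0, df = n - 1L, p = 1, cohens_d = 0,
                  pct_b_better = pct, n = n))
    }
    stop("zero-variance non-zero differences: paired test undefined")
  }
  tt <- stats::t.test(acc_b, acc_a, paired = TRUE)
  r <- stats::cor(acc_a, acc_b)
  s_within <- stats::sd(d) / sqrt(2 * (1 - r))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = mean(d) / s_within,
       pct_b_better = pct, n = n)
}

#' Bootstrap out-of-bag classification of sequence sources
#'
#' Quantifies how well a single randomness measure separates two labeled
#' groups of sequences (e.g. human-generated vs model-generated).  Per
#' bootstrap iteration: pool both groups, draw `n_draw` units with
#' replacement, fit an intercept-plus-slope logistic regression of group
#' label on the measure, classify the out-of-bag (undrawn) units at
#' probability threshold 0.5, and record the correct classification rate.
#' Returns the mean rate and its empirical 2.5/97.5 percentiles over
#' iterations; 50% means the measure separates the groups only at chance.
#'
#' @param values_human measure values of the first group.
#' @param values_other measure values of the second group.
#' @param iters bootstrap iterations.
#' @param n_draw resamples per iteration; defaults to twice the first
#'   group's size (pairing each unit of one source with one of the other).
#' @param seed integer seed, or `NULL`.
#' @param measure label stored in the result.
#' @return A list of class `classification_result`: `measure`,
#'   `mean_correct`, `ci_low`, `ci_high` (percentages), `iters`,
#'   `converged` (fraction of iterations in which the logistic fit
#'   converged).
#' @export
bootstrap_classification <- function(values_human, values_other,
                                     iters = 1000L, n_draw = NULL,
                                     seed = NULL, measure = "measure") {
  vh <- values_human[is.finite(values_human)]
  vo <- values_other[is.finite(values_other)]
  if (!length(vh) || !length(vo))
    stop("both groups must contain finite measure values")
  if (is.null(n_draw)) n_draw <- 2L * length(vh)
  if (!is.null(seed)) set.seed(seed)
  x <- c(vh, vo)
  lab <- c(rep(0L, length(vh)), rep(1L, length(vo)))
  n_pool <- length(x)
  rates <- numeric(iters)
  conv <- logical(iters)
  for (b in seq_len(iters)) {
    idx <- sample.int(n_pool, n_draw, replace = TRUE)
    oob <- setdiff(seq_len(n_pool), idx)
    if (!length(oob) || length(unique(lab[idx])) < 2L) {
      rates[b] <- NA_real_
      next
    }
    fit <- suppressWarnings(
      stats::glm(lab[idx] ~ x[idx], family = stats::binomial(),
                 control = stats::glm.control(maxit = 50L)))
    conv[b] <- fit$converged
    eta <- stats::coef(fit)[1] + stats::coef(fit)[2] * x[oob]
    pred <- as.integer(eta > 0)          # probability 0.5 threshold
    rates[b] <- mean(pred == lab[oob])
  }
  rates <- 100 * rates[is.finite(rates)]
  structure(list(measure = measure, mean_correct = mean(rates),
                 ci_low = unname(stats::quantile(rates, 0.025)),
                 ci_high = unname(stats::quantile(rates, 0.975)),
                 iters = length(rates), converged = mean(conv)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s: %.2f%% [%.2f%%, %.2f%%] (%d iterations)\n",
              x$measure, x$mean_correct, x$ci_low, x$ci_high, x$iters))
  invisible(x)
}

#' Default simulation ranges for the recovery study
#'
#' The published recovery design draws true parameters uniformly between
#' the 2.5th and 97.5th percentiles of the individual-level estimates of
#' a large human cohort.  Without that cohort shipped, the default ranges
#' are the normal-implied percentiles `mu +/- 1.96 sigma` of the reported
#' population hyperparameters of the logarithmic cycling model
#' (epsilon: mean -0.41, SD 1.48; delta: mean -0.32, SD 0.69; beta:
#' mean 0.77, SD 0.37).
#'
#' @param variant model variant tag.
#' @return A named list of `c(low, high)` ranges per parameter.
#' @export
default_recovery_ranges <- function(variant = "cyc3_log") {
  hyper <- list(epsilon = c(-0.41, 1.48), eta = c(0, 1),
                delta = c(-0.32, 0.69), beta = c(0.77, 0.37))
  pn <- variant_param_names(variant)
  stats::setNames(lapply(pn, function(p)
    hyper[[p]][1] + c(-1.96, 1.96) * hyper[[p]][2]), pn)
}

#' Parameter-recovery study
#'
#' Draws true parameter vectors uniformly within per-parameter ranges,
#' simulates one sequence per draw, refits the same model variant, and
#' reports the correlation between true and fitted values per parameter
#' together with the cross-correlation matrix of the fitted values
#' (which should be near zero if the biases are estimated independently).
#'
#' @param variant model variant tag.
#' @param n_seq number of simulated sequences (the published design uses
#'   250).
#' @param length responses per sequence.
#' @param ranges named list of `c(low, high)` per parameter; defaults to
#'   [default_recovery_ranges()].
#' @param layout a [keypad_layout()].
#' @param seed integer master seed.
#' @param fit_method `"hierarchical"` (default) fits all simulated
#'   sequences jointly with [fit_hierarchical()] and takes per-sequence
#'   posterior means, mirroring the hierarchical estimation used
#'   throughout; shrinkage keeps weakly identified parameters (e.g. the
#'   repetition weight of a sequence containing no repetitions at all)
#'   off the `[-10, 10]` boundary.  `"mle"` fits each sequence separately
#'   with [fit_mle()]; it is faster but boundary estimates from
#'   degenerate sequences can depress the recovery correlations.
#' @param mcmc list of sampler settings for the hierarchical fit
#'   (`chains`, `iter`, `warmup`).
#' @return A list of class `recovery_result`: `recovery` (named vector of
#'   true-vs-fitted correlations), `cross_correlation` (correlation
#'   matrix of fitted values), `table` (data frame of true and fitted
#'   values), `n_failed` (fits that errored, excluded).
#' @export
recovery_study <- function(variant = "cyc3_log", n_seq = 250L, length = 200L,
                           ranges = default_recovery_ranges(variant),
                           layout = keypad_layout("grid3x3"), seed = 1L,
                           fit_method = c("hierarchical", "mle"),
                           mcmc = list(chains = 4L, iter = 1000L,
                                       warmup = 1000L)) {
  variant <- match.arg(tolower(variant), model_variants())
  fit_method <- match.arg(fit_method)
  pn <- variant_param_names(variant)
  if (!setequal(names(ranges), pn))
    stop("`ranges` must name exactly the parameters: ",
         paste(pn, collapse = ", "))
  for (p in pn) {
    rg <- ranges[[p]]
    if (length(rg) != 2L || !all(is.finite(rg)) || rg[1] > rg[2])
      stop("range for '", p, "' must be finite c(low, high) with low <= high")
  }
  degenerate <- vapply(ranges[pn], function(rg) rg[1] == rg[2], logical(1))
  seeds <- spawn_seeds(seed, 2L)
  set.seed(seeds[1])
  true <- vapply(pn, function(p)
    stats::runif(n_seq, ranges[[p]][1], ranges[[p]][2]), numeric(n_seq))
  true <- matrix(true, nrow = n_seq, dimnames = list(NULL, pn))
  sim_seeds <- spawn_seeds(seeds[2], n_seq)
  fitted <- matrix(NA_real_, n_seq, length(pn), dimnames = list(NULL, pn))
  n_failed <- 0L
  seqs <- vector("list", n_seq)
  for (i in seq_len(n_seq)) {
    pars <- params_from_vector(variant, true[i, ])
    set.seed(sim_seeds[i])
    seqs[[i]] <- rng_sequence(
      generate_responses(pars, as.integer(length), layout),
      participant_id = paste0("rec", i), K = layout$K)
  }
  if (fit_method == "hierarchical") {
    hfit <- fit_hierarchical(variant, seqs, layout, chains = mcmc$chains,
                             iter = mcmc$iter, warmup = mcmc$warmup,
                             seed = seeds[1])
    fitted[, pn] <- as.matrix(hfit$participants[, pn])
  } else {
    for (i in seq_len(n_seq)) {
      est <- tryCatch(fit_mle(variant, seqs[[i]], layout),
                      error = function(e) NULL)
      if (is.null(est)) n_failed <- n_failed + 1L
      else fitted[i, ] <- param_vector(est)
    }
  }
  ok <- stats::complete.cases(fitted)
  recovery <- vapply(pn, function(p) {
    if (degenerate[[p]] || sum(ok) < 3L) NA_real_
    else stats::cor(true[ok, p], fitted[ok, p])
  }, numeric(1))
  cross <- if (sum(ok) >= 3L) stats::cor(fitted[ok, , drop = FALSE])
           else matrix(NA_real_, length(pn), length(pn),
                       dimnames = list(pn, pn))
  tab <- data.frame(true, fitted)
  names(tab) <- c(paste0("true_", pn), paste0("fitted_", pn))
  structure(list(variant = variant, recovery = recovery,
                 cross_correlation = cross, table = tab,
                 n_failed = n_failed, degenerate = degenerate),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("<recovery_result>", x$variant, "- true-vs-fitted correlations:\n")
  print(round(x$recovery, 3))
  cat("cross-correlations of fitted values:\n")
  print(round(x$cross_correlation, 3))
  if (x$n_failed) cat(x$n_failed, "fits failed and were excluded\n")
  invisible(x)
}
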