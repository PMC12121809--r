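#' Model variants and their parameters
#'
#' Four nested softmax choice models of number generation are supported.
#' Writing `z_i` for the linear predictor of digit `i`, the choice
#' probability is `exp(z_i) / sum_j exp(z_j)` with
#' \describe{
#'   \item{`"yousif2"`}{`z_i = eps * r_i + eta * s_i` — repetition plus
#'     side-switching (the original two-parameter model).}
#'   \item{`"dist2"`}{`z_i = eps * r_i + delta * d_i` — repetition plus
#'     keypad distance.}
#'   \item{`"cyc3_lin"`}{`z_i = eps * r_i + delta * d_i + beta * g_i` —
#'     adds a cycling bias linear in the gap since digit `i` was last
#'     produced.}
#'   \item{`"cyc3_log"`}{`z_i = eps * r_i + delta * d_i + beta * log2(g_i)`
#'     — cycling bias on a base-2 logarithmic gap scale, so the pull of a
#'     long-unused digit saturates.}
#' }
#' Positive `eps` favours immediate repetitions, negative `eps` avoids
#' them; negative `delta` favours digits close to the previous one on the
#' keypad; positive `beta` reproduces the gambler's-fallacy tendency to
#' cycle through all digits too quickly.  A value of 0 means no bias.
#'
#' @param variant one of `"yousif2"`, `"dist2"`, `"cyc3_lin"`,
#'   `"cyc3_log"` (case-insensitive).
#' @param epsilon repetition weight (all variants).
#' @param eta side-switching weight (`"yousif2"` only).
#' @param delta distance weight (all but `"yousif2"`).
#' @param beta cycling weight (`"cyc3_lin"`, `"cyc3_log"`).
#' @return An object of class `rng_model_params`.
#' @examples
#' model_params("cyc3_log", epsilon = -0.41, delta = -0.32, beta = 0.77)
#' @export
model_params <- function(variant, epsilon = 0, eta = NULL, delta = NULL,
                         beta = NULL) {
  variant <- match.arg(tolower(variant), model_variants())
  need <- variant_param_names(variant)
  given <- list(epsilon = epsilon, eta = eta, delta = delta, beta = beta)
  extra <- setdiff(names(given)[!vapply(given, is.null, logical(1))], need)
  if (length(extra))
    stop("parameter(s) ", paste(extra, collapse = ", "),
         " are not part of variant '", variant, "'")
  vals <- lapply(need, function(p) {
    v <- given[[p]]
    if (is.null(v))
      stop("variant '", variant, "' requires parameter '", p, "'")
    v <- as.numeric(v)
    if (length(v) != 1L || !is.finite(v))
      stop("parameter '", p, "' must be a single finite number")
    v
  })
  names(vals) <- need
  structure(c(list(variant = variant), vals), class = "rng_model_params")
}

#' @rdname model_params
#' @export
model_variants <- function() c("yousif2", "dist2", "cyc3_lin", "cyc3_log")

#' @rdname model_params
#' @export
variant_param_names <- function(variant) {
  switch(match.arg(tolower(variant), model_variants()),
         yousif2  = c("epsilon", "eta"),
         dist2    = c("epsilon", "delta"),
         cyc3_lin = c("epsilon", "delta", "beta"),
         cyc3_log = c("epsilon", "delta", "beta"))
}

#' @export
print.rng_model_params <- function(x, ...) {
  pn <- variant_param_names(x$variant)
  cat("<rng_model_params>", x$variant, ":",
      paste(sprintf("%s = %.4g", pn, unlist(x[pn])), collapse = ", "), "\n")
  invisible(x)
}

# numeric parameter vector in canonical order for a variant
param_vector <- function(params) {
  pn <- variant_param_names(params$variant)
  stats::setNames(vapply(pn, function(p) params[[p]], numeric(1)), pn)
}

params_from_vector <- function(variant, theta) {
  pn <- variant_param_names(variant)
  do.call(model_params, c(list(variant = variant),
                          stats::setNames(as.list(theta), pn)))
}

# stack the design matrices the variant's linear predictor needs, in the
# same order as param_vector(); feats comes from encode_features()
variant_design <- function(variant, feats) {
  switch(variant,
         yousif2  = list(epsilon = feats$R, eta = feats$S),
         dist2    = list(epsilon = feats$R, delta = feats$D),
         cyc3_lin = list(epsilon = feats$R, delta = feats$D, beta = feats$G),
         cyc3_log = list(epsilon = feats$R, delta = feats$D,
                         beta = log2(feats$G)))
}

# row-wise log-sum-exp, stabilized
row_logsumexp <- function(Z) {
  m <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  m + log(rowSums(exp(Z - m)))
}

# linear predictor matrix for a parameter vector over a design list
linear_predictor <- function(theta, X) {
  Z <- theta[[1L]] * X[[1L]]
  for (j in seq_along(X)[-1L]) Z <- Z + theta[[j]] * X[[j]]
  Z
}

#' Choice probabilities for one prediction step
#'
#' Evaluates the softmax over the `K` digits for a model variant, given
#' the feature state of the current step.
#'
#' @param params an [model_params()] object.
#' @param state a [feature_state()] (a list with `r`, `s`, `d`, `g` as the
#'   variant requires; the gap `g` must have all entries `>= 1`).
#' @return A probability vector of length `K` (entries in (0,1), summing
#'   to 1).
#' @examples
#' kp <- keypad_layout("grid3x3")
#' st <- feature_state(prev = 3, gap = update_gap(init_gap(9), 3), kp)
#' choice_probabilities(model_params("dist2", epsilon = 1, delta = 0), st)
#' @export
choice_probabilities <- function(params, state) {
  stopifnot(inherits(params, "rng_model_params"))
  v <- params$variant
  feat_of <- function(name, required) {
    x <- state[[name]]
    if (required && is.null(x))
      stop("feature '", name, "' is required by variant '", v, "'")
    x
  }
  r <- feat_of("r", TRUE)
  z <- params$epsilon * r
  if (v == "yousif2") {
    z <- z + params$eta * feat_of("s", TRUE)
  } else {
    z <- z + params$delta * feat_of("d", TRUE)
  }
  if (v %in% c("cyc3_lin", "cyc3_log")) {
    g <- feat_of("g", TRUE)
    if (any(g < 1)) stop("gap entries must be >= 1")
    z <- z + params$beta * (if (v == "cyc3_log") log2(g) else g)
  }
  if (any(!is.finite(z))) stop("non-finite linear predictor")
  w <- exp(z - max(z))
  w / sum(w)
}

#' Log-likelihood of a response sequence under a choice model
#'
#' Sums, over responses `2..T`, the log probability the model assigns to
#' the response actually produced, with the feature state rebuilt from the
#' realized history at each step.  The first response contributes no term
#' (it has no defined features).
#'
#' @param params an [model_params()] object.
#' @param seq an [rng_sequence()] or integer response vector.
#' @param layout a [keypad_layout()].
#' @return The log-likelihood (a single negative number).
#' @examples
#' kp <- keypad_layout("grid3x3")
#' p <- model_params("cyc3_log", epsilon = -0.4, delta = -0.3, beta = 0.8)
#' sequence_loglik(p, c(1, 5, 9, 2, 6, 4), kp)
#' @export
sequence_loglik <- function(params, seq, layout = keypad_layout("grid3x3")) {
  stopifnot(inherits(params, "rng_model_params"))
  feats <- encode_features(seq, layout)
  loglik_from_features(param_vector(params),
                       variant_design(params$variant, feats), feats$y)
}

# core log-likelihood on precomputed designs; theta in canonical order
loglik_from_features <- function(theta, X, y) {
  Z <- linear_predictor(theta, X)
  n <- length(y)
  sum(Z[cbind(seq_len(n), y)]) - sum(row_logsumexp(Z))
}

# analytic gradient of loglik_from_features w.r.t. theta
loglik_gradient <- function(theta, X, y) {
  Z <- linear_predictor(theta, X)
  P <- exp(Z - row_logsumexp(Z))
  n <- length(y)
  idx <- cbind(seq_len(n), y)
  vapply(X, function(Xj) sum(Xj[idx]) - sum(P * Xj), numeric(1))
}

# softmax probability matrix over trials for precomputed designs
prob_matrix <- function(theta, X) {
  Z <- linear_predictor(theta, X)
  exp(Z - row_logsumexp(Z))
}
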