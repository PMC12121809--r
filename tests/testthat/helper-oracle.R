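# Independent brute-force oracle for the choice models, written naively
# (per-trial loops, its own geometry and gap bookkeeping) so that tests of
# the package's vectorized likelihood/scorer check against a second route.

oracle_coords <- function(n, kind = "grid3x3") {
  if (kind == "grid3x3") c((n - 1) %/% 3 + 1, (n - 1) %% 3 + 1)
  else c(n, 0)
}

oracle_distance <- function(a, b, kind = "grid3x3") {
  pa <- oracle_coords(a, kind); pb <- oracle_coords(b, kind)
  sqrt(sum((pa - pb)^2))
}

oracle_side <- function(i) if (i <= 4) -1 else if (i == 5) 0 else 1

# probabilities of the next response given the full history, rebuilt from
# scratch: gap via last-occurrence positions (g_i = t - last_i + 1, with
# last_i = 0 for digits never seen after t trials)
oracle_probs <- function(variant, theta, history, K = 9, kind = "grid3x3") {
  t_now <- length(history)
  prev <- history[t_now]
  last <- integer(K)
  for (t in seq_len(t_now)) last[history[t]] <- t
  g <- t_now - last + 1
  z <- numeric(K)
  for (i in seq_len(K)) {
    z[i] <- theta[["epsilon"]] * as.numeric(i == prev)
    if (variant == "yousif2") {
      s_i <- if (prev == 5 || i == 5) 0
             else if (oracle_side(i) != oracle_side(prev)) 1 else -1
      z[i] <- z[i] + theta[["eta"]] * s_i
    } else {
      z[i] <- z[i] + theta[["delta"]] * oracle_distance(prev, i, kind)
    }
    if (variant == "cyc3_lin") z[i] <- z[i] + theta[["beta"]] * g[i]
    if (variant == "cyc3_log") z[i] <- z[i] + theta[["beta"]] * log(g[i]) / log(2)
  }
  exp(z) / sum(exp(z))
}

oracle_loglik <- function(variant, theta, responses, K = 9, kind = "grid3x3") {
  ll <- 0
  for (t in 2:length(responses)) {
    p <- oracle_probs(variant, theta, responses[1:(t - 1)], K, kind)
    ll <- ll + log(p[responses[t]])
  }
  ll
}

oracle_accuracy <- function(variant, theta, responses, K = 9, kind = "grid3x3") {
  credits <- numeric(length(responses) - 1)
  for (t in 2:length(responses)) {
    p <- oracle_probs(variant, theta, responses[1:(t - 1)], K, kind)
    modal <- which(p >= max(p) * (1 - 1e-9))
    credits[t - 1] <- if (responses[t] %in% modal) 1 / length(modal) else 0
  }
  mean(credits)
}

# a fixed 10-trial worked sequence used by several oracle-equivalence tests
worked_sequence <- c(5, 2, 2, 8, 2, 9, 1, 6, 4, 7)
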