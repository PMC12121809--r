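#' Simulate a response sequence from a choice model
#'
#' The first response is drawn uniformly from `1..K` (every model needs a
#' starting number before it can predict); each later response is sampled
#' from the model's choice probabilities given the evolving history.
#'
#' Seeding: a master `seed` deterministically spawns an independent child
#' stream for the sequence, so that [simulate_cohort()] with the same
#' master seed reproduces the same sequences irrespective of how many are
#' drawn or in which order.  With `seed = NULL` the current RNG state is
#' used.
#'
#' @param params an [model_params()] object.
#' @param length number of responses to generate (`>= 1`).
#' @param layout a [keypad_layout()].
#' @param seed integer master seed, or `NULL`.
#' @param participant_id identifier for the returned sequence.
#' @return An [rng_sequence()].
#' @examples
#' p <- model_params("cyc3_log", epsilon = -0.4, delta = -0.3, beta = 0.8)
#' simulate_sequence(p, length = 20, seed = 1)
#' @export
simulate_sequence <- function(params, length, layout = keypad_layout("grid3x3"),
                              seed = NULL, participant_id = "sim1") {
  if (length < 1L) stop("`length` must be >= 1")
  if (!is.null(seed)) set.seed(spawn_seeds(seed, 1L))
  rng_sequence(generate_responses(params, as.integer(length), layout),
               participant_id = participant_id, K = layout$K)
}

# child-seed derivation: one master seed -> n independent child seeds
spawn_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  children <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  children
}

# sampling loop using the current RNG state
generate_responses <- function(params, length, layout) {
  stopifnot(inherits(params, "rng_model_params"))
  assert_layout(layout)
  K <- layout$K
  v <- params$variant
  if (v == "yousif2" && K != 9L)
    stop("the side-switching variant is defined only for the 9-digit task")
  eps <- params$epsilon
  resp <- integer(length)
  resp[1L] <- sample.int(K, 1L)
  if (length == 1L) return(resp)
  side_rows <- if (v == "yousif2")
    t(vapply(1:9, side_vector, numeric(9)))
  dmat <- layout$distances
  g <- rep(1L, K)
  for (t in 2:length) {
    prev <- resp[t - 1L]
    g <- g + 1L
    g[prev] <- 1L
    z <- if (v == "yousif2") params$eta * side_rows[prev, ]
         else params$delta * dmat[prev, ]
    z[prev] <- z[prev] + eps
    if (v == "cyc3_lin") z <- z + params$beta * g
    else if (v == "cyc3_log") z <- z + params$beta * log2(g)
    w <- exp(z - max(z))
    resp[t] <- sample.int(K, 1L, prob = w)
  }
  resp
}

#' Simulate a cohort of virtual participants
#'
#' For each parameter set, simulates `reps` sequences of the given length
#' (defaults: 20 replicate sequences of 200 responses per participant,
#' i.e. 4,000 simulated numbers per parameter set).
#'
#' @param param_sets a named list of [model_params()] objects (one per
#'   participant), or a single object.
#' @param reps replicate sequences per parameter set.
#' @param length responses per sequence.
#' @param layout a [keypad_layout()].
#' @param seed integer master seed, or `NULL`.
#' @return A list of [rng_sequence()] objects with participant ids
#'   `"<name>.r<rep>"`.
#' @export
simulate_cohort <- function(param_sets, reps = 20L, length = 200L,
                            layout = keypad_layout("grid3x3"), seed = NULL) {
  if (inherits(param_sets, "rng_model_params")) param_sets <- list(param_sets)
  if (!is.list(param_sets) || !length(param_sets))
    stop("`param_sets` must be a non-empty list of model_params")
  if (reps < 1L) stop("`reps` must be >= 1")
  if (is.null(names(param_sets)) || any(names(param_sets) == ""))
    names(param_sets) <- paste0("p", seq_along(param_sets))
  n_total <- length(param_sets) * reps
  children <- if (!is.null(seed)) spawn_seeds(seed, n_total)
  out <- vector("list", n_total)
  k <- 0L
  for (i in seq_along(param_sets)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      if (!is.null(children)) set.seed(children[k])
      out[[k]] <- rng_sequence(
        generate_responses(param_sets[[i]], as.integer(length), layout),
        participant_id = paste0(names(param_sets)[i], ".r", r),
        K = layout$K)
    }
  }
  names(out) <- vapply(out, function(s) s$participant_id, character(1))
  out
}

#' Random permutations of a sequence
#'
#' Produces `reps` uniformly random permutations of a sequence's
#' responses; each permutation holds the digit multiset fixed, giving a
#' random-like benchmark composed of exactly the same numbers.
#'
#' @param seq an [rng_sequence()] or integer response vector.
#' @param reps number of permutations.
#' @param seed integer master seed, or `NULL`.
#' @param K number of response alternatives (used when `seq` is a bare
#'   vector).
#' @return A list of [rng_sequence()] objects, ids `"<id>.perm<rep>"`.
#' @export
permute_sequence <- function(seq, reps = 20L, seed = NULL, K = 9L) {
  if (reps < 1L) stop("`reps` must be >= 1")
  seq <- as_rng_sequence(seq, K = K)
  children <- if (!is.null(seed)) spawn_seeds(seed, reps)
  lapply(seq_len(reps), function(r) {
    if (!is.null(children)) set.seed(children[r])
    rng_sequence(seq$responses[sample.int(length(seq$responses))],
                 participant_id = paste0(seq$participant_id, ".perm", r),
                 K = seq$K)
  })
}
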