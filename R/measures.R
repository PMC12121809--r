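#' Randomness measures for response sequences
#'
#' Four sequence-level indices used to compare human-generated,
#' model-generated and permuted sequences.  Measures that are undefined
#' for a particular sequence (e.g. the coupon score when some digit never
#' appears) return `NA` and are excluded pairwise downstream.
#'
#' @param seq an [rng_sequence()] or integer response vector.
#' @param K number of response alternatives (used when `seq` is a bare
#'   vector).
#' @name measures
NULL

#' @describeIn measures interleaved-repetition index for sliding blocks.
#'   Over all `L - block + 1` overlapping windows, `p_obs` is the fraction
#'   whose first and last element are equal; `p_exp` is the probability
#'   that two draws without replacement from the sequence's digit counts
#'   coincide, `sum n_k (n_k - 1) / (L (L - 1))`.  Returns
#'   `100 * (p_obs - p_exp)`: negative values mean too few repetitions at
#'   lag `block - 1`.
#' @param block window length (default 4 for the phi index, 3 for block
#'   entropy).
#' @examples
#' phi_index(rep(1:3, length.out = 201))      # lag-3 always repeats: ~ +67
#' @export
phi_index <- function(seq, block = 4L, K = 9L) {
  resp <- as_responses(seq, infer_K(seq, K))
  L <- length(resp)
  block <- as.integer(block)
  if (L < block) stop("sequence shorter than the block size")
  first <- resp[1:(L - block + 1L)]
  last <- resp[block:L]
  p_obs <- mean(first == last)
  n_k <- tabulate(resp)
  p_exp <- sum(n_k * (n_k - 1)) / (L * (L - 1))
  100 * (p_obs - p_exp)
}

#' @describeIn measures Shannon entropy (bits) of the empirical
#'   distribution of overlapping length-`block` windows.  0 means a single
#'   block type was used throughout; larger values mean more evenly spread
#'   block usage.
#' @examples
#' block_entropy(rep(7, 50))                  # one block type: 0 bits
#' @export
block_entropy <- function(seq, block = 3L, K = 9L) {
  K <- infer_K(seq, K)
  resp <- as_responses(seq, K)
  L <- length(resp)
  block <- as.integer(block)
  if (L < block) stop("sequence shorter than the block size")
  n_win <- L - block + 1L
  # encode each window as an integer key in base K + 1
  key <- as.numeric(resp[1:n_win])
  for (j in seq_len(block - 1L))
    key <- key * (K + 1) + resp[(1L + j):(n_win + j)]
  p <- tabulate(factor(key)) / n_win
  -sum(p * log2(p))
}

#' @describeIn measures mean number of responses needed for all `K` digits
#'   to appear at least once: scan left to right, record the count when a
#'   full set completes, reset, continue; `NA` if no set ever completes.
#' @examples
#' coupon_score(rep(1:9, 4))                  # every set completes in 9
#' @export
coupon_score <- function(seq, K = 9L) {
  K <- infer_K(seq, K)
  resp <- as_responses(seq, K)
  seen <- logical(K)
  n_seen <- 0L
  count <- 0L
  times <- integer(0)
  for (x in resp) {
    count <- count + 1L
    if (!seen[x]) {
      seen[x] <- TRUE
      n_seen <- n_seen + 1L
      if (n_seen == K) {
        times <- c(times, count)
        seen[] <- FALSE
        n_seen <- 0L
        count <- 0L
      }
    }
  }
  if (!length(times)) NA_real_ else mean(times)
}

#' @describeIn measures mean positional distance between successive
#'   occurrences of the same digit, pooled over digits (adjacent trials
#'   differ by 1); `NA` if no digit recurs.
#' @examples
#' mean_gap(rep(1:9, 4))                      # every recurrence gap is 9
#' @export
mean_gap <- function(seq, K = 9L) {
  K <- infer_K(seq, K)
  resp <- as_responses(seq, K)
  if (length(resp) < 2L) stop("sequence must have length >= 2")
  gaps <- unlist(lapply(seq_len(K), function(k) diff(which(resp == k))),
                 use.names = FALSE)
  if (!length(gaps)) NA_real_ else mean(gaps)
}

infer_K <- function(seq, K) if (inherits(seq, "rng_sequence")) seq$K else K

#' Randomness profile table for a collection of sequences
#'
#' Computes all four measures for each sequence.
#'
#' @param seqs a list of [rng_sequence()] objects (or a single one).
#' @param phi_block,entropy_block window lengths for the phi index and
#'   block entropy.
#' @return A data frame with columns `participant_id`, `phi4`,
#'   `block_entropy3`, `coupon`, `mean_gap`.
#' @export
randomness_profile <- function(seqs, phi_block = 4L, entropy_block = 3L) {
  if (inherits(seqs, "rng_sequence")) seqs <- list(seqs)
  data.frame(
    participant_id = vapply(seqs, function(s) s$participant_id, character(1)),
    phi4 = vapply(seqs, phi_index, numeric(1), block = phi_block),
    block_entropy3 = vapply(seqs, block_entropy, numeric(1),
                            block = entropy_block),
    coupon = vapply(seqs, coupon_score, numeric(1)),
    mean_gap = vapply(seqs, mean_gap, numeric(1)),
    row.names = NULL)
}
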