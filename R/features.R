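#' History-dependent predictor vectors
#'
#' The choice models predict each response from four features of the
#' preceding history, all vectors of length `K` over the response
#' alternatives:
#' \describe{
#'   \item{`r` (repetition)}{1 at the previous response, 0 elsewhere.}
#'   \item{`s` (side)}{+1 for digits on the opposite half of the keypad
#'     (1-4 low, 6-9 high) from the previous response, -1 for the same
#'     half, 0 at the neutral digit 5; the whole vector is 0 when the
#'     previous response was 5.  Defined only for the nine-digit task.}
#'   \item{`d` (distance)}{Euclidean distance from the previous response
#'     in the keypad layout, in grid units.}
#'   \item{`g` (gap)}{number of steps since each digit was last produced;
#'     every entry starts at 1, the selected digit resets to 1 and all
#'     others increment by 1 at each step.}
#' }
#' The first response of a sequence has no feature state; prediction and
#' likelihood start at the second response.
#'
#' @param prev previous response, an integer in `1..K`.
#' @param K number of response alternatives.
#' @name features
NULL

#' @describeIn features one-hot repetition indicator.
#' @return `repetition_vector`: binary vector of length `K`.
#' @examples
#' repetition_vector(3, 9)
#' @export
repetition_vector <- function(prev, K = 9L) {
  K <- as.integer(K)
  prev <- as.integer(prev)
  if (length(prev) != 1L || is.na(prev) || prev < 1L || prev > K)
    stop("`prev` must be a single integer in 1..", K)
  r <- numeric(K)
  r[prev] <- 1
  r
}

# side membership of digits 1..9: -1 low half, +1 high half, 0 neutral
.side_of <- c(-1, -1, -1, -1, 0, 1, 1, 1, 1)

#' @describeIn features side-switch coding (nine-digit task only).
#' @return `side_vector`: vector of length 9 over \{-1, 0, +1\}.
#' @examples
#' side_vector(3)
#' side_vector(5)  # all zero: no switch is defined from the neutral digit
#' @export
side_vector <- function(prev, K = 9L) {
  if (as.integer(K) != 9L)
    stop("the side-switching feature is defined only for the 9-digit task")
  prev <- as.integer(prev)
  if (length(prev) != 1L || is.na(prev) || prev < 1L || prev > 9L)
    stop("`prev` must be a single integer in 1..9")
  if (prev == 5L) return(numeric(9))
  # +1 where the candidate lies on the other side, -1 on the same side
  -.side_of[prev] * .side_of
}

#' @describeIn features Euclidean distance from the previous response.
#' @param layout a [keypad_layout()].
#' @return `distance_vector`: nonnegative vector of length `K`.
#' @examples
#' distance_vector(5, keypad_layout("grid3x3"))
#' @export
distance_vector <- function(prev, layout = keypad_layout("grid3x3")) {
  assert_layout(layout)
  prev <- as.integer(prev)
  if (length(prev) != 1L || is.na(prev) || prev < 1L || prev > layout$K)
    stop("`prev` = ", prev, " is not a digit of the layout (1..", layout$K, ")")
  unname(layout$distances[prev, ])
}

#' @describeIn features initial gap vector (all ones).
#' @return `init_gap`: integer vector of length `K`, all 1.
#' @export
init_gap <- function(K = 9L) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  rep(1L, K)
}

#' @describeIn features update the gap vector after a selection: the chosen
#'   digit resets to 1, every other entry increments by 1.  The input is
#'   not modified.
#' @param g current gap vector.
#' @param chosen the selected digit.
#' @return `update_gap`: the updated gap vector.
#' @examples
#' update_gap(init_gap(9), 3)
#' @export
update_gap <- function(g, chosen) {
  if (any(g < 1)) stop("gap entries must be >= 1")
  chosen <- as.integer(chosen)
  if (length(chosen) != 1L || is.na(chosen) || chosen < 1L || chosen > length(g))
    stop("`chosen` must be a single integer in 1..", length(g))
  out <- g + 1L
  out[chosen] <- 1L
  out
}

#' Feature state for one prediction step
#'
#' Bundles the four predictor vectors valid for predicting the next
#' response, given the previous response and the current gap vector.
#'
#' @param prev previous response.
#' @param gap gap vector reflecting all selections up to and including
#'   `prev` (see [update_gap()]).
#' @param layout a [keypad_layout()].
#' @return A list of class `feature_state` with elements `r`, `s`, `d`,
#'   `g` (the side feature `s` is `NULL` for layouts other than the
#'   nine-digit grid or line).
#' @export
feature_state <- function(prev, gap, layout = keypad_layout("grid3x3")) {
  assert_layout(layout)
  if (length(gap) != layout$K) stop("gap vector must have length K")
  structure(
    list(r = repetition_vector(prev, layout$K),
         s = if (layout$K == 9L) side_vector(prev) else NULL,
         d = distance_vector(prev, layout),
         g = gap),
    class = "feature_state")
}

#' Encode a whole sequence as per-trial feature matrices
#'
#' Builds, for responses `2..T` of a sequence, the stacked feature rows the
#' models consume: row `t` holds the features used to predict response
#' `t + 1` from responses `1..t`.  This is the fast path used by the
#' likelihood, the fitters and the predictive scorer.
#'
#' @param seq an [rng_sequence()] (or bare integer vector of responses).
#' @param layout a [keypad_layout()].
#' @return A list with `(T-1) x K` matrices `R` (repetition), `S` (side;
#'   `NULL` unless `K = 9`), `D` (distance), `G` (gap), the integer vector
#'   `y` of observed responses `2..T`, and `K`.
#' @export
encode_features <- function(seq, layout = keypad_layout("grid3x3")) {
  assert_layout(layout)
  resp <- as_responses(seq, layout$K)
  T_len <- length(resp)
  if (T_len < 2L) stop("sequence must have length >= 2 to encode features")
  K <- layout$K
  n <- T_len - 1L
  R <- matrix(0, n, K)
  S <- if (K == 9L) matrix(0, n, K) else NULL
  D <- matrix(0, n, K)
  G <- matrix(0, n, K)
  side_rows <- if (K == 9L)
    t(vapply(1:9, side_vector, numeric(9))) else NULL
  g <- rep(1L, K)
  for (t in seq_len(n)) {
    prev <- resp[t]
    g <- g + 1L
    g[prev] <- 1L
    R[t, prev] <- 1
    if (!is.null(S)) S[t, ] <- side_rows[prev, ]
    D[t, ] <- layout$distances[prev, ]
    G[t, ] <- g
  }
  list(R = R, S = S, D = D, G = G, y = resp[-1L], K = K)
}
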