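#' A response sequence from an RNG task
#'
#' One participant's ordered responses: integers in `1..K` (default
#' `K = 9`, the nine-digit keypad task).
#'
#' @param responses integer vector of responses, each in `1..K`.
#' @param participant_id identifier string.
#' @param K number of response alternatives.
#' @return An object of class `rng_sequence`: a list with elements
#'   `participant_id`, `responses`, `K`.
#' @examples
#' rng_sequence(c(1, 5, 9, 5, 1), participant_id = "p01")
#' @export
rng_sequence <- function(responses, participant_id = "s1", K = 9L) {
  K <- as.integer(K)
  responses <- as_responses(responses, K)
  structure(list(participant_id = as.character(participant_id),
                 responses = responses, K = K),
            class = "rng_sequence")
}

#' @export
print.rng_sequence <- function(x, ...) {
  cat("<rng_sequence> participant", x$participant_id, "-",
      length(x$responses), "responses in 1..", x$K, "\n")
  utils::head(x$responses, 20L) |> paste(collapse = " ") |> cat("...\n")
  invisible(x)
}

#' @export
length.rng_sequence <- function(x) length(x$responses)

# coerce a sequence-like object to a validated integer response vector
as_responses <- function(seq, K = 9L) {
  if (inherits(seq, "rng_sequence")) {
    if (seq$K != K)
      stop("sequence has K = ", seq$K, " but K = ", K, " was expected")
    return(seq$responses)
  }
  resp <- as.integer(seq)
  if (length(resp) < 1L) stop("a response sequence must have length >= 1")
  bad <- which(is.na(resp) | resp < 1L | resp > K)
  if (length(bad))
    stop("responses out of range 1..", K, " at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  resp
}

as_rng_sequence <- function(seq, K = 9L) {
  if (inherits(seq, "rng_sequence")) seq
  else rng_sequence(seq, K = K)
}
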