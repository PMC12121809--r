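#' Keypad layouts for the RNG task
#'
#' A layout maps each response alternative to a coordinate so that the
#' distance feature of the choice models can be computed.  Two layouts are
#' supported: the 3x3 telephone/ATM keypad used in grid-based RNG tasks
#' (digits 1-3 on the top row, 4-6 in the middle, 7-9 at the bottom, unit
#' grid spacing), and a one-dimensional line where the distance between two
#' digits is their numerical difference (suited to oral or number-line
#' response formats).
#'
#' @param kind `"grid3x3"` or `"line1d"`.
#' @param K number of response alternatives.  Must be 9 for `"grid3x3"`;
#'   any `K >= 2` for `"line1d"`.
#'
#' @return An object of class `keypad_layout`: a list with elements
#'   `kind`, `K`, `coords` (a `K x 2` matrix of coordinates, row `i` for
#'   digit `i`) and `distances` (the `K x K` Euclidean distance matrix in
#'   grid units).
#'
#' @examples
#' kp <- keypad_layout("grid3x3")
#' kp$distances[4, 7]  # one row apart: 1
#' keypad_layout("line1d")$distances[4, 7]  # numerical distance: 3
#' @export
keypad_layout <- function(kind = c("grid3x3", "line1d"), K = 9L) {
  kind <- match.arg(kind)
  K <- as.integer(K)
  if (kind == "grid3x3") {
    if (K != 9L)
      stop("the grid3x3 layout covers exactly the digits 1..9 (K = 9)")
    coords <- cbind(row = ceiling(1:9 / 3), col = ((1:9 - 1L) %% 3L) + 1L)
  } else {
    if (K < 2L) stop("line1d layout needs K >= 2")
    coords <- cbind(pos = 1:K, 0)
  }
  rownames(coords) <- as.character(1:K)
  structure(
    list(kind = kind, K = K, coords = coords,
         distances = as.matrix(stats::dist(coords))),
    class = "keypad_layout")
}

#' @export
print.keypad_layout <- function(x, ...) {
  cat("<keypad_layout> kind =", x$kind, ", K =", x$K, "\n")
  invisible(x)
}

is_keypad_layout <- function(x) inherits(x, "keypad_layout")

assert_layout <- function(layout) {
  if (!is_keypad_layout(layout))
    stop("`layout` must be a keypad_layout object")
  layout
}
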