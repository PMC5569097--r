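#' Lattice dimensions
#'
#' The simulation domain is a rectangular lattice with `S1` rows (the
#' vertical, periodic axis, coordinate `r1`) and `S2` columns (the
#' horizontal axis along which the chemotactic gradient increases,
#' coordinate `r2`). Coordinates are 1-based: `1 <= r1 <= S1`,
#' `1 <= r2 <= S2`.
#'
#' @param S1 vertical extent (periodic axis); positive integer.
#' @param S2 horizontal extent (gradient axis); integer `>= 2`.
#' @return An object of class `lattice_dims`: a list with elements `S1`
#'   and `S2`.
#' @examples
#' lattice_dims(100, 300)
#' @export
lattice_dims <- function(S1, S2) {
  S1 <- as.integer(S1)
  S2 <- as.integer(S2)
  if (length(S1) != 1L || is.na(S1) || S1 < 1L)
    stop("S1 must be a positive integer")
  if (length(S2) != 1L || is.na(S2) || S2 < 2L)
    stop("S2 must be an integer >= 2")
  structure(list(S1 = S1, S2 = S2), class = "lattice_dims")
}

#' @export
print.lattice_dims <- function(x, ...) {
  cat(sprintf("lattice %d x %d (r1 periodic, r2 reflecting)\n", x$S1, x$S2))
  invisible(x)
}

#' Chemotactic gradient value
#'
#' The static chemotactic signal G(r1, r2) = r2 / S2: a linear attractive
#' gradient toward the target column r2 = S2, constant along r1. The
#' gradient is independent of the ECM resistance field.
#'
#' @param r1,r2 1-based lattice coordinates.
#' @param dims a [lattice_dims()] object.
#' @return The gradient value, a real in (0, 1].
#' @examples
#' gradient_value(1, 300, lattice_dims(100, 300))  # 1 at the target column
#' @export
gradient_value <- function(r1, r2, dims) {
  stopifnot(inherits(dims, "lattice_dims"))
  if (any(r1 < 1L | r1 > dims$S1) || any(r2 < 1L | r2 > dims$S2))
    stop("coordinates out of range")
  r2 / dims$S2
}

#' Full chemotactic gradient field
#'
#' @param dims a [lattice_dims()] object.
#' @return An `S1 x S2` matrix with entry `[r1, r2] = r2 / S2`.
#' @export
gradient_field <- function(dims) {
  stopifnot(inherits(dims, "lattice_dims"))
  matrix(rep(seq_len(dims$S2) / dims$S2, each = dims$S1),
         nrow = dims$S1, ncol = dims$S2)
}
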