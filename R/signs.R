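#' Sign vector of a flux vector
#'
#' Applies the sign function component-wise, with a zero tolerance: entries
#' with absolute value at most `tol` are treated as zero. Sign vectors are
#' represented as integer vectors over \{-1, 0, +1\}; see [sign_to_string()]
#' for the `"-0+"` string form.
#'
#' @param x Numeric vector of fluxes. All entries must be finite.
#' @param tol Zero tolerance. The default 1e-9 sits three orders of magnitude
#'   below the LP flux lower bound (1e-6) used by tope feasibility checks and
#'   above the solver tolerance (1e-10), so LP witness fluxes are never
#'   misclassified as zero.
#' @return Integer vector in \{-1, 0, 1\} of the same length as `x`.
#' @examples
#' sign_of(c(-1, 0, 2)) # -1 0 1
#' @export
sign_of <- function(x, tol = 1e-9) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` contains non-finite entries", call. = FALSE)
  s <- integer(length(x))
  s[x > tol] <- 1L
  s[x < -tol] <- -1L
  s
}

#' Conformality of sign vectors
#'
#' `conforms(xi, eta)` tests the partial order on sign vectors induced by
#' 0 < - and 0 < +: `xi` conforms to `eta` when every nonzero entry of `xi`
#' equals the corresponding entry of `eta`. A flux mode belongs to the tope
#' defined by `eta` exactly when its sign vector conforms to `eta`.
#'
#' @param xi,eta Integer sign vectors over \{-1, 0, 1\} of equal length.
#' @return Logical scalar.
#' @examples
#' conforms(c(-1L, 0L, 1L), c(-1L, -1L, 1L)) # TRUE
#' @export
conforms <- function(xi, eta) {
  if (length(xi) != length(eta)) stop("sign vectors differ in length", call. = FALSE)
  .check_sign(xi); .check_sign(eta)
  all(xi == 0L | xi == eta)
}

#' Conformality of real vectors
#'
#' Two flux vectors are conformal when no component has strictly opposite
#' signs, i.e. `x[i] * y[i] >= 0` for all `i` (up to the zero tolerance).
#' Equivalently, a common upper-bound sign vector exists for their signs.
#'
#' @param x,y Numeric vectors of equal length.
#' @inheritParams sign_of
#' @return Logical scalar.
#' @export
is_conformal <- function(x, y, tol = 1e-9) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  all(sign_of(x, tol) * sign_of(y, tol) >= 0L)
}

#' Upper bound on the number of cells of a central hyperplane arrangement
#'
#' For `r` distinct central hyperplanes in dimension `d`, at most
#' \eqn{2 \sum_{i=0}^{d-1} \binom{r-1}{i}} of the `2^r` full sign vectors
#' correspond to cells; the bound simplifies to `2^r` when `d >= r`.
#'
#' @param r Number of hyperplanes (>= 1).
#' @param d Ambient dimension (>= 1).
#' @return The bound, as a double (it can exceed the integer range).
#' @examples
#' cell_upper_bound(6, 3) # 32
#' @export
cell_upper_bound <- function(r, d) {
  if (length(r) != 1 || length(d) != 1 || !is.finite(r) || !is.finite(d) ||
      r < 1 || d < 1 || r != round(r) || d != round(d)) {
    stop("`r` and `d` must be positive integers", call. = FALSE)
  }
  if (d >= r) return(2^r)
  2 * sum(choose(r - 1, 0:(d - 1)))
}

#' Upper bound on the number of flux topes
#'
#' Each tope fixes the direction of every independent reversible reaction,
#' giving the obvious bound `2^n_rev`. A network without reversible reactions
#' has exactly one tope.
#'
#' @param n_rev Number of independent reversible reactions (>= 0).
#' @return The bound `2^n_rev` as a double.
#' @examples
#' tope_upper_bound(31) # 2147483648
#' @export
tope_upper_bound <- function(n_rev) {
  if (length(n_rev) != 1 || !is.finite(n_rev) || n_rev < 0 || n_rev != round(n_rev)) {
    stop("`n_rev` must be a nonnegative integer", call. = FALSE)
  }
  2^n_rev
}

#' Number of signed direction pairs among reversible reactions
#'
#' Counting each reversible reaction twice (forward and backward direction),
#' the number of unordered pairs of signed directions is `choose(2 * n_rev, 2)`.
#' This is the number of cells inspected by [pair_direction_matrix()] style
#' coordination analyses.
#'
#' @inheritParams tope_upper_bound
#' @return Integer count.
#' @examples
#' signed_pair_count(27) # 1431
#' @export
signed_pair_count <- function(n_rev) {
  if (length(n_rev) != 1 || !is.finite(n_rev) || n_rev < 0 || n_rev != round(n_rev)) {
    stop("`n_rev` must be a nonnegative integer", call. = FALSE)
  }
  choose(2 * n_rev, 2)
}

#' Serialize sign vectors to and from strings
#'
#' Sign vectors serialize to strings over the alphabet `-0+`, one character
#' per reaction, in the model's reaction order.
#'
#' @param s Integer sign vector over \{-1, 0, 1\}.
#' @param str Character scalar over the alphabet `-0+`.
#' @return `sign_to_string()` returns a character scalar; `string_to_sign()`
#'   the corresponding integer vector.
#' @examples
#' sign_to_string(c(-1L, 0L, 1L)) # "-0+"
#' @export
sign_to_string <- function(s) {
  .check_sign(s)
  paste(c("-", "0", "+")[s + 2L], collapse = "")
}

#' @rdname sign_to_string
#' @export
string_to_sign <- function(str) {
  ch <- strsplit(str, "")[[1]]
  if (!all(ch %in% c("-", "0", "+"))) {
    stop("sign string must use the alphabet \"-0+\"", call. = FALSE)
  }
  match(ch, c("-", "0", "+")) - 2L
}

.check_sign <- function(s) {
  if (!all(s %in% c(-1L, 0L, 1L))) {
    stop("sign vector entries must lie in {-1, 0, +1}", call. = FALSE)
  }
  invisible(s)
}

# packed key for the visited tree: one character (+/-) per tracked position
.sign_key <- function(s, positions) {
  paste0("k", paste(ifelse(s[positions] > 0L, "+", "-"), collapse = ""))
}
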