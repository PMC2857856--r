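#' Clamped B-spline basis
#'
#' Builds a uniform, clamped (repeated boundary knots) B-spline basis with
#' `n_basis` basis functions of the given degree on a closed interval. The
#' basis is a partition of unity on the domain: the basis values at any point
#' are non-negative and sum to one. Points outside the domain are clamped to
#' the nearest boundary before evaluation, so the basis extends as a constant
#' beyond the interval.
#'
#' @param n_basis Number of basis functions (knot weights), at least
#'   `degree + 1`... in fact any value `>= 2` is accepted; the interior
#'   breakpoints are spaced uniformly.
#' @param degree Polynomial degree (3 = cubic).
#' @param domain Length-2 numeric, the closed interval `[lo, hi]`, `lo < hi`.
#' @return An object of class `rdn_spline_basis` with fields `knots`,
#'   `degree`, `domain` and `n_basis`.
#' @seealso [spline_basis_matrix()]
#' @export
#' @examples
#' b <- spline_basis(5, 3, c(1, 24))
#' rowSums(spline_basis_matrix(b, c(1, 7, 24)))  # all 1
spline_basis <- function(n_basis = 5L, degree = 3L, domain = c(0, 1)) {
  if (length(domain) != 2L || !all(is.finite(domain)) || diff(domain) <= 0) {
    stop("`domain` must be a finite interval [lo, hi] with lo < hi.")
  }
  if (n_basis < 2L) stop("`n_basis` must be >= 2.")
  if (degree < 1L) stop("`degree` must be >= 1.")
  if (n_basis < degree + 1L) {
    stop("`n_basis` must be at least `degree + 1` for a clamped basis.")
  }
  lo <- domain[1]; hi <- domain[2]
  inner <- seq(lo, hi, length.out = n_basis - degree + 1L)
  knots <- c(rep(lo, degree), inner, rep(hi, degree))
  structure(
    list(knots = knots, degree = as.integer(degree),
         domain = c(lo, hi), n_basis = as.integer(n_basis)),
    class = "rdn_spline_basis"
  )
}

#' Evaluate a B-spline basis at a vector of points
#'
#' @param basis An [spline_basis()] object.
#' @param x Numeric vector of evaluation points; values outside the domain are
#'   clamped to the boundary.
#' @return A `length(x)` by `n_basis` matrix of basis factors.
#' @export
spline_basis_matrix <- function(basis, x) {
  stopifnot(inherits(basis, "rdn_spline_basis"))
  xc <- pmin(pmax(x, basis$domain[1]), basis$domain[2])
  splines::splineDesign(basis$knots, xc, ord = basis$degree + 1L)
}
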