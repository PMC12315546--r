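#' B-spline basis over the adult age range
#'
#' Constructs a clamped B-spline basis used for both the location and the
#' log-scale curves of the aging-trajectory model. The default is a cubic
#' basis with four control points whose anchor ages are 27, 45, 63 and 81
#' years, evaluated over the age domain 18--90. With four cubic basis
#' functions the knot vector is fully clamped at the domain ends, so the
#' curve is a single smooth cubic segment; the anchor ages are the ages at
#' which generator trajectories are specified (see
#' [trajectory_coef_from_anchors()]).
#'
#' The basis functions are nonnegative and sum to one (partition of unity)
#' at every age in the domain, so constant coefficients give a constant
#' curve and coefficients bound the curve's range.
#'
#' @param control_ages Strictly increasing anchor ages, one per basis
#'   function. Default `c(27, 45, 63, 81)`.
#' @param degree Polynomial degree of the spline. Default cubic (3).
#'   Degree 0 with a single control age reduces to a constant (bin
#'   indicator) model.
#' @param domain Two ages bounding the evaluation domain; must contain all
#'   control ages. Default `c(18, 90)`.
#' @return An object of class `bspline_basis` with elements `degree`,
#'   `control_ages`, `knots`, `n_basis` and `domain`.
#' @examples
#' basis <- bspline_basis()
#' B <- eval_basis(basis, c(20, 50, 85))
#' rowSums(B)  # partition of unity
#' @export
bspline_basis <- function(control_ages = c(27, 45, 63, 81),
                          degree = 3L,
                          domain = c(18, 90)) {
  degree <- as.integer(degree)
  if (degree < 0L) stop("`degree` must be a nonnegative integer")
  if (is.unsorted(control_ages, strictly = TRUE)) {
    stop("`control_ages` must be strictly increasing")
  }
  n_basis <- length(control_ages)
  if (n_basis < degree + 1L) {
    stop("need at least degree + 1 control points (",
         degree + 1L, "), got ", n_basis)
  }
  if (length(domain) != 2L || domain[1] >= domain[2]) {
    stop("`domain` must be two increasing ages")
  }
  if (min(control_ages) < domain[1] || max(control_ages) > domain[2]) {
    stop("`domain` must contain all control ages")
  }
  n_interior <- n_basis - degree - 1L
  interior <- numeric(0)
  if (n_interior > 0L) {
    # knot averaging over consecutive control ages keeps the collocation
    # matrix at the control ages invertible (Schoenberg-Whitney)
    interior <- vapply(seq_len(n_interior), function(j) {
      mean(control_ages[(j + 1L):(j + degree)])
    }, numeric(1))
  }
  knots <- c(rep(domain[1], degree + 1L), interior, rep(domain[2], degree + 1L))
  structure(
    list(degree = degree, control_ages = control_ages, knots = knots,
         n_basis = n_basis, domain = domain),
    class = "bspline_basis"
  )
}

#' Evaluate a B-spline basis at given ages
#'
#' Returns the matrix of basis function values. Ages outside the basis
#' domain are an error unless `allow_extrapolation = TRUE`, in which case
#' the basis is extended linearly (C1) from the nearest domain edge.
#'
#' @param basis A [bspline_basis()].
#' @param ages Numeric vector of ages in years.
#' @param allow_extrapolation Permit ages outside the domain. Default FALSE.
#' @return A `length(ages)` by `basis$n_basis` matrix.
#' @export
eval_basis <- function(basis, ages, allow_extrapolation = FALSE) {
  stopifnot(inherits(basis, "bspline_basis"))
  ages <- as.numeric(ages)
  if (anyNA(ages)) stop("`ages` contains missing values")
  lo <- basis$domain[1]; hi <- basis$domain[2]
  outside <- ages < lo | ages > hi
  if (any(outside) && !allow_extrapolation) {
    stop("ages outside the basis domain [", lo, ", ", hi,
         "]; set `allow_extrapolation = TRUE` to extend linearly")
  }
  ord <- basis$degree + 1L
  inside <- !outside
  B <- matrix(0, length(ages), basis$n_basis)
  if (any(inside)) {
    B[inside, ] <- splines::splineDesign(basis$knots, ages[inside], ord = ord)
  }
  if (any(outside)) {
    for (edge in c(lo, hi)) {
      sel <- if (edge == lo) outside & ages < lo else outside & ages > hi
      if (!any(sel)) next
      B0 <- splines::splineDesign(basis$knots, edge, ord = ord)
      D0 <- if (basis$degree >= 1L) {
        splines::splineDesign(basis$knots, edge, ord = ord, derivs = 1L)
      } else {
        matrix(0, 1, basis$n_basis)
      }
      B[sel, ] <- rep(1, sum(sel)) %o% drop(B0) +
        (ages[sel] - edge) %o% drop(D0)
    }
  }
  B
}

#' Solve for spline coefficients from values at the anchor ages
#'
#' Generator trajectories are specified by their values at the anchor ages
#' (by default 27, 45, 63 and 81 years). This solves the square collocation
#' system `B(anchor ages) %*% theta = values` so that the resulting spline
#' passes exactly through the anchor values, keeping simulated truths inside
#' the fitted model family.
#'
#' @param basis A [bspline_basis()].
#' @param values Numeric vector of trajectory values at
#'   `basis$control_ages` (same length as `n_basis`).
#' @return Coefficient vector of length `n_basis`.
#' @export
trajectory_coef_from_anchors <- function(basis, values) {
  stopifnot(inherits(basis, "bspline_basis"))
  if (length(values) != basis$n_basis) {
    stop("`values` must have one entry per control age (",
         basis$n_basis, ")")
  }
  A <- eval_basis(basis, basis$control_ages)
  drop(solve(A, as.numeric(values)))
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat("B-spline basis: degree", x$degree, "with", x$n_basis,
      "control points\n")
  cat("  anchor ages:", paste(x$control_ages, collapse = ", "), "\n")
  cat("  domain: [", x$domain[1], ",", x$domain[2], "] years\n")
  invisible(x)
}
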