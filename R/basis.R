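#' Specify an equally spaced B-spline basis
#'
#' Defines a B-spline basis on `[lower, upper]` with equally spaced knots.
#' Knots are extended `degree` intervals beyond each end of the domain so
#' that the basis forms a partition of unity everywhere inside it.  The
#' number of basis functions is `ceiling((upper - lower) / spacing) + degree`.
#'
#' @param lower,upper Domain endpoints (age or calendar-year units).
#' @param spacing Knot spacing in domain units.  Default 5, the usual
#'   choice for single-year mortality surfaces.
#' @param degree Spline degree.  Default 3 (cubic).
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(lower, upper, spacing = 5, degree = 3) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L)
  if (upper <= lower) stop("`upper` must exceed `lower`")
  if (spacing <= 0) stop("`spacing` must be positive")
  if (degree < 0 || degree != round(degree)) {
    stop("`degree` must be a nonnegative integer")
  }
  nseg <- as.integer(ceiling((upper - lower) / spacing))
  structure(
    list(lower = lower, upper = upper, spacing = spacing,
         degree = as.integer(degree), nseg = nseg,
         nbasis = nseg + as.integer(degree),
         knots = seq(lower - degree * spacing,
                     lower + (nseg + degree) * spacing, by = spacing)),
    class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("B-spline basis: degree %d, spacing %g on [%g, %g] (%d functions)\n",
              x$degree, x$spacing, x$lower, x$upper, x$nbasis))
  invisible(x)
}

#' Evaluate a B-spline basis on a grid
#'
#' @param spec A [basis_spec()].
#' @param x Evaluation points; must lie inside the domain.  Points outside
#'   the domain are an error, never silent extrapolation.
#' @param sparse Return a sparse `Matrix` (default `FALSE`).
#' @return Matrix of dimension `length(x)` by `spec$nbasis`; rows sum to 1.
#' @export
build_basis <- function(spec, x, sparse = FALSE) {
  stopifnot(inherits(spec, "basis_spec"))
  if (any(x < spec$lower - 1e-12) || any(x > spec$upper + 1e-12)) {
    stop(sprintf("evaluation points outside basis domain [%g, %g]",
                 spec$lower, spec$upper))
  }
  B <- splines::splineDesign(spec$knots, x = x, ord = spec$degree + 1L,
                             sparse = sparse)
  if (sparse) B <- methods::as(B, "CsparseMatrix")
  B
}

#' Difference penalty matrix for adjacent B-spline coefficients
#'
#' Returns `t(D) %*% D` where `D` is the order-`order` difference operator
#' on `nbasis` coefficients.  The result is positive semidefinite with rank
#' `nbasis - order`; an order-2 penalty vanishes exactly on coefficient
#' vectors that are linear sequences.
#'
#' @param nbasis Number of coefficients.
#' @param order Difference order (default 2).
#' @export
build_penalty <- function(nbasis, order = 2) {
  stopifnot(nbasis == round(nbasis), order == round(order), order >= 1)
  if (order >= nbasis) stop("penalty order must be smaller than the basis size")
  D <- diff(diag(nbasis), differences = order)
  crossprod(D)
}
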