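# Clamped cubic B-spline basis over age, used as the nonlinear part of the
# normative-model design. Three evenly spaced interior knots by default, so
# the basis has degree + n_interior + 1 = 7 functions.

#' Build a clamped B-spline basis over observed ages
#'
#' Interior knots are placed evenly between the minimum and maximum observed
#' age (open interval); boundary knots are repeated `degree + 1` times
#' (clamped), so at the boundaries a single basis function equals one.
#'
#' @param ages Numeric vector of ages in years (>= 2 distinct values).
#' @param n_interior_knots Number of interior knots (default 3).
#' @param degree Spline degree (default 3, cubic).
#' @return An object of class `spline_basis` with fields `degree`,
#'   `interior_knots`, `boundary` and `n_basis`.
#' @export
build_spline_basis <- function(ages, n_interior_knots = 3L, degree = 3L) {
  ages <- ages[is.finite(ages)]
  if (length(unique(ages)) < 2) stop("need at least 2 distinct ages")
  if (n_interior_knots < 1) stop("n_interior_knots must be >= 1")
  bnd <- range(ages)
  interior <- seq(bnd[1], bnd[2], length.out = n_interior_knots + 2L)
  interior <- interior[-c(1L, n_interior_knots + 2L)]
  structure(list(degree = as.integer(degree),
                 interior_knots = interior,
                 boundary = bnd,
                 n_basis = as.integer(degree + n_interior_knots + 1L)),
            class = "spline_basis")
}

#' Evaluate a spline basis at given ages
#'
#' @param basis A [build_spline_basis()] object.
#' @param ages Ages to evaluate; must lie within `basis$boundary` unless
#'   `clamp = TRUE`, in which case out-of-range ages are clamped to the
#'   boundary with a warning.
#' @param clamp Clamp out-of-range ages instead of erroring (used for
#'   cross-validation test folds).
#' @return Matrix with one row per age and `basis$n_basis` columns; rows sum
#'   to one (partition of unity of the clamped basis).
#' @export
eval_spline_basis <- function(basis, ages, clamp = FALSE) {
  stopifnot(inherits(basis, "spline_basis"))
  lo <- basis$boundary[1]; hi <- basis$boundary[2]
  out_of_range <- ages < lo | ages > hi
  if (any(out_of_range)) {
    if (!clamp)
      stop(sprintf("%d age(s) outside basis boundary [%g, %g]",
                   sum(out_of_range), lo, hi))
    warning(sprintf("clamping %d age(s) to basis boundary [%g, %g]",
                    sum(out_of_range), lo, hi))
    ages <- pmin(pmax(ages, lo), hi)
  }
  knots <- c(rep(lo, basis$degree + 1L), basis$interior_knots,
             rep(hi, basis$degree + 1L))
  B <- splines::splineDesign(knots, ages, ord = basis$degree + 1L,
                             outer.ok = FALSE)
  colnames(B) <- sprintf("spline%d", seq_len(ncol(B)))
  B
}

#' Build the normative-model design matrix
#'
#' Columns: intercept, raw age (years), sex code, and the clamped B-spline
#' expansion of age. The spline span includes affine functions of age, so the
#' design is deliberately rank-deficient; the Gaussian weight prior of the
#' Bayesian fit regularizes it.
#'
#' @param ages Numeric ages.
#' @param sexes Sex codes in \{0, 1\}.
#' @param basis A [build_spline_basis()] object.
#' @param clamp Passed to [eval_spline_basis()].
#' @return Numeric matrix with labeled columns.
#' @export
build_design <- function(ages, sexes, basis, clamp = FALSE) {
  if (length(ages) != length(sexes)) stop("ages and sexes lengths differ")
  if (any(!is.finite(ages))) stop("non-finite ages")
  if (any(!sexes %in% c(0, 1))) stop("sex codes must be 0 or 1")
  B <- eval_spline_basis(basis, ages, clamp = clamp)
  X <- cbind(intercept = rep(1, length(ages)), age = ages, sex = sexes, B)
  storage.mode(X) <- "double"
  X
}
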