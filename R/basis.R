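#' Cubic B-spline age basis with evenly spaced knots
#'
#' Builds the covariate basis of the normative model: a cubic
#' ("third-order polynomial") B-spline expansion with `n_knots` evenly
#' spaced knots spanning the training age range, boundary knots clamped.
#' With the default five knots on ages spanning 45--85 the knots sit at
#' 45, 55, 65, 75, 85 and the basis has `M = 7` functions. The clamped
#' basis forms a partition of unity on the training domain, so it spans
#' constants and no separate intercept column is needed.
#'
#' Evaluation at ages outside the training domain clamps them to the
#' boundary (with a warning): extrapolated predictions are held at the
#' boundary value rather than polynomial-extrapolated.
#'
#' @param ages Numeric vector of training ages (years); at least two
#'   distinct values.
#' @param n_knots Number of evenly spaced knots including the two boundary
#'   knots (default 5).
#' @param degree Spline degree (default 3, cubic).
#' @return An object of class `nm_basis` with fields `knots`, `degree`,
#'   `domain` and `n_fun` (the number of basis functions M).
#' @examples
#' b <- nm_basis(c(45, 60, 85))
#' rowSums(nm_basis_matrix(b, c(50, 70)))  # partition of unity
#' @export
nm_basis <- function(ages, n_knots = 5, degree = 3) {
  ages <- ages[is.finite(ages)]
  if (length(unique(ages)) < 2L) {
    abort("`ages` must contain at least two distinct finite values.")
  }
  check_number(n_knots, "n_knots", lower = 2)
  rng <- range(ages)
  knots <- seq(rng[1], rng[2], length.out = n_knots)
  structure(
    list(degree = as.integer(degree),
         knots = knots,
         interior = knots[-c(1L, n_knots)],
         domain = rng,
         n_fun = as.integer(n_knots - 2L + degree + 1L)),
    class = "nm_basis")
}

#' @export
print.nm_basis <- function(x, ...) {
  cat(sprintf("<nm_basis> degree %d, %d knots on [%.3g, %.3g], M = %d\n",
              x$degree, length(x$knots), x$domain[1], x$domain[2], x$n_fun))
  invisible(x)
}

#' @rdname nm_basis
#' @param basis An `nm_basis` object.
#' @param warn Warn when ages are clamped to the training domain.
#' @return `nm_basis_matrix()`: an `length(ages) x M` design matrix.
#' @export
nm_basis_matrix <- function(basis, ages, warn = TRUE) {
  stopifnot(inherits(basis, "nm_basis"))
  if (anyNA(ages) || any(!is.finite(ages))) {
    abort("`ages` must be finite for basis evaluation.")
  }
  lo <- basis$domain[1]; hi <- basis$domain[2]
  n_out <- sum(ages < lo | ages > hi)
  if (n_out > 0L && warn) {
    warn(sprintf(
      "%d age(s) outside the training domain [%.3g, %.3g] clamped to the boundary.",
      n_out, lo, hi))
  }
  x <- pmin(pmax(ages, lo), hi)
  m <- splines::bs(x, knots = basis$interior, degree = basis$degree,
                   Boundary.knots = basis$domain, intercept = TRUE)
  m <- unclass(m)
  attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
  m
}
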