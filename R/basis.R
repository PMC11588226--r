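#' Basis systems for functional observations
#'
#' A basis system describes how curves are represented numerically: either
#' directly by their values on a common grid (`discrete_basis()`), or by
#' coefficients of a Fourier (`fourier_basis()`) or B-spline
#' (`bspline_basis()`) expansion.  Every basis carries the Gram matrix `W`
#' of pairwise basis-function inner products on the domain, which turns
#' Euclidean operations on coefficient vectors into L2 operations on curves.
#'
#' For the discrete family `W = h I` with `h` the grid spacing, so that
#' coefficient-space sums of squares approximate L2 integrals (a Riemann
#' weight).  Scaling `W` by a positive constant does not change archetype
#' minimisers, but keeps residual sums of squares comparable across grid
#' resolutions.  The Fourier family is orthonormal on its domain, so `W` is
#' the identity.  For B-splines, `W` is computed by Gauss-Legendre
#' quadrature with 8 nodes per knot span, which is exact for the
#' polynomial products involved.
#'
#' @param n_points,m number of grid points (discrete) or basis functions.
#' @param a,b domain endpoints, `a < b`.
#' @param order B-spline order (degree + 1); the default 4 gives cubics.
#'
#' @return An object of class `faa_basis` with fields `family`, `m`,
#'   `domain`, `W` and, for the discrete family, `grid`.
#' @examples
#' discrete_basis(25)
#' fourier_basis(5)$W[1:3, 1:3]
#' @name basis
NULL

new_basis <- function(family, m, domain, W, grid = NULL, order = NULL,
                      knots = NULL) {
  structure(
    list(family = family, m = m, domain = domain, W = W, grid = grid,
         order = order, knots = knots),
    class = "faa_basis")
}

check_domain <- function(a, b) {
  check_number(a, "a"); check_number(b, "b")
  if (a >= b) {
    abort("Domain is invalid: `a` must be strictly smaller than `b`.",
          class = "faaknn_error_domain")
  }
}

#' @rdname basis
#' @export
discrete_basis <- function(n_points, a = 0, b = 1) {
  n_points <- check_count(n_points, "n_points", min = 2L)
  check_domain(a, b)
  h <- (b - a) / (n_points - 1)
  new_basis("discrete", n_points, c(a, b), diag(h, n_points),
            grid = seq(a, b, length.out = n_points))
}

#' @rdname basis
#' @export
fourier_basis <- function(m, a = 0, b = 1) {
  m <- check_count(m, "m", min = 1L)
  check_domain(a, b)
  new_basis("fourier", m, c(a, b), diag(1, m))
}

#' @rdname basis
#' @export
bspline_basis <- function(m, a = 0, b = 1, order = 4) {
  order <- check_count(order, "order", min = 1L)
  m <- check_count(m, "m", min = order)
  check_domain(a, b)
  interior <- if (m > order) seq(a, b, length.out = m - order + 2L)[-c(1L, m - order + 2L)] else numeric()
  knots <- c(rep(a, order), interior, rep(b, order))
  basis <- new_basis("bspline", m, c(a, b), W = NULL, order = order,
                     knots = knots)
  basis$W <- gram_matrix(basis)
  basis
}

#' Evaluate the basis functions on a grid
#'
#' Returns the `length(t)` by `m` matrix of basis-function values, the
#' design matrix used for least-squares coefficient fits.
#'
#' @param basis a [basis] object.
#' @param t evaluation points inside the basis domain.
#' @return numeric matrix, one row per evaluation point.
#' @export
eval_basis <- function(basis, t) {
  stopifnot(inherits(basis, "faa_basis"))
  a <- basis$domain[1]; b <- basis$domain[2]
  if (any(t < a - 1e-12) || any(t > b + 1e-12)) {
    abort("Evaluation points lie outside the basis domain.",
          class = "faaknn_error_domain")
  }
  t <- pmin(pmax(t, a), b)
  switch(basis$family,
    discrete = {
      idx <- vapply(t, function(ti) which.min(abs(basis$grid - ti)), 1L)
      if (any(abs(basis$grid[idx] - t) > 1e-8)) {
        abort("Discrete bases can only be evaluated on their own grid.",
              class = "faaknn_error_grid")
      }
      diag(1, basis$m)[idx, , drop = FALSE]
    },
    fourier = {
      L <- b - a
      u <- (t - a) / L
      B <- matrix(0, length(t), basis$m)
      B[, 1] <- 1 / sqrt(L)
      if (basis$m > 1) {
        for (h in seq_len(basis$m - 1L)) {
          j <- ceiling(h / 2)
          B[, h + 1L] <- if (h %% 2 == 1) {
            sqrt(2 / L) * sin(2 * pi * j * u)
          } else {
            sqrt(2 / L) * cos(2 * pi * j * u)
          }
        }
      }
      B
    },
    bspline = splines::splineDesign(basis$knots, x = t, ord = basis$order)
  )
}

# 8-point Gauss-Legendre rule on [-1, 1]
gl8 <- list(
  nodes = c(-0.9602898564975363, -0.7966664774136267, -0.5255324099163290,
            -0.1834346424956498,  0.1834346424956498,  0.5255324099163290,
             0.7966664774136267,  0.9602898564975363),
  weights = c(0.1012285362903763, 0.2223810344533745, 0.3137066458778873,
              0.3626837833783620, 0.3626837833783620, 0.3137066458778873,
              0.2223810344533745, 0.1012285362903763))

#' Gram matrix of a basis system
#'
#' The `m` by `m` matrix of inner products of pairs of basis functions over
#' the domain: the identity for the orthonormal Fourier family, the grid
#' weight `h I` for the discrete family, and Gauss-Legendre quadrature
#' (8 nodes per knot span, exact for the polynomial products) for
#' B-splines.
#'
#' @inheritParams eval_basis
#' @return symmetric positive semidefinite matrix.
#' @export
gram_matrix <- function(basis) {
  stopifnot(inherits(basis, "faa_basis"))
  if (!is.null(basis$W)) return(basis$W)
  spans <- unique(basis$knots)
  W <- matrix(0, basis$m, basis$m)
  for (s in seq_len(length(spans) - 1L)) {
    lo <- spans[s]; hi <- spans[s + 1L]
    half <- (hi - lo) / 2
    t_nodes <- lo + half * (gl8$nodes + 1)
    B <- eval_basis(basis, t_nodes)
    W <- W + crossprod(B * sqrt(gl8$weights * half))
  }
  (W + t(W)) / 2
}

#' @export
print.faa_basis <- function(x, ...) {
  cat(sprintf("<faa_basis> family = %s, m = %d, domain = [%g, %g]\n",
              x$family, x$m, x$domain[1], x$domain[2]))
  invisible(x)
}
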