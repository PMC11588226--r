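#' Fit functional archetype analysis
#'
#' Decomposes `n` curves into `p` archetypes: every curve is approximated
#' by a convex mixture (weights `alpha`, rows on the unit simplex) of
#' archetypes, and every archetype is itself a convex mixture (weights
#' `beta`) of the observed curves.  The residual sum of squares is measured
#' in the L2 norm of the underlying functions, i.e. on basis coefficients
#' through the Gram matrix `W` of the basis; a Cholesky factor of `W` maps
#' the problem to ordinary Euclidean archetype analysis on transformed
#' coefficients (for the diagonal metrics of the discrete and Fourier
#' families this is a column scaling).
#'
#' The optimiser alternates the two simplex-constrained least-squares
#' subproblems, each solved by non-negative least squares on a design
#' padded with a sum-to-one penalty row of magnitude `200 * max|X|`.
#' The alternation is non-deterministic in its starting point, so it is
#' restarted `n_restarts` times from random Dirichlet-initialised `beta`
#' matrices and the best model (lowest RSS; ties broken toward the lowest
#' restart index) is kept.  Restart seeds are derived from
#' `(seed, p, restart)`, so fits for different `p` under one master seed
#' are mutually independent and individually reproducible.
#'
#' @param x curves: an [functional_sample()], or a plain numeric matrix
#'   (rows = curves) treated as values on an equispaced grid over `[0, 1]`.
#' @param p number of archetypes, `1 <= p <= n`.
#' @param n_restarts random restarts of the alternating solver.
#' @param max_iter maximum alternations per restart.
#' @param tol relative RSS improvement below which a restart stops.
#' @param seed master seed; the fit is deterministic given all arguments.
#'
#' @return An object of class `faa`: a list with `p`, `alpha` (n x p),
#'   `beta` (p x n), `archetypes` (p x m coefficient matrix `beta %*% X`),
#'   `rss`, `rss_path` (per-iteration RSS of the winning restart),
#'   `iterations`, `converged`, `n_restarts` and `best_restart`.
#' @seealso [rss_curve()], [choose_elbow()], [detect_outliers()]
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' fit <- fit_archetypes(x, p = 3, seed = 1)
#' glance(fit)
#' @export
fit_archetypes <- function(x, p, n_restarts = 10, max_iter = 150,
                           tol = 1e-6, seed = 1) {
  x <- as_fsample(x)
  X <- x$coefficients
  n <- nrow(X)
  p <- check_count(p, "p")
  n_restarts <- check_count(n_restarts, "n_restarts")
  max_iter <- check_count(max_iter, "max_iter")
  if (p > n) {
    abort("`p` cannot exceed the number of curves.",
          class = "faaknn_error_p")
  }

  R <- metric_chol(x)
  Xt <- X %*% t(R)

  if (p == n) {
    # every curve is its own archetype: the optimum is exact
    fit <- list(alpha = diag(1, n), beta = diag(1, n), rss = 0,
                rss_path = 0, iterations = 0L, converged = TRUE)
    best <- 1L
  } else {
    fit <- NULL
    best <- NA_integer_
    for (r in seq_len(n_restarts)) {
      set.seed(derive_seed(seed, p, r))
      beta0 <- matrix(rexp(p * n), p, n)
      beta0 <- beta0 / rowSums(beta0)
      cand <- aa_fit_cpp(Xt, beta0, max_iter, tol)
      if (is.null(fit) || cand$rss < fit$rss) {
        fit <- cand
        best <- r
      }
    }
  }

  structure(
    list(p = p, alpha = fit$alpha, beta = fit$beta,
         archetypes = fit$beta %*% X,
         archetypes_metric = fit$beta %*% Xt,
         rss = fit$rss, rss_path = fit$rss_path,
         iterations = fit$iterations, converged = fit$converged,
         n_restarts = n_restarts, best_restart = best,
         seed = seed, tol = tol, max_iter = max_iter,
         metric_chol = R, sample = x),
    class = "faa")
}

# Upper-triangular factor R with W = t(R) %*% R; row vectors transform as
# a %*% t(R) so that a' W a becomes an ordinary squared Euclidean norm.
metric_chol <- function(x) {
  W <- sample_metric(x)
  d <- diag(W)
  if (all(abs(W - diag(d, nrow(W))) < 1e-12)) {
    return(diag(sqrt(pmax(d, 0)), nrow(W)))
  }
  chol(W + diag(1e-12 * max(d), nrow(W)))
}

#' @export
print.faa <- function(x, ...) {
  cat(sprintf("<faa> p = %d archetypes, n = %d curves, RSS = %.6g (%d restart(s), best = %d)\n",
              x$p, nrow(x$alpha), x$rss, x$n_restarts, x$best_restart))
  invisible(x)
}

#' Project curves onto fitted archetypes
#'
#' Solves, for each curve in `newdata`, the simplex-constrained projection
#' onto the fixed archetypes of a fitted model, returning the mixture
#' weights.  With `newdata` omitted, returns the training `alpha`.
#'
#' @param object a fitted `faa` model.
#' @param newdata curves compatible with the training basis (an `fsample`
#'   or matrix with the same number of coefficient columns).
#' @param ... unused.
#' @return numeric matrix of mixture weights, rows on the unit simplex.
#' @export
predict.faa <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$alpha)
  newdata <- as_fsample(newdata)
  X <- newdata$coefficients
  if (ncol(X) != ncol(object$archetypes)) {
    abort("`newdata` has an incompatible number of coefficient columns.",
          class = "faaknn_error_mismatch")
  }
  Xt <- X %*% t(object$metric_chol)
  M <- 200 * max(1e-8, max(abs(Xt)))
  aa_alpha_step(Xt, object$archetypes_metric, M)
}

#' RSS profile over a range of archetype counts
#'
#' Fits archetype models for `p = 1, ..., p_max` (each the best of
#' `n_restarts` seeded restarts) and returns the residual-sum-of-squares
#' profile used for elbow selection of the projection range.
#'
#' @inheritParams fit_archetypes
#' @param p_max largest archetype count to fit.
#' @return a tibble with columns `p` and `rss`.
#' @export
rss_curve <- function(x, p_max, n_restarts = 10, max_iter = 150,
                      tol = 1e-6, seed = 1) {
  x <- as_fsample(x)
  p_max <- check_count(p_max, "p_max")
  if (p_max > nrow(x$coefficients)) {
    abort("`p_max` cannot exceed the number of curves.",
          class = "faaknn_error_p")
  }
  tibble::tibble(
    p = seq_len(p_max),
    rss = vapply(seq_len(p_max), function(p) {
      fit_archetypes(x, p, n_restarts = n_restarts, max_iter = max_iter,
                     tol = tol, seed = seed)$rss
    }, 1.0))
}

#' Elbow selection on an RSS profile
#'
#' Picks the archetype count where the RSS profile bends: the point with
#' maximal perpendicular distance to the chord joining the first and last
#' profile points.  This automates the visual elbow criterion; ties are
#' broken toward the smallest `p`, and any downstream use accepts a manual
#' override.
#'
#' @param curve a data frame with columns `p` and `rss` (as returned by
#'   [rss_curve()]), holding at least three points.
#' @return the selected archetype count (integer).
#' @export
choose_elbow <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("p", "rss") %in% names(curve)))
  if (nrow(curve) < 3L) {
    abort("Need at least three (p, rss) points to locate an elbow.",
          class = "faaknn_error_argument")
  }
  curve <- curve[order(curve$p), ]
  p <- curve$p; r <- curve$rss
  n <- length(p)
  dx <- p[n] - p[1]; dy <- r[n] - r[1]
  len <- sqrt(dx^2 + dy^2)
  d <- abs(dy * (p - p[1]) - dx * (r - r[1])) / max(len, .Machine$double.eps)
  inner <- 2:(n - 1L)
  as.integer(p[inner][which.max(d[inner])])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy an archetype fit
#'
#' `tidy()` returns the mixture weights in long form (one row per curve and
#' archetype); `glance()` returns a one-row model summary; `augment()`
#' returns the per-curve weights in wide form together with the curve
#' index.
#'
#' @param x a fitted `faa` model.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.faa <- function(x, ...) {
  tibble::tibble(
    curve = rep(seq_len(nrow(x$alpha)), times = x$p),
    archetype = rep(seq_len(x$p), each = nrow(x$alpha)),
    alpha = as.vector(x$alpha))
}

#' @rdname tidy.faa
#' @export
glance.faa <- function(x, ...) {
  tibble::tibble(p = x$p, rss = x$rss, iterations = x$iterations,
                 converged = x$converged, n_restarts = x$n_restarts,
                 best_restart = x$best_restart)
}

#' @rdname tidy.faa
#' @export
augment.faa <- function(x, ...) {
  alpha <- tibble::as_tibble(x$alpha, .name_repair = ~ paste0("alpha_", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(curve = seq_len(nrow(x$alpha))), alpha)
}

#' Serialise / restore an archetype fit
#'
#' Writes the fitted quantities (weights, archetype coefficients, RSS and
#' solver settings) to JSON for reproducibility, and reads them back.
#' The restored object supports `predict()` but drops the training sample.
#'
#' @param x a fitted `faa` model.
#' @param path file path.
#' @return `write_faa()` returns `path` invisibly; `read_faa()` the model.
#' @export
write_faa <- function(x, path) {
  stopifnot(inherits(x, "faa"))
  keep <- c("p", "alpha", "beta", "archetypes", "archetypes_metric", "rss",
            "rss_path", "iterations", "converged", "n_restarts",
            "best_restart", "seed", "tol", "max_iter", "metric_chol")
  jsonlite::write_json(x[keep], path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_faa
#' @export
read_faa <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("alpha", "beta", "archetypes", "archetypes_metric", "metric_chol")) {
    obj[[f]] <- as.matrix(obj[[f]])
  }
  structure(obj, class = "faa")
}
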