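#' Functional samples
#'
#' A functional sample holds `n` curves in coefficient form: an `n` by `m`
#' matrix whose rows are either basis-expansion coefficients or, for the
#' discrete family, the raw curve values on a common grid.  Multivariate
#' curves are stored as horizontally stacked per-variable coefficient
#' blocks sharing the observation index; the sample then carries one basis
#' per block and the overall inner-product metric is block diagonal.
#'
#' @param coefficients numeric `n` by `m` matrix (rows = curves).  A data
#'   frame of numeric columns is accepted and converted.
#' @param basis a [basis] object (or list of one basis per variable block).
#' @param var_blocks optional list of integer column index vectors, one per
#'   variable; defaults to a single block spanning all columns.
#'
#' @return An object of class `fsample` with fields `coefficients`,
#'   `bases`, `var_blocks`, `n_vars` and `grid` (discrete family only).
#' @export
functional_sample <- function(coefficients, basis, var_blocks = NULL) {
  coefficients <- check_finite_matrix(coefficients, "coefficients")
  bases <- if (inherits(basis, "faa_basis")) list(basis) else basis
  stopifnot(all(vapply(bases, inherits, TRUE, "faa_basis")))
  if (is.null(var_blocks)) {
    widths <- vapply(bases, function(b) b$m, 1L)
    ends <- cumsum(widths)
    var_blocks <- Map(function(s, e) seq.int(s, e), c(1L, ends[-length(ends)] + 1L), ends)
  }
  if (sum(lengths(var_blocks)) != ncol(coefficients) || any(lengths(var_blocks) == 0L)) {
    abort("Variable blocks must be non-empty and cover all coefficient columns.",
          class = "faaknn_error_blocks")
  }
  for (v in seq_along(bases)) {
    if (bases[[v]]$m != length(var_blocks[[v]])) {
      abort("Each block width must equal its basis dimension.",
            class = "faaknn_error_blocks")
    }
  }
  grid <- if (length(bases) == 1L && bases[[1L]]$family == "discrete") bases[[1L]]$grid
  structure(
    list(coefficients = coefficients, bases = bases, var_blocks = var_blocks,
         n_vars = length(var_blocks), grid = grid),
    class = "fsample")
}

#' @export
print.fsample <- function(x, ...) {
  cat(sprintf("<fsample> n = %d curves, %d coefficient column(s), %d variable(s) [%s]\n",
              nrow(x$coefficients), ncol(x$coefficients), x$n_vars,
              paste(vapply(x$bases, function(b) b$family, ""), collapse = ", ")))
  invisible(x)
}

#' @export
dim.fsample <- function(x) dim(x$coefficients)

# Block-diagonal inner-product metric of a (possibly multivariate) sample.
sample_metric <- function(x) {
  Ws <- lapply(x$bases, gram_matrix)
  m <- sum(vapply(Ws, nrow, 1L))
  W <- matrix(0, m, m)
  at <- 0L
  for (Wv in Ws) {
    idx <- at + seq_len(nrow(Wv))
    W[idx, idx] <- Wv
    at <- at + nrow(Wv)
  }
  W
}

#' Fit basis coefficients to observed curve values
#'
#' Projects each observed curve (a row of `values`, sampled on `grid`) onto
#' the basis by ordinary least squares against the basis functions
#' evaluated at the grid.  For the discrete family the grid must coincide
#' with the basis grid and the values pass through unchanged.
#'
#' @param values numeric `n` by `g` matrix of curve values.
#' @param grid length-`g` strictly increasing vector of sampling points.
#' @param basis target [basis] object with `m <= g`.
#' @return an [functional_sample()] holding the fitted coefficients.
#' @export
fit_coefficients <- function(values, grid, basis) {
  values <- check_finite_matrix(values, "values")
  stopifnot(inherits(basis, "faa_basis"))
  if (length(grid) != ncol(values) || any(diff(grid) <= 0)) {
    abort("`grid` must be strictly increasing and match the columns of `values`.",
          class = "faaknn_error_grid")
  }
  if (basis$family == "discrete") {
    if (length(grid) != basis$m || any(abs(grid - basis$grid) > 1e-8)) {
      abort("For the discrete family the sampling grid must equal the basis grid.",
            class = "faaknn_error_grid")
    }
    return(functional_sample(values, basis))
  }
  if (length(grid) < basis$m) {
    abort("Need at least as many sampling points as basis functions.",
          class = "faaknn_error_grid")
  }
  B <- eval_basis(basis, grid)
  qrB <- qr(B)
  if (qrB$rank < basis$m) {
    abort("Basis evaluation matrix is rank deficient on this grid.",
          class = "faaknn_error_rank")
  }
  coef <- t(qr.coef(qrB, t(values)))
  functional_sample(coef, basis)
}

#' Stack several functional samples into one multivariate sample
#'
#' Concatenates the coefficient blocks of samples observed on the same
#' curves (identical `n`), as used for multivariate functional archetype
#' analysis: the fit then runs on the joined `n x (m1 + m2 + ...)`
#' coefficient matrix under the block-diagonal metric.  When the variables
#' live on very different scales, per-variable standardisation (z-scoring
#' each coefficient column within its block) can be enabled.
#'
#' @param ... `fsample` objects sharing the number of curves.
#' @param standardize z-score coefficient columns per variable block.
#' @return a single multivariate `fsample`.
#' @export
stack_variables <- function(..., standardize = FALSE) {
  samples <- list(...)
  if (length(samples) == 1L && !inherits(samples[[1L]], "fsample")) {
    samples <- samples[[1L]]
  }
  stopifnot(all(vapply(samples, inherits, TRUE, "fsample")))
  if (length(samples) == 1L && !standardize) return(samples[[1L]])
  n <- unique(vapply(samples, function(s) nrow(s$coefficients), 1L))
  if (length(n) != 1L) {
    abort("All samples must contain the same number of curves.",
          class = "faaknn_error_mismatch")
  }
  blocks <- lapply(samples, function(s) {
    x <- s$coefficients
    if (standardize) {
      sds <- apply(x, 2, sd)
      x <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
      attr(x, "scaled:center") <- NULL
      attr(x, "scaled:scale") <- NULL
    }
    x
  })
  functional_sample(do.call(cbind, blocks),
                    basis = unlist(lapply(samples, function(s) s$bases),
                                   recursive = FALSE))
}

#' Extract one variable block of a multivariate sample
#'
#' @param x an `fsample`.
#' @param which block index in `1:n_vars`.
#' @return a univariate `fsample` holding that block.
#' @export
extract_variable <- function(x, which) {
  stopifnot(inherits(x, "fsample"))
  which <- check_count(which, "which")
  if (which > x$n_vars) abort("Block index out of range.", class = "faaknn_error_blocks")
  functional_sample(x$coefficients[, x$var_blocks[[which]], drop = FALSE],
                    x$bases[[which]])
}

# Coerce matrices / data frames / fsamples to an fsample for fitting.
# Plain matrices are treated as curves on an equispaced grid over [0, 1]
# (discrete family), the computation path used throughout the simulations.
as_fsample <- function(x) {
  if (inherits(x, "fsample")) return(x)
  if (inherits(x, "labeled_sample")) return(x$sample)
  x <- check_finite_matrix(x, "x")
  functional_sample(x, discrete_basis(ncol(x)))
}
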