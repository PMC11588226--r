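#' @keywords internal
"_PACKAGE"

#' @useDynLib faaknn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort %||%
#' @importFrom stats dnorm quantile rexp rnorm sd dist
NULL

# Mix a master seed with extra integer tags into a new seed in [1, 2^31 - 2].
# Used so that, e.g., the restarts of the p-archetype fit inside an ensemble
# have seeds that depend only on (master, p, restart): adding further p
# values to the ensemble never perturbs existing components.
derive_seed <- function(master, ...) {
  mod <- 2147483647  # 2^31 - 1, prime
  x <- as.numeric(master) %% mod
  for (tag in c(...)) {
    x <- (x * 48271 + as.numeric(tag) * 30269 + 1) %% mod
  }
  as.integer(x %% (mod - 1)) + 1L
}

check_number <- function(x, what, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s.", what, min),
          class = "faaknn_error_argument")
  }
  invisible(x)
}

check_count <- function(x, what, min = 1L) {
  check_number(x, what, min = min)
  if (x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number.", what),
          class = "faaknn_error_argument")
  }
  as.integer(x)
}

check_finite_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    abort(sprintf("`%s` must be a numeric matrix with all entries finite.", what),
          class = "faaknn_error_nonfinite")
  }
  x
}
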