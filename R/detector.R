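#' k-nearest-neighbour outlier scores
#'
#' Scores every point of a configuration by the sum of Euclidean distances
#' to its `k` nearest neighbours (the point itself excluded); the larger
#' the score, the more isolated the point.  Ties among equidistant
#' neighbours are broken by stable index order, so the score is
#' deterministic.
#'
#' @param points numeric matrix (rows = points) or data frame.
#' @param k number of neighbours, `1 <= k <= n - 1`; a vector of `k`
#'   values returns one score column per `k`.
#' @return for scalar `k` a numeric vector of length `n`; for vector `k`
#'   an `n` by `length(k)` matrix with columns named by `k`.
#' @examples
#' knn_score(cbind(c(0, 1, 10)), k = 1)
#' @export
knn_score <- function(points, k) {
  points <- check_finite_matrix(points, "points")
  n <- nrow(points)
  k <- vapply(k, check_count, 1L, what = "k")
  if (any(k > n - 1L)) {
    abort("`k` must be at most n - 1 (self excluded).",
          class = "faaknn_error_k")
  }
  D <- as.matrix(dist(points))
  # sorting each row once serves every k: the score for k is the k-th
  # partial sum of the sorted neighbour distances (self excluded)
  scores <- matrix(0, n, length(k), dimnames = list(NULL, k))
  for (i in seq_len(n)) {
    part <- cumsum(sort.int(D[i, -i], method = "radix"))
    scores[i, ] <- part[k]
  }
  if (length(k) == 1L) drop(scores) else scores
}

#' Harden continuous outlier scores with a boxplot fence
#'
#' Converts scores to binary labels by flagging every score above the
#' upper boxplot fence `Q3 + 1.5 IQR` (quartiles by linear interpolation).
#' Only the upper side flags: low scores indicate normality by
#' construction.
#'
#' @param scores numeric vector of at least four outlier scores.
#' @return a list with `labels` (logical vector) and `threshold` (the
#'   fence).
#' @export
harden_scores <- function(scores) {
  if (!is.numeric(scores) || length(scores) < 4L || anyNA(scores)) {
    abort("`scores` must be a numeric vector of at least four values.",
          class = "faaknn_error_argument")
  }
  q <- quantile(scores, c(0.25, 0.75), names = FALSE, type = 7)
  threshold <- q[2] + 1.5 * (q[2] - q[1])
  list(labels = scores > threshold, threshold = threshold)
}

#' Detect outlying curves by archetype projection ensembles
#'
#' The full detector: for every archetype count `p` in `p1:p2` the curves
#' are projected into the `p`-dimensional mixture-weight (alpha) subspace
#' by functional archetype analysis; in each subspace every curve receives
#' a k-nearest-neighbour outlier score for every `k` in `k_values`; the
#' final score of a curve is the arithmetic mean of its scores over all
#' `(p, k)` components.  Because the same `k` values recur in every
#' subspace the component scores share a scale, so plain averaging is a
#' well-founded ensemble and reduces the variance of the ranking.
#' Optionally the continuous scores are hardened to binary labels with the
#' upper boxplot fence ([harden_scores()]), or by flagging a fixed top
#' quantile.
#'
#' `p1` is typically placed at the elbow of the RSS profile
#' ([choose_elbow()]) and `p2` a few counts above it; `k` bounds the size
#' of a group of curves that can be flagged jointly — a cluster larger
#' than `k` keeps its members mutually proximal and is never flagged.
#'
#' @inheritParams fit_archetypes
#' @param p1,p2 smallest and largest archetype count of the projection
#'   ensemble, `1 <= p1 <= p2`.
#' @param k_values neighbour counts of the kNN scoring ensemble.
#' @param harden also return binary labels (boxplot rule by default).
#' @param top_q optional quantile in (0, 1); when given, hardening flags
#'   scores above this quantile instead of the boxplot fence.
#' @return An object of class `faa_outliers`: list with `scores`
#'   (ensemble-averaged, length n), `labels` and `threshold` (when
#'   hardened), `components` (tibble with one row per `(p, k)` pair and a
#'   list-column of score vectors), `fits` (per-`p` model summaries) and
#'   the configuration.
#' @examples
#' x <- rbind(matrix(rnorm(60, sd = 0.1), 20, 3), c(5, 5, 5))
#' res <- detect_outliers(x, p1 = 2, p2 = 3, k_values = 1:3, seed = 1)
#' which(res$labels)
#' @export
detect_outliers <- function(x, p1 = 2, p2 = 5, k_values = 5:15,
                            n_restarts = 10, max_iter = 150, tol = 1e-6,
                            seed = 1, harden = TRUE, top_q = NULL) {
  x <- as_fsample(x)
  n <- nrow(x$coefficients)
  p1 <- check_count(p1, "p1"); p2 <- check_count(p2, "p2")
  if (p1 > p2 || p2 > n) {
    abort("Require 1 <= p1 <= p2 <= n.", class = "faaknn_error_p")
  }
  k_values <- sort(unique(vapply(k_values, check_count, 1L, what = "k_values")))
  if (length(k_values) == 0L || max(k_values) > n - 1L) {
    abort("Every k must satisfy 1 <= k <= n - 1.", class = "faaknn_error_k")
  }

  fits <- vector("list", p2 - p1 + 1L)
  comp <- vector("list", (p2 - p1 + 1L) * length(k_values))
  row <- 0L
  for (p in seq.int(p1, p2)) {
    fit <- fit_archetypes(x, p, n_restarts = n_restarts,
                          max_iter = max_iter, tol = tol, seed = seed)
    fits[[p - p1 + 1L]] <- glance(fit)
    sc <- knn_score(fit$alpha, k_values)
    sc <- matrix(sc, nrow = n)
    for (j in seq_along(k_values)) {
      row <- row + 1L
      comp[[row]] <- tibble::tibble(p = p, k = k_values[j],
                                    scores = list(sc[, j]))
    }
  }
  components <- dplyr::bind_rows(comp)
  scores <- rowMeans(do.call(cbind, components$scores))

  labels <- NULL; threshold <- NULL
  if (harden) {
    if (is.null(top_q)) {
      h <- harden_scores(scores)
      labels <- h$labels; threshold <- h$threshold
    } else {
      check_number(top_q, "top_q", min = 0)
      threshold <- quantile(scores, top_q, names = FALSE, type = 7)
      labels <- scores > threshold
    }
  }

  structure(
    list(scores = scores, labels = labels, threshold = threshold,
         components = components, fits = dplyr::bind_rows(fits),
         config = list(p1 = p1, p2 = p2, k_values = k_values,
                       n_restarts = n_restarts, max_iter = max_iter,
                       tol = tol, seed = seed, harden = harden,
                       top_q = top_q)),
    class = "faa_outliers")
}

#' @export
print.faa_outliers <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<faa_outliers> n = %d curves, p = %d..%d, k = {%s}\n",
              length(x$scores), cfg$p1, cfg$p2,
              paste(cfg$k_values, collapse = ", ")))
  if (!is.null(x$labels)) {
    cat(sprintf("  flagged %d curve(s) above fence %.4g: %s\n",
                sum(x$labels), x$threshold,
                paste(which(x$labels), collapse = ", ")))
  }
  invisible(x)
}

#' Tidy detector output
#'
#' `tidy()` returns one row per curve with its ensemble score (and label
#' when hardened); `glance()` summarises the run.
#'
#' @param x a `faa_outliers` object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.faa_outliers <- function(x, ...) {
  out <- tibble::tibble(curve = seq_along(x$scores), score = x$scores)
  if (!is.null(x$labels)) out$outlier <- x$labels
  out
}

#' @rdname tidy.faa_outliers
#' @export
glance.faa_outliers <- function(x, ...) {
  tibble::tibble(
    n = length(x$scores), p1 = x$config$p1, p2 = x$config$p2,
    n_components = nrow(x$components),
    n_flagged = if (is.null(x$labels)) NA_integer_ else sum(x$labels),
    threshold = if (is.null(x$threshold)) NA_real_ else x$threshold)
}
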