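# Independent reference implementations used as oracles.  These stay
# deliberately separate from the package's solver paths: the kNN oracle
# works from the full pairwise distance matrix; the archetype reference is
# a plain-R alternating solver built on pracma's Lawson-Hanson routine.

# Sum of distances to the k nearest neighbours via the full distance matrix.
oracle_knn <- function(points, k) {
  D <- as.matrix(stats::dist(points))
  sapply(seq_len(nrow(D)), function(i) sum(sort(D[i, -i])[seq_len(k)]))
}

# Exact solve of min ||A x - b|| subject to x >= 0, sum(x) = 1, by brute
# enumeration of active supports: for every candidate support the
# equality-constrained least-squares KKT system is solved directly and the
# best nonnegative solution is kept.  Exhaustive, so exact up to linear
# algebra; the optimal support has at most rank(A) + 1 elements.
oracle_simplex_solve <- function(A, b, max_support = NULL) {
  q <- ncol(A)
  if (is.null(max_support)) max_support <- qr(A)$rank + 1L
  max_support <- min(max_support, q)
  best <- NULL; best_obj <- Inf
  for (s in seq_len(max_support)) {
    for (S in utils::combn(q, s, simplify = FALSE)) {
      AS <- A[, S, drop = FALSE]
      K <- rbind(cbind(crossprod(AS), 1), c(rep(1, s), 0))
      sol <- tryCatch(solve(K, c(crossprod(AS, b), 1)), error = function(e) NULL)
      if (is.null(sol)) next
      xS <- sol[seq_len(s)]
      if (any(xS < -1e-10)) next
      obj <- sum((AS %*% xS - b)^2)
      if (obj < best_obj - 1e-15) {
        best_obj <- obj
        best <- numeric(q); best[S] <- pmax(xS, 0)
      }
    }
  }
  best / sum(best)
}

oracle_simplex_rows <- function(Design, targets, max_support = NULL) {
  t(apply(targets, 1L, function(b) oracle_simplex_solve(Design, b, max_support)))
}

# Reference archetype fit: the standard alternating scheme, but with every
# simplex subproblem solved exactly by support enumeration (no penalty
# device), run from many Dirichlet starts to a tight tolerance; returns
# the best RSS found.
oracle_aa_rss <- function(X, p, n_restarts = 200, max_iter = 500,
                          tol = 1e-10, seed = 99) {
  n <- nrow(X)
  rank1 <- qr(X)$rank + 1L
  best <- Inf
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    beta <- matrix(rexp(p * n), p, n)
    beta <- beta / rowSums(beta)
    rss_old <- Inf
    for (it in seq_len(max_iter)) {
      Z <- beta %*% X
      alpha <- oracle_simplex_rows(t(Z), X)
      Zt <- tryCatch(solve(crossprod(alpha) + diag(1e-12, p), t(alpha) %*% X),
                     error = function(e) matrix(colMeans(X), p, ncol(X), byrow = TRUE))
      beta <- oracle_simplex_rows(t(X), Zt, max_support = rank1)
      rss <- sum((X - alpha %*% beta %*% X)^2)
      if (is.finite(rss_old) && abs(rss_old - rss) < tol * max(rss_old, 1e-12)) break
      rss_old <- rss
    }
    if (rss < best) best <- rss
  }
  best
}

# Global reference for two archetypes of planar data: archetypes lie on
# the boundary of the convex hull, so both are mixtures of the endpoints
# of a hull edge.  Grid every edge-mixture weight at `lam_step`, evaluate
# the exact projection objective (sum of squared distances to the segment
# joining the two candidate archetypes), then polish the best grid cell
# with box-constrained quasi-Newton.  Independent of the package solver.
oracle_planar_aa2_rss <- function(X, lam_step = 0.01) {
  stopifnot(ncol(X) == 2L)
  hull <- grDevices::chull(X)
  edges <- cbind(hull, c(hull[-1L], hull[1L]))
  lam <- seq(0, 1, by = lam_step)
  cand <- do.call(rbind, lapply(seq_len(nrow(edges)), function(e) {
    A <- X[edges[e, 1L], ]; B <- X[edges[e, 2L], ]
    cbind((1 - lam) * A[1] + lam * B[1], (1 - lam) * A[2] + lam * B[2],
          e, lam)
  }))
  K <- nrow(cand)
  seg_obj <- function(z1, z2) {
    v <- z2 - z1
    v2 <- max(sum(v^2), 1e-300)
    tot <- 0
    for (i in seq_len(nrow(X))) {
      w <- X[i, ] - z1
      tt <- min(max(sum(w * v) / v2, 0), 1)
      tot <- tot + sum((w - tt * v)^2)
    }
    tot
  }
  best <- Inf; bi <- bj <- NA
  for (i in seq_len(K)) {
    z1 <- cand[i, 1:2]
    v <- cand[, 1:2, drop = FALSE] - matrix(z1, K, 2, byrow = TRUE)
    v2 <- pmax(rowSums(v^2), 1e-300)
    tot <- numeric(K)
    for (r in seq_len(nrow(X))) {
      w <- X[r, ] - z1
      dwv <- c(v %*% w)
      tt <- pmin(pmax(dwv / v2, 0), 1)
      tot <- tot + sum(w^2) - 2 * tt * dwv + tt^2 * v2
    }
    j <- which.min(tot)
    if (tot[j] < best) { best <- tot[j]; bi <- i; bj <- j }
  }
  pol <- stats::optim(
    c(cand[bi, 4L], cand[bj, 4L]),
    function(par) {
      e1 <- edges[cand[bi, 3L], ]; e2 <- edges[cand[bj, 3L], ]
      seg_obj((1 - par[1]) * X[e1[1], ] + par[1] * X[e1[2], ],
              (1 - par[2]) * X[e2[1], ] + par[2] * X[e2[2], ])
    },
    method = "L-BFGS-B", lower = 0, upper = 1)
  min(best, pol$value)
}

# L2 Gram matrix by dense trapezoid integration of basis-function products.
oracle_gram_trapz <- function(basis, n_grid = 10001) {
  g <- seq(basis$domain[1], basis$domain[2], length.out = n_grid)
  B <- eval_basis(basis, g)
  h <- diff(g)[1]
  w <- c(h / 2, rep(h, n_grid - 2L), h / 2)
  crossprod(B * sqrt(w))
}

# Small deterministic multi-cluster coefficient fixture for solver tests.
fixture_clusters <- function(n_per = 8, seed = 7) {
  set.seed(seed)
  centers <- rbind(c(0, 0, 0, 0, 0), c(6, 0, 2, 0, 0), c(0, 6, 0, 2, 0))
  do.call(rbind, lapply(seq_len(nrow(centers)), function(c0) {
    matrix(rnorm(n_per * 5, sd = 0.4), n_per, 5) +
      matrix(centers[c0, ], n_per, 5, byrow = TRUE)
  }))
}
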