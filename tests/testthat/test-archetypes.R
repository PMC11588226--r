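test_that("a single archetype is the column mean with unit weights", {
  set.seed(11)
  X <- matrix(rnorm(20 * 10), 20, 10)
  fit <- fit_archetypes(X, 1, seed = 1)
  expect_lt(max(abs(fit$archetypes - matrix(colMeans(X), 1))), 1e-8)
  expect_equal(unname(fit$alpha[, 1]), rep(1, 20))
  # W = h I for the default discrete basis on [0, 1]
  h <- 1 / 9
  ctr <- sweep(X, 2, colMeans(X))
  expect_equal(fit$rss, h * sum(ctr^2), tolerance = 1e-8)
})

test_that("hull vertices are recovered exactly when p matches their count", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(0.2, 0.2))
  fit <- fit_archetypes(X, 3, seed = 1)
  expect_lt(fit$rss, 1e-8)
  # each vertex is recovered by some archetype
  D <- as.matrix(dist(rbind(X[1:3, ], fit$archetypes)))[1:3, 4:6]
  expect_lt(max(apply(D, 1, min)), 1e-4)
  # and the vertex rows of alpha are unit rows up to permutation
  expect_equal(sort(apply(fit$alpha[1:3, ], 1, max)), rep(1, 3),
               tolerance = 1e-4)
})

test_that("p = n returns the exact identity decomposition", {
  X <- matrix(rnorm(30), 6, 5)
  fit <- fit_archetypes(X, 6, seed = 1)
  expect_identical(fit$alpha, diag(1, 6))
  expect_identical(fit$rss, 0)
})

test_that("fits are feasible, internally consistent, and seed-deterministic", {
  set.seed(5)
  for (case in 1:3) {
    X <- switch(case,
      fixture_clusters(),
      matrix(rnorm(60), 12, 5),
      matrix(rexp(80), 16, 5))
    for (p in c(2, 4)) {
      fit <- fit_archetypes(X, p, seed = case)
      expect_lt(max(abs(rowSums(fit$alpha) - 1)), 1e-6)
      expect_lt(max(abs(rowSums(fit$beta) - 1)), 1e-6)
      expect_gte(min(fit$alpha), -1e-9)
      expect_gte(min(fit$beta), -1e-9)
      expect_lt(max(abs(fit$archetypes - fit$beta %*% X)), 1e-8)
      # recomputed W-metric RSS (h-scaled Euclidean for the discrete basis)
      h <- 1 / (ncol(X) - 1)
      resid <- X - fit$alpha %*% fit$beta %*% X
      expect_equal(fit$rss, h * sum(resid^2), tolerance = 1e-6)
      # per-iteration monotonicity of the recorded path
      expect_true(all(diff(fit$rss_path) <= 1e-9))
      # determinism
      refit <- fit_archetypes(X, p, seed = case)
      expect_identical(refit$rss, fit$rss)
      expect_identical(refit$alpha, fit$alpha)
    }
  }
})

test_that("RSS decreases softly in p and vanishes when p covers the data", {
  X <- fixture_clusters()
  curve <- rss_curve(X, 6, seed = 3)
  expect_true(all(curve$rss[-1] <= curve$rss[-nrow(curve)] * 1.05))

  # two distinct rows: two archetypes suffice
  X2 <- rbind(matrix(1, 3, 4), matrix(-1, 4, 4))
  c2 <- rss_curve(X2, 3, seed = 1)
  expect_lt(c2$rss[2], 1e-8)
  expect_lt(c2$rss[3], 1e-8)

  # p = n reproduces the sample exactly
  Xs <- matrix(rnorm(20), 5, 4)
  expect_lt(rss_curve(Xs, 5, seed = 1)$rss[5], 1e-8)
})

test_that("row permutation permutes the mixture weights with it", {
  X <- fixture_clusters()
  set.seed(8)
  perm <- sample(nrow(X))
  f1 <- fit_archetypes(X, 3, seed = 5)
  f2 <- fit_archetypes(X[perm, ], 3, seed = 5)
  # match archetypes of the two fits, then compare permuted weights
  D <- as.matrix(dist(rbind(f1$archetypes, f2$archetypes)))[1:3, 4:6]
  match_j <- apply(D, 1, which.min)
  expect_equal(unname(sort(match_j)), 1:3)  # bijective matching
  expect_lt(max(abs(f1$alpha[perm, ] - f2$alpha[, match_j])), 1e-2)
})

test_that("projection onto fixed archetypes recovers known mixtures", {
  X <- fixture_clusters()
  fit <- fit_archetypes(X, 3, seed = 2)
  # the archetypes themselves project to unit rows
  A <- predict(fit, fit$archetypes)
  expect_equal(unname(apply(A, 1, max)), rep(1, 3), tolerance = 1e-6)
  # training data reproduce the training weights
  expect_lt(max(abs(predict(fit, X) - fit$alpha)), 1e-6)
  # the midpoint of two archetypes splits its weight evenly
  fit2 <- fit_archetypes(X, 2, seed = 2)
  mid <- (fit2$archetypes[1, ] + fit2$archetypes[2, ]) / 2
  expect_equal(unname(predict(fit2, matrix(mid, 1))[1, ]), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_error(predict(fit, matrix(0, 2, 3)), class = "faaknn_error_mismatch")
})

test_that("elbow selection maximises distance to the first-last chord", {
  expect_identical(choose_elbow(data.frame(p = 1:4, rss = c(100, 10, 9, 8.5))), 2L)
  expect_identical(choose_elbow(data.frame(p = 1:4, rss = c(50, 40, 5, 4))), 3L)
  # a strictly linear decline has no elbow; ties break toward small p
  expect_identical(choose_elbow(data.frame(p = 1:5, rss = c(50, 40, 30, 20, 10))), 2L)
  expect_error(choose_elbow(data.frame(p = 1:2, rss = c(2, 1))),
               class = "faaknn_error_argument")
})

test_that("invalid archetype requests error cleanly", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_archetypes(X, 0, seed = 1), class = "faaknn_error_argument")
  expect_error(fit_archetypes(X, 6, seed = 1), class = "faaknn_error_p")
  X[2, 2] <- NA
  expect_error(fit_archetypes(X, 2, seed = 1), class = "faaknn_error_nonfinite")
})

test_that("tidiers expose weights and summaries; JSON round-trips the model", {
  X <- fixture_clusters()
  fit <- fit_archetypes(X, 3, seed = 4)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(X) * 3L)
  expect_equal(sum(td$alpha), nrow(X), tolerance = 1e-6)
  expect_equal(td$alpha[td$curve == 2], unname(fit$alpha[2, ]))
  gl <- glance(fit)
  expect_identical(gl$p, 3L)
  expect_identical(gl$rss, fit$rss)
  ag <- augment(fit)
  expect_equal(unname(as.matrix(ag[, -1])), unname(fit$alpha))

  path <- withr::local_tempfile(fileext = ".json")
  write_faa(fit, path)
  back <- read_faa(path)
  expect_equal(back$rss, fit$rss)
  expect_lt(max(abs(predict(back, X) - fit$alpha)), 1e-6)
})
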