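#' Gaussian-process noise curves
#'
#' Draws `n` independent zero-mean Gaussian-process curves on `grid` with
#' the exponential covariance `gamma(s, t) = 0.3 exp(-|s - t| / 0.3)`
#' (marginal variance 0.3, correlation length 0.3).  Realisations are
#' produced by multiplying standard normal draws with the symmetric matrix
#' square root of the covariance evaluated on the grid, and are
#' deterministic given `seed`.
#'
#' @param n number of curves.
#' @param grid strictly increasing evaluation points.
#' @param seed integer seed.
#' @param variance,range covariance parameters; the defaults are the ones
#'   used throughout the simulation study.
#' @return an `n` by `length(grid)` matrix, one curve per row.
#' @export
gp_noise <- function(n, grid, seed = 1, variance = 0.3, range = 0.3) {
  n <- check_count(n, "n")
  if (any(diff(grid) <= 0)) {
    abort("`grid` must be strictly increasing.", class = "faaknn_error_grid")
  }
  S <- gp_cov_sqrt(grid, variance, range)
  set.seed(seed)
  matrix(rnorm(n * length(grid)), n, length(grid)) %*% S
}

#' @rdname gp_noise
#' @export
gp_covariance <- function(grid, variance = 0.3, range = 0.3) {
  variance * exp(-abs(outer(grid, grid, "-")) / range)
}

gp_cov_sqrt <- function(grid, variance, range) {
  G <- gp_covariance(grid, variance, range)
  e <- eigen(G, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Cluster-1 mean function
#'
#' The baseline mean `30 t (1 - t)^{3/2}` of the simulated curves, extended
#' continuously by zero for `t > 1` (the mean vanishes at `t = 1` and the
#' expression is undefined beyond it).  The extension is what makes the
#' horizontally shifted evaluations `t + 0.15` and `t + 0.3` well defined
#' on the observation grid.
#'
#' @param t evaluation points, `t >= 0`.
#' @return numeric vector of mean values.
#' @export
mean_cluster1 <- function(t) {
  ifelse(t <= 1, 30 * t * (1 - pmin(t, 1))^1.5, 0)
}

# Alternative mean shapes of the "shape" outlier family.
mean_shape_out <- function(t) 15 * t^2 * (1 - t)^2
mean_shape_c2 <- function(t) 10 * t^(1 / 3) * (1 - t)^3

#' Truncated standard-normal bump
#'
#' A localized bump used by the isolated outlier family: zero outside a
#' window of `2 * half_window + 1` grid points centred on
#' `center` (1-based), and inside the window the standard normal density
#' evaluated at equally spaced arguments spanning `[-3, 3]`.
#'
#' @param center 1-based index of the bump centre on the grid.
#' @param half_window window half-width in grid points (default 5, giving
#'   the 11-point windows used in the simulations).
#' @param grid_size number of grid points.
#' @return numeric vector of length `grid_size`.
#' @examples
#' normal_bump(6)[6]   # peak value dnorm(0)
#' @export
normal_bump <- function(center, half_window = 5, grid_size = 25) {
  center <- check_count(center, "center")
  half_window <- check_count(half_window, "half_window")
  grid_size <- check_count(grid_size, "grid_size")
  idx <- (center - half_window):(center + half_window)
  if (idx[1] < 1L || idx[length(idx)] > grid_size) {
    abort("Bump window does not fit inside the grid.",
          class = "faaknn_error_window")
  }
  out <- numeric(grid_size)
  out[idx] <- dnorm(seq(-3, 3, length.out = length(idx)))
  out
}

outlier_types <- c("amplitude", "v_shift", "h_shift", "shape", "isolated")

#' Simulate a clustered functional dataset with planted outliers
#'
#' Generates the synthetic study data: curves observed on `grid_size`
#' equidistant points in `[0, 1]`, built from the baseline process
#' `X1(t) = 30 t (1 - t)^{3/2} + e(t)` with Gaussian-process noise `e`
#' ([gp_noise()]).  Scenario 1 (`"one_cluster"`) contains a single cluster
#' of `n_total - n_outliers` baseline curves plus `n_outliers` planted
#' outliers; scenario 2 (`"two_cluster"`) splits the normal curves into a
#' main cluster and a second cluster of `n_cluster2` curves whose shape
#' depends on the outlier family.
#'
#' The five outlier families displace the systematic part of the process;
#' the Gaussian-process noise keeps unit scale (variance 0.3) for every
#' curve, so contamination changes the signal, not the noise level:
#' \describe{
#'   \item{amplitude}{outliers `3 m(t) + e(t)`, cluster 2 `6 m(t) + e(t)`,
#'     with `m` the baseline mean}
#'   \item{v_shift}{outliers `3 + X1(t)`, cluster 2 `6 + X1(t)`}
#'   \item{h_shift}{outliers `X1(t + 0.15)`, cluster 2 `X1(t + 0.3)`
#'     (fresh noise on the observation grid, zero-extended mean)}
#'   \item{shape}{outliers `15 t^2 (1 - t)^2 + e(t)`, cluster 2
#'     `10 t^{1/3} (1 - t)^3 + e(t)`}
#'   \item{isolated}{outliers `X1(t) + 15 Z1`, cluster 2 `X1(t) + 15 Z2`,
#'     with `Z1`/`Z2` the [normal_bump()] centred on the 6th / 20th grid
#'     point}
#' }
#'
#' @param scenario `"one_cluster"`/`1` or `"two_cluster"`/`2`.
#' @param outlier_type one of `"amplitude"`, `"v_shift"`, `"h_shift"`,
#'   `"shape"`, `"isolated"`.
#' @param n_total total number of curves.
#' @param n_outliers number of planted outliers.
#' @param n_cluster2 size of the second cluster (two-cluster scenario).
#' @param grid_size number of equidistant observation points in `[0, 1]`.
#' @param seed integer seed; the dataset is deterministic given all
#'   arguments.
#' @return An object of class `labeled_sample`: list with `sample` (an
#'   [functional_sample()] on the discrete basis), `labels` (logical,
#'   `TRUE` for planted outliers), `cluster_ids` (0 = outlier, 1, 2 =
#'   clusters), `base_curves` (baseline realisations `m(t) + e(t)` sharing
#'   the noise paths of the generated curves, from which the amplitude /
#'   v-shift / isolated transforms reproduce exactly) and the
#'   generating configuration.  Curves are ordered cluster 1, cluster 2,
#'   outliers.
#' @export
simulate_scenario <- function(scenario = c("one_cluster", "two_cluster"),
                              outlier_type = outlier_types,
                              n_total = 100, n_outliers = 5, n_cluster2 = 25,
                              grid_size = 25, seed = 1) {
  if (is.numeric(scenario)) scenario <- c("one_cluster", "two_cluster")[scenario]
  scenario <- match.arg(scenario)
  outlier_type <- match.arg(outlier_type)
  n_total <- check_count(n_total, "n_total")
  n_outliers <- check_count(n_outliers, "n_outliers")
  grid_size <- check_count(grid_size, "grid_size", min = 2L)
  n_c2 <- if (scenario == "two_cluster") check_count(n_cluster2, "n_cluster2") else 0L
  n_c1 <- n_total - n_outliers - n_c2
  if (n_c1 < 1L) {
    abort("Cluster sizes and outlier count must sum to at most n_total.",
          class = "faaknn_error_config")
  }

  grid <- seq(0, 1, length.out = grid_size)
  mu1 <- mean_cluster1(grid)

  base1 <- sweep(gp_noise(n_c1, grid, seed = derive_seed(seed, 1L)), 2, mu1, "+")
  noise2 <- gp_noise(max(n_c2, 1L), grid, seed = derive_seed(seed, 2L))[seq_len(n_c2), , drop = FALSE]
  noise_out <- gp_noise(n_outliers, grid, seed = derive_seed(seed, 3L))
  base2 <- sweep(noise2, 2, mu1, "+")
  base_out <- sweep(noise_out, 2, mu1, "+")

  out_curves <- switch(outlier_type,
    amplitude = sweep(noise_out, 2, 3 * mu1, "+"),
    v_shift = 3 + base_out,
    h_shift = sweep(noise_out, 2, mean_cluster1(grid + 0.15), "+"),
    shape = sweep(noise_out, 2, mean_shape_out(grid), "+"),
    isolated = sweep(base_out, 2, 15 * normal_bump(6L, grid_size = grid_size), "+"))
  c2_curves <- if (n_c2 > 0L) switch(outlier_type,
    amplitude = sweep(noise2, 2, 6 * mu1, "+"),
    v_shift = 6 + base2,
    h_shift = sweep(noise2, 2, mean_cluster1(grid + 0.3), "+"),
    shape = sweep(noise2, 2, mean_shape_c2(grid), "+"),
    isolated = sweep(base2, 2, 15 * normal_bump(20L, grid_size = grid_size), "+"))

  curves <- rbind(base1, c2_curves, out_curves)
  cluster_ids <- c(rep(1L, n_c1), rep(2L, n_c2), rep(0L, n_outliers))

  structure(
    list(sample = functional_sample(curves, discrete_basis(grid_size)),
         labels = cluster_ids == 0L,
         cluster_ids = cluster_ids,
         base_curves = rbind(base1, base2, base_out),
         config = list(scenario = scenario, outlier_type = outlier_type,
                       n_total = n_total, n_outliers = n_outliers,
                       n_cluster2 = n_c2, grid_size = grid_size, seed = seed)),
    class = "labeled_sample")
}

#' @export
print.labeled_sample <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<labeled_sample> %s%s: %d curves (%d outlier(s)) on %d grid points, seed %d\n",
              cfg$scenario, if (!is.null(cfg$outlier_type)) paste0(", ", cfg$outlier_type) else "",
              length(x$labels), sum(x$labels), ncol(x$sample$coefficients), cfg$seed))
  invisible(x)
}

#' Tidy a labelled sample into long format
#'
#' One row per curve and grid point, with curve index, cluster id and
#' outlier label — the natural input for ggplot2 curve displays.
#'
#' @param x a `labeled_sample`.
#' @param ... unused.
#' @return a tibble with columns `curve`, `t`, `value`, `cluster`,
#'   `outlier`.
#' @export
tidy.labeled_sample <- function(x, ...) {
  curves <- x$sample$coefficients
  grid <- x$sample$grid %||% seq_len(ncol(curves))
  tibble::tibble(
    curve = rep(seq_len(nrow(curves)), each = ncol(curves)),
    t = rep(grid, times = nrow(curves)),
    value = as.vector(t(curves)),
    cluster = rep(x$cluster_ids, each = ncol(curves)),
    outlier = rep(x$labels, each = ncol(curves)))
}

#' Multicluster toy fixture
#'
#' A synthetic 66-curve dataset built for demonstrating how the
#' neighbour count `k` controls which groups are flagged: three
#' well-separated clusters of 20 curves, one micro-cluster of 5 curves and
#' a single isolated curve.  Running the detector with `p1 = 3`, `p2 = 5`
#' and `k` in `1:5` flags only the singleton; with `k` in `6:10` the five
#' micro-cluster members lose their mutual support (each has only four
#' mates) and are flagged as a group.  The construction is synthetic and
#' not a reconstruction of any published dataset.
#'
#' Within-cluster dispersion is deterministic by design: members of each
#' cluster sit on a ring of phase-shifted sinusoidal perturbations around
#' the cluster mean (alternating ring radii `0.75 r` and `1.25 r`), which
#' makes every member's neighbour geometry homogeneous — no spurious
#' "lonely" curves arise inside the large clusters, so the k-threshold
#' behaviour above is a property of the constructed separations rather
#' than of a lucky noise draw.  The micro-cluster ring radius is shrunk by
#' `sin(pi/20) / sin(pi/5)` so its internal nearest-neighbour distances
#' match those of the 20-curve clusters.  The seed only drives a small
#' i.i.d. observation noise (sd 0.05).
#'
#' @param seed integer seed.
#' @param grid_size number of grid points on `[0, 1]`.
#' @return a `labeled_sample`; `cluster_ids` are 1-3 for the large
#'   clusters, 4 for the micro-cluster and 0 for the singleton, and
#'   `labels` marks only the singleton.
#' @export
toy_multicluster <- function(seed = 1, grid_size = 25) {
  grid_size <- check_count(grid_size, "grid_size", min = 2L)
  grid <- seq(0, 1, length.out = grid_size)
  ring <- function(mu, n0, r) {
    t(vapply(seq_len(n0) - 1L, function(i) {
      ri <- r * (0.75 + 0.5 * (i %% 2))
      mu + ri * sin(2 * pi * grid + 2 * pi * i / n0)
    }, numeric(grid_size)))
  }
  eps <- 0.8
  big_means <- list(10 * sin(pi * grid), 10 * (1 - grid), 10 * grid)
  big <- do.call(rbind, lapply(big_means, ring, n0 = 20L, r = eps))
  r_micro <- eps * sin(pi / 20) / sin(pi / 5)
  micro <- ring(10 * sin(pi * grid) + 4 * cos(pi * grid), 5L, r_micro)
  single <- matrix(25, 1L, grid_size)
  set.seed(seed)
  curves <- rbind(big, micro, single)
  curves <- curves + matrix(rnorm(length(curves), sd = 0.05), nrow(curves))
  sizes <- c(20L, 20L, 20L, 5L, 1L)
  cluster_ids <- rep(c(1L, 2L, 3L, 4L, 0L), times = sizes)
  structure(
    list(sample = functional_sample(curves, discrete_basis(grid_size)),
         labels = cluster_ids == 0L,
         cluster_ids = cluster_ids,
         base_curves = curves,
         config = list(scenario = "toy_multicluster", outlier_type = NULL,
                       n_total = sum(sizes), n_outliers = 1L,
                       grid_size = grid_size, seed = seed)),
    class = "labeled_sample")
}
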