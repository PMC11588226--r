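#' True- and false-positive rates of one detection run
#'
#' Compares hardened detector labels against the ground truth of a
#' simulated dataset: the true-positive rate is the fraction of planted
#' outliers flagged, the false-positive rate the fraction of normal curves
#' flagged.  Both are exact counts over the respective groups.
#'
#' @param labeled a `labeled_sample` (see [simulate_scenario()]).
#' @param result a hardened `faa_outliers` run on the same curves; when
#'   omitted, [detect_outliers()] is run with the settings in `...`.
#' @param ... detector settings forwarded to [detect_outliers()] when
#'   `result` is missing.
#' @return a one-row tibble with columns `tp` and `fp`.
#' @export
evaluate_replicate <- function(labeled, result = NULL, ...) {
  stopifnot(inherits(labeled, "labeled_sample"))
  if (is.null(result)) {
    result <- detect_outliers(labeled$sample, ..., harden = TRUE)
  }
  stopifnot(inherits(result, "faa_outliers"))
  if (is.null(result$labels)) {
    abort("Detector result carries no hardened labels.",
          class = "faaknn_error_labels")
  }
  if (length(result$labels) != length(labeled$labels)) {
    abort("Detector result and sample have different sizes.",
          class = "faaknn_error_mismatch")
  }
  truth <- labeled$labels
  tibble::tibble(tp = mean(result$labels[truth]),
                 fp = mean(result$labels[!truth]))
}

#' Replicated detection study
#'
#' Generates `n_reps` independently seeded datasets from one scenario /
#' outlier-family combination, runs the hardened detector on each, and
#' summarises the per-replicate true- and false-positive proportions by
#' their mean and standard deviation.  Data seeds and detector seeds are
#' derived independently from the master seed, so either side can be held
#' fixed in ablations.
#'
#' @inheritParams simulate_scenario
#' @inheritParams detect_outliers
#' @param n_reps number of replicate datasets.
#' @param seed master seed for the whole study.
#' @return a one-row tibble (class `faa_study`) with columns `scenario`,
#'   `outlier_type`, `n_reps`, `tp_mean`, `tp_sd`, `fp_mean`, `fp_sd`;
#'   the per-replicate table is attached as attribute `"replicates"`.
#' @export
run_study <- function(scenario = "one_cluster", outlier_type = "amplitude",
                      n_reps = 50, p1 = 2, p2 = 5, k_values = 5:15,
                      n_restarts = 10, n_total = 100, n_outliers = 5,
                      n_cluster2 = 25, grid_size = 25, seed = 1) {
  n_reps <- check_count(n_reps, "n_reps")
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    labeled <- simulate_scenario(
      scenario, outlier_type, n_total = n_total, n_outliers = n_outliers,
      n_cluster2 = n_cluster2, grid_size = grid_size,
      seed = derive_seed(seed, r, 1L))
    res <- evaluate_replicate(labeled, p1 = p1, p2 = p2, k_values = k_values,
                              n_restarts = n_restarts,
                              seed = derive_seed(seed, r, 2L))
    dplyr::mutate(res, rep = r, .before = 1L)
  })
  out <- tibble::tibble(
    scenario = if (is.numeric(scenario)) c("one_cluster", "two_cluster")[scenario] else scenario,
    outlier_type = outlier_type,
    n_reps = n_reps,
    tp_mean = mean(reps$tp), tp_sd = if (n_reps > 1) sd(reps$tp) else 0,
    fp_mean = mean(reps$fp), fp_sd = if (n_reps > 1) sd(reps$fp) else 0)
  attr(out, "replicates") <- reps
  class(out) <- c("faa_study", class(out))
  out
}

#' Format study summaries as a report table
#'
#' Binds study summaries into one table with `mean (sd)` formatting for
#' the true- and false-positive proportions, optionally writing both the
#' raw numbers (CSV) and returning the pretty table.
#'
#' @param summaries a list of [run_study()] results (or a single one).
#' @param path optional CSV path for the raw numeric table.
#' @param digits digits for the formatted columns.
#' @return a tibble with columns `scenario`, `outlier_type`, `n_reps`,
#'   `true_positive`, `false_positive` (formatted strings).
#' @export
summary_table <- function(summaries, path = NULL, digits = 2) {
  if (inherits(summaries, "data.frame")) summaries <- list(summaries)
  raw <- if (length(summaries) == 0L) {
    tibble::tibble(scenario = character(), outlier_type = character(),
                   n_reps = integer(), tp_mean = numeric(), tp_sd = numeric(),
                   fp_mean = numeric(), fp_sd = numeric())
  } else {
    dplyr::bind_rows(lapply(summaries, function(s) tibble::as_tibble(unclass(s))))
  }
  if (!is.null(path)) readr::write_csv(raw, path)
  fmt <- function(m, s) sprintf(paste0("%.", digits, "f (%.", digits, "f)"), m, s)
  dplyr::transmute(raw,
    scenario = .data$scenario, outlier_type = .data$outlier_type,
    n_reps = .data$n_reps,
    true_positive = fmt(.data$tp_mean, .data$tp_sd),
    false_positive = fmt(.data$fp_mean, .data$fp_sd))
}

#' @importFrom rlang .data
NULL
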