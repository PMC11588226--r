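#' Read and write curve matrices as CSV
#'
#' Curves are stored one per row; the header row holds the grid values
#' (for the discrete family) or coefficient indices.  A JSON sidecar file
#' (`<path>.json` by default) records the basis family, domain and
#' variable blocks so the sample can be reconstructed faithfully.
#'
#' @param x an [functional_sample()] or plain matrix.
#' @param path CSV file path.
#' @param sidecar sidecar JSON path; `NULL` suppresses it on write and
#'   falls back to the discrete family on read if absent.
#' @return `write_curves()` returns `path` invisibly; `read_curves()` an
#'   `fsample`.
#' @export
write_curves <- function(x, path, sidecar = paste0(path, ".json")) {
  x <- as_fsample(x)
  mat <- x$coefficients
  header <- if (!is.null(x$grid)) x$grid else seq_len(ncol(mat))
  df <- as.data.frame(mat)
  names(df) <- as.character(header)
  readr::write_csv(df, path)
  if (!is.null(sidecar)) {
    meta <- list(
      families = vapply(x$bases, function(b) b$family, ""),
      m = vapply(x$bases, function(b) b$m, 1L),
      domains = lapply(x$bases, function(b) b$domain),
      orders = lapply(x$bases, function(b) b$order),
      var_blocks = x$var_blocks,
      n = nrow(mat))
    jsonlite::write_json(meta, sidecar, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path, sidecar = paste0(path, ".json")) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  mat <- as.matrix(df)
  dimnames(mat) <- NULL
  if (!is.null(sidecar) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    bases <- lapply(seq_along(meta$families), function(v) {
      dom <- if (is.list(meta$domains)) meta$domains[[v]] else meta$domains
      switch(meta$families[[v]],
        discrete = discrete_basis(meta$m[[v]], dom[1], dom[2]),
        fourier = fourier_basis(meta$m[[v]], dom[1], dom[2]),
        bspline = bspline_basis(meta$m[[v]], dom[1], dom[2],
                                order = if (is.list(meta$orders)) meta$orders[[v]] else meta$orders))
    })
    return(functional_sample(mat, bases))
  }
  grid <- suppressWarnings(as.numeric(names(df)))
  if (!anyNA(grid) && all(diff(grid) > 0)) {
    h <- diff(grid)
    if (max(abs(h - h[1])) < 1e-8) {
      return(functional_sample(mat, discrete_basis(ncol(mat), grid[1],
                                                   grid[length(grid)])))
    }
  }
  functional_sample(mat, discrete_basis(ncol(mat)))
}

#' Write detector scores as CSV
#'
#' One row per curve with its identifier, ensemble score and (when
#' hardened) binary label; a JSON sidecar stores the configuration, the
#' fence threshold and per-component summaries.
#'
#' @param result a `faa_outliers` object.
#' @param path CSV file path.
#' @param sidecar sidecar JSON path; `NULL` suppresses it.
#' @return `path`, invisibly.
#' @export
write_scores <- function(result, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(result, "faa_outliers"))
  df <- tidy(result)
  names(df)[1] <- "curve_id"
  readr::write_csv(df, path)
  if (!is.null(sidecar)) {
    comp <- dplyr::mutate(result$components,
                          scores = vapply(.data$scores, max, 1.0))
    names(comp)[3] <- "max_score"
    jsonlite::write_json(
      list(config = result$config, threshold = result$threshold,
           components = comp, fits = result$fits),
      sidecar, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write ground-truth labels as CSV
#'
#' @param labeled a `labeled_sample`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labeled, path) {
  stopifnot(inherits(labeled, "labeled_sample"))
  readr::write_csv(
    tibble::tibble(curve_id = seq_along(labeled$labels),
                   is_outlier = labeled$labels,
                   cluster_id = labeled$cluster_ids),
    path)
  invisible(path)
}
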