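#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_segment labs theme_minimal scale_colour_manual
#' @export
ggplot2::autoplot

#' Plot detector scores
#'
#' Lollipop display of the ensemble outlier score of every curve, with the
#' boxplot fence (when hardened) as a dashed line and flagged curves
#' highlighted.
#'
#' @param object a `faa_outliers` result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.faa_outliers <- function(object, ...) {
  df <- tidy(object)
  if (is.null(df$outlier)) df$outlier <- FALSE
  p <- ggplot(df, aes(x = .data$curve, y = .data$score, colour = .data$outlier)) +
    geom_segment(aes(xend = .data$curve, yend = 0), linewidth = 0.3) +
    geom_point(size = 1.6) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "#d1495b"),
                        name = "flagged") +
    labs(x = "curve", y = "ensemble outlier score") +
    theme_minimal()
  if (!is.null(object$threshold)) {
    p <- p + geom_hline(yintercept = object$threshold, linetype = "dashed")
  }
  p
}

#' Plot a simulated dataset
#'
#' Draws every curve against its grid, coloured by cluster membership with
#' planted outliers emphasised.
#'
#' @param object a `labeled_sample`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.labeled_sample <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$t, y = .data$value, group = .data$curve,
                 colour = factor(.data$cluster), alpha = .data$outlier)) +
    geom_line(linewidth = 0.4) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                guide = "none") +
    labs(x = "t", y = "x(t)", colour = "cluster") +
    theme_minimal()
}

#' Plot an RSS profile with its elbow
#'
#' @param object a tibble from [rss_curve()].
#' @param elbow draw the [choose_elbow()] selection as a vertical line.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_rss_curve <- function(object, elbow = TRUE, ...) {
  p <- ggplot(object, aes(x = .data$p, y = .data$rss)) +
    geom_line() + geom_point() +
    labs(x = "number of archetypes p", y = "RSS") +
    theme_minimal()
  if (elbow && nrow(object) >= 3L) {
    p <- p + ggplot2::geom_vline(xintercept = choose_elbow(object),
                                 linetype = "dashed", colour = "#d1495b")
  }
  p
}

#' Plot fitted archetypes as curves
#'
#' For discrete-family samples the archetype coefficient rows are curves
#' on the grid and are drawn over the (faded) data curves.
#'
#' @param object a fitted `faa` model.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.faa <- function(object, ...) {
  x <- object$sample
  grid <- x$grid %||% seq_len(ncol(x$coefficients))
  data_df <- tibble::tibble(
    curve = rep(seq_len(nrow(x$coefficients)), each = length(grid)),
    t = rep(grid, nrow(x$coefficients)),
    value = as.vector(t(x$coefficients)))
  arch_df <- tibble::tibble(
    archetype = factor(rep(seq_len(object$p), each = length(grid))),
    t = rep(grid, object$p),
    value = as.vector(t(object$archetypes)))
  ggplot(data_df, aes(x = .data$t, y = .data$value)) +
    geom_line(aes(group = .data$curve), colour = "grey75", linewidth = 0.3) +
    geom_line(data = arch_df,
              aes(colour = .data$archetype, group = .data$archetype),
              linewidth = 0.9) +
    labs(x = "t", y = "x(t)", colour = "archetype") +
    theme_minimal()
}
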