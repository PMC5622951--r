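# ggplot2 views of the main result types.

#' Plot a replicate S-score set against the standard-normal reference
#'
#' Pooled histogram of per-cluster S-scores with the N(0,1) density overlaid
#' -- the null calibration the statistic advertises.
#'
#' @param object An `sscore_set`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sscore_set <- function(object, bins = 80, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sscore)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::stat_function(fun = stats::dnorm, colour = "firebrick",
                           linewidth = 0.8) +
    ggplot2::labs(x = "S-score", y = "density",
                  title = "Replicate S-scores vs N(0,1)") +
    ggplot2::theme_minimal()
}

#' SAM quantile plot
#'
#' Observed d statistics against the expected (median null) order
#' statistics, with the selected delta band; the classic SAM display.
#'
#' @param object A `sam_result`.
#' @param d_null Optional null d matrix to recompute expected quantiles; the
#'   stored FDR curve is used otherwise.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sam_result <- function(object, d_null = NULL, ...) {
  tab <- object$table
  df <- tibble::tibble(
    observed = sort(tab$d),
    expected = qnorm(stats::ppoints(nrow(tab))),
    called = tab$called[order(tab$d)]
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
                                        colour = .data$called)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "expected quantile", y = "observed d",
                  title = sprintf("One-Class SAM (delta = %.3g, %d called)",
                                  object$delta, sum(tab$called))) +
    ggplot2::theme_minimal()
  if (is.finite(object$delta)) {
    p <- p + ggplot2::geom_hline(yintercept = c(-1, 1) * object$delta,
                                 linetype = 3, colour = "firebrick")
  }
  p
}

#' Dot plot of over-represented gene sets
#'
#' @param object An `enrichment_result`.
#' @param top Number of top sets to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  df <- head(dplyr::arrange(tibble::as_tibble(object), .data$p), top)
  df$set_name <- factor(df$set_name, levels = rev(df$set_name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p), y = .data$set_name,
                                   size = .data$k / .data$K)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = expression(-log[10]~p), y = NULL, size = "hit fraction",
                  title = "Gene-set over-representation") +
    ggplot2::theme_minimal()
}

#' ELISA standard curve with back-calculated samples
#'
#' @param object An `elisa_plate`.
#' @param result Optional output of [elisa_concentration()] to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.elisa_plate <- function(object, result = NULL, ...) {
  p <- ggplot2::ggplot(object$standards,
                       ggplot2::aes(x = .data$concentration, y = .data$od)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.6) +
    ggplot2::labs(x = "standard concentration (ng)", y = "OD (450 nm)",
                  title = "ELISA standard curve") +
    ggplot2::theme_minimal()
  if (!is.null(result)) {
    p <- p + ggplot2::geom_point(data = result,
                                 ggplot2::aes(x = .data$concentration,
                                              y = .data$od),
                                 colour = "firebrick", shape = 17)
  }
  p
}
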