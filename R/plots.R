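# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dot plot
#'
#' @param object A `dot_plot`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dot_plot <- function(object, ...) {
  ggplot2::ggplot(object$hits, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_point(shape = 15, size = 0.4) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "window start (bp)", y = "window start (bp)",
      title = sprintf("dot plot: window %d bp, stringency %g%%",
                      object$window, object$stringency_pct)) +
    ggplot2::theme_minimal()
}

#' Plot a per-position base-frequency profile
#'
#' Stacked per-position base frequencies of the circular consensus -- the
#' tabular equivalent of a sequence logo.
#'
#' @param object A `consensus_logo`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_logo <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$frequency,
                                     fill = .data$base)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "circular position (bp)", y = "base frequency") +
    ggplot2::theme_minimal()
}

#' Plot a restriction ladder
#'
#' Fragment-length histogram of an in-silico digest; for a tandem array the
#' monomer band and its multiples dominate.
#'
#' @param object A `digest_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.digest_result <- function(object, ...) {
  ggplot2::ggplot(object$ladder, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(width = max(1, object$monomer_length / 50)) +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments",
                  title = sprintf("%s (%s) digest of %d-copy array",
                                  object$enzyme, object$site, object$copies)) +
    ggplot2::theme_minimal()
}

#' Plot cluster sizes against genome proportion
#'
#' @param object A `cluster_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$proportion_pct, y = .data$size,
                                   colour = .data$classification)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genome proportion (%)", y = "reads in cluster") +
    ggplot2::theme_minimal()
}

#' Plot a slot-blot standard curve
#'
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$amount_ng, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = object$slope,
                         linetype = "dashed") +
    ggplot2::labs(x = "standard amount (ng)", y = "signal",
                  title = sprintf("slope %.3g, R^2 %.4f", object$slope,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}
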