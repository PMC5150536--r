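# ggplot2 visualisations: scan trajectories, F-score profiles, and the
# positional frequency contrast a fitted BPB model encodes.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a wrapper-selection scan trajectory
#'
#' Accuracy against the scan parameter (F-score threshold, dimension count,
#' or greedy trial index), one panel per stage — the conventional way these
#' threshold/dimension scans are reported.
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_result <- function(object, ...) {
  d <- dplyr::filter(object$trajectory, .data$valid)
  ggplot2::ggplot(d, ggplot2::aes(.data$param, 100 * .data$acc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$stage), scales = "free_x") +
    ggplot2::labs(x = "scan parameter", y = "jackknife Acc (%)",
                  title = "Wrapper feature-selection trajectory") +
    ggplot2::theme_minimal()
}

#' Plot the top of an F-score ranking
#'
#' @param object An `fscore_ranking`.
#' @param top Number of features shown (default 30).
#' @param ... Unused.
#' @return A ggplot (lollipop of F-scores, coloured by feature family).
#' @export
autoplot.fscore_ranking <- function(object, top = 30L, ...) {
  d <- utils::head(tidy(object), top)
  d$family <- feature_family(d$feature)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(.data$fscore, .data$feature,
                                  colour = .data$family)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$feature),
                          colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "F-score", y = NULL, colour = "family") +
    ggplot2::theme_minimal()
}

#' Plot the positional contrast of a bi-profile Bayes model
#'
#' Per-position difference between positive-class and negative-class base
#' frequencies; planted or biological positional signal shows up as spikes.
#'
#' @param object A `bpb_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bpb_model <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_wider(d, names_from = "class", values_from = "freq")
  d$delta <- d$positive - d$negative
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$delta,
                                  colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (bp)",
                  y = "freq(positive) - freq(negative)", colour = "base") +
    ggplot2::theme_minimal()
}
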