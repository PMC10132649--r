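#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot repeated-split performance with confidence intervals
#'
#' @param object A `"performance_summary"`.
#' @param metrics Which metrics to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.performance_summary <- function(object,
                                         metrics = c("auc", "sens_90",
                                                     "sens_95"), ...) {
  dat <- dplyr::filter(object$performance, .data$metric %in% metrics)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$variant, y = .data$mean,
                                    colour = .data$variant)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean over splits (95% CI)",
                  title = "Out-of-sample performance by model variant") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot selection frequencies from a stability-selection run
#'
#' @param object A `"selection_summary"`.
#' @param min_frequency Hide features below this frequency (default 0.1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_summary <- function(object, min_frequency = 0.1, ...) {
  thr <- attr(object, "freq_threshold")
  dat <- tibble::as_tibble(object) |>
    dplyr::filter(.data$frequency >= min_frequency) |>
    dplyr::mutate(feature = stats::reorder(.data$feature, .data$frequency))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$frequency, y = .data$feature,
                                    fill = .data$kept)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::labs(x = "selection frequency over resamples", y = NULL,
                  title = "Stability selection") +
    ggplot2::theme_minimal()
}

#' Plot the marginal importance ranking of fused SDoH features
#'
#' Log odds (on the unit feature scale) of each SDoH feature's best fused
#' version, with Wald 95% intervals.
#'
#' @param object An `"importance_ranking"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_ranking <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::filter(!.data$unstable) |>
    dplyr::mutate(
      label = sprintf("%s (%s, %d)", .data$feature, .data$method, .data$k),
      label = stats::reorder(.data$label, abs(.data$log_odds)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log_odds, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$log_odds - 1.96 * .data$se,
      xmax = .data$log_odds + 1.96 * .data$se)) +
    ggplot2::labs(x = "log odds (unit feature scale)", y = NULL,
                  title = "Best fused version per SDoH feature") +
    ggplot2::theme_minimal()
}
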