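# ggplot2 displays mirroring the figures the pipelines feed: per-cell dot
# plots with replicate shading, condition means with SEM bars, and contact
# ratios per condition.

#' Dot plot of per-cell intensities by condition
#'
#' Each cell is one dot, colored by biological replicate, with the
#' condition mean as a black crossbar — the standard presentation of
#' per-cell stain quantification.
#'
#' @param object A per-cell tibble with `condition`, `replicate`, and the
#'   value column.
#' @param value Column to plot (default `mean_intensity`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_records <- function(object, value = "mean_intensity", ...) {
  df <- tibble::as_tibble(object)
  stopifnot(value %in% names(df))
  if (!"condition" %in% names(df)) df$condition <- "field"
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data[[value]])) +
    ggplot2::geom_jitter(ggplot2::aes(alpha = factor(.data$replicate)),
                         width = 0.25, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.4, color = "black") +
    ggplot2::scale_alpha_ordinal(range = c(0.35, 0.9), name = "replicate") +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_classic()
}

#' Condition means with SEM error bars
#'
#' @param object A `condition_summary` from [summarize_replicates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.condition_summary <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::unnest_longer("replicate_values")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$replicate_values),
                        size = 2, alpha = 0.7) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$grand_mean,
                                        ymin = .data$grand_mean,
                                        ymax = .data$grand_mean),
                           width = 0.5, linewidth = 0.4) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$grand_mean - .data$sem,
                                        ymax = .data$grand_mean + .data$sem),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "replicate statistic") +
    ggplot2::theme_classic()
}

#' Contact ratios per condition
#'
#' @param results Tibble from [run_contact_pipeline()] or
#'   [batch_contact()] with a `condition` column.
#' @return A ggplot object.
#' @export
plot_contact_ratios <- function(results) {
  stopifnot("contact_ratio" %in% names(results))
  if (!"condition" %in% names(results)) results$condition <- "all"
  ggplot2::ggplot(results, ggplot2::aes(x = .data$condition,
                                        y = .data$contact_ratio)) +
    ggplot2::geom_jitter(width = 0.15, size = 2, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = expression("contact ratio (" * mu * m^-1 * ")")) +
    ggplot2::theme_classic()
}
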