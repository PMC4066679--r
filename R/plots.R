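#' Gantt chart of a simulated schedule
#'
#' Draws each task as a horizontal segment on its (VM, core) lane, coloured
#' by tool, with VM readiness marked; the visual counterpart of the event
#' log.
#'
#' @param object An `ethread_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ethread_sim
#' @export
autoplot.ethread_sim <- function(object, ...) {
  sched <- dplyr::filter(object$schedule, !is.na(.data$start_min))
  sched <- dplyr::mutate(sched,
                         lane = paste0(.data$vm, ":c", .data$core),
                         tool_lab = ifelse(is.na(.data$tool), "meta", .data$tool))
  ggplot2::ggplot(sched) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start_min,
                                       xend = .data$end_min,
                                       y = .data$lane, yend = .data$lane,
                                       colour = .data$tool_lab),
                          linewidth = 3) +
    ggplot2::geom_vline(data = object$vms,
                        ggplot2::aes(xintercept = .data$ready_min),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "time (min)", y = NULL, colour = "tool",
                  title = sprintf("policy %s: TTS %.1f min, CTS $%.2f",
                                  object$config$policy,
                                  object$metrics$tts_min,
                                  object$metrics$cts_usd)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot scenarios in the time/cost plane
#'
#' Scatter of candidate executions with the Pareto-optimal subset
#' highlighted and connected; the classic makespan-versus-dollars trade-off
#' view.
#'
#' @param scenarios A data frame with time and cost columns (and optionally a
#'   `label` column for point labels).
#' @param tts,cts Column names for time and cost.
#' @return A ggplot object.
#' @export
plot_pareto <- function(scenarios, tts = "tts_min", cts = "cts_usd") {
  front <- pareto_front(scenarios, tts = tts, cts = cts)
  front <- front[order(front[[tts]]), , drop = FALSE]
  p <- ggplot2::ggplot(scenarios,
                       ggplot2::aes(x = .data[[tts]], y = .data[[cts]])) +
    ggplot2::geom_point(colour = "grey50") +
    ggplot2::geom_step(data = front, colour = "firebrick") +
    ggplot2::geom_point(data = front, colour = "firebrick", size = 2.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time-to-solution (min)", y = "cost-to-solution (USD)") +
    ggplot2::theme_minimal()
  if ("label" %in% names(scenarios)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$label),
                                vjust = -0.8, size = 3)
  }
  p
}
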