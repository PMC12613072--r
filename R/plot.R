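#' Plot trace channels
#'
#' One facet per ROI, with the requested channels overlaid over time.
#'
#' @param traces Trace tibble (long format, possibly processed).
#' @param rois Optional ROI ids to keep.
#' @param channels Channels to draw, among `raw`, `smoothed`, `f0`, `dff`.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, rois = NULL,
                        channels = intersect(c("raw", "smoothed", "f0", "dff"),
                                             names(traces))) {
  if (!length(channels)) abort("No plottable channels in `traces`.")
  if (!("roi_id" %in% names(traces))) traces$roi_id <- 1L
  if (!is.null(rois)) traces <- traces[traces$roi_id %in% rois, , drop = FALSE]
  long <- tidyr::pivot_longer(traces, cols = dplyr::all_of(channels),
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = channels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$roi_id),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "fluorescence / dF/F0",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot detected events on the dF/F0 trace
#'
#' @param traces Processed trace tibble (needs `dff`).
#' @param events Event tibble from [detect_events()].
#' @param rois Optional ROI ids to keep.
#' @return A ggplot object.
#' @export
plot_events <- function(traces, events, rois = NULL) {
  if (!("dff" %in% names(traces))) abort("`traces` has no `dff` channel.")
  if (!("roi_id" %in% names(traces))) traces$roi_id <- 1L
  if (!is.null(rois)) {
    traces <- traces[traces$roi_id %in% rois, , drop = FALSE]
    events <- events[events$roi_id %in% rois, , drop = FALSE]
  }
  p <- ggplot2::ggplot(traces, ggplot2::aes(x = .data$time_s, y = .data$dff)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$roi_id)) +
    ggplot2::labs(x = "time (s)", y = "dF/F0") +
    ggplot2::theme_minimal()
  if (nrow(events)) {
    p <- p + ggplot2::geom_point(
      data = events,
      ggplot2::aes(x = .data$peak_time_s, y = .data$height),
      colour = "red", size = 1.2)
  }
  p
}

#' @describeIn tidy.ca_group_test Plot per-unit values by group with the
#'   group means overlaid.
#' @param object A `ca_group_test`.
#' @export
autoplot.ca_group_test <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = object$measure,
                  subtitle = object$method) +
    ggplot2::theme_minimal()
}
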