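#' Fisher-Pearson moment skewness
#'
#' The biased moment coefficient `g1 = m3 / m2^(3/2)` (the default of the
#' numerical environment the processing chain is modelled on); set
#' `adjust = TRUE` for the bias-corrected `G1`.
#'
#' @param x Numeric vector (length >= 3).
#' @param adjust Apply the `sqrt(n(n-1))/(n-2)` correction.
#' @return Skewness (dimensionless).
#' @examples
#' skewness_g1(c(rep(0, 9), 1))
#' @export
skewness_g1 <- function(x, adjust = FALSE) {
  n <- length(x)
  if (n < 3L) abort("Skewness needs at least 3 observations.")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) return(NaN)
  g1 <- mean(xc^3) / m2^1.5
  if (adjust) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Classify cells as active or inactive
#'
#' A cell is active when all three criteria hold on its dF/F0 series,
#' as strict inequalities: skewness > 1.0, SD > 0.04, and at least one
#' detected Ca2+ event.  Skewness is the biased moment coefficient
#' ([skewness_g1()]); SD uses the `n - 1` denominator.  The event
#' frequency (events/min) is reported for active cells (by default) and
#' the mean amplitude whenever at least one event was detected.
#'
#' @param traces Processed trace tibble (needs `dff`).
#' @param events Event tibble from [detect_events()] for the same ROIs.
#' @param skew_min Skewness threshold (strict; default 1.0).
#' @param sd_min SD threshold in dF/F0 units (strict; default 0.04).
#' @param freq_active_only If `TRUE` (default) `freq_per_min` is `NA` for
#'   inactive cells, matching the convention that frequency and amplitude
#'   are statistics of active cells; if `FALSE` it is reported for every
#'   cell.
#' @param frame_rate Hz; defaults to the trace attribute.
#' @return One row per ROI: `roi_id`, `skewness`, `sd_dff`, `n_events`,
#'   `active`, `freq_per_min`, `mean_amp`.
#' @examples
#' rec <- simulate_recording(synth_config(n_cells = 4, seed = 9))
#' traces <- process_traces(rec$traces, processing_params(30, sg_width = 31))
#' events <- detect_events(traces)
#' classify_cells(traces, events)
#' @export
classify_cells <- function(traces, events, skew_min = 1.0, sd_min = 0.04,
                           freq_active_only = TRUE, frame_rate = NULL) {
  if (!("dff" %in% names(traces))) {
    abort("`traces` has no `dff` channel; run process_traces() first.")
  }
  fr <- frame_rate %||% trace_frame_rate(traces)
  groups <- if ("roi_id" %in% names(traces)) {
    split(traces, traces$roi_id)
  } else {
    list(`1` = traces)
  }
  out <- purrr::map_dfr(groups, function(df) {
    if (nrow(df) < 3L) abort("dF/F0 series shorter than 3 frames: skewness undefined.")
    roi <- if ("roi_id" %in% names(df)) df$roi_id[1L] else 1L
    ev <- if ("roi_id" %in% names(events)) {
      events[events$roi_id == roi, , drop = FALSE]
    } else {
      events
    }
    duration <- nrow(df) / fr
    n_ev <- nrow(ev)
    skew <- skewness_g1(df$dff)
    sd_dff <- sd(df$dff)
    active <- isTRUE(skew > skew_min) && sd_dff > sd_min && n_ev >= 1L
    tibble::tibble(
      roi_id = roi,
      skewness = skew,
      sd_dff = sd_dff,
      n_events = n_ev,
      active = active,
      freq_per_min = if (n_ev >= 1L && (active || !freq_active_only)) {
        n_ev / (duration / 60)
      } else {
        NA_real_
      },
      mean_amp = if (n_ev >= 1L) mean(ev$height) else NA_real_
    )
  })
  dplyr::arrange(out, .data$roi_id)
}

#' Summarise cell records per organoid
#'
#' The active cell rate of a recording is `100 * n_active / n_rois` (% of
#' ROIs); per-cell frequency and amplitude vectors are collected for the
#' group-level statistics.
#'
#' @param cells Cell record tibble from [classify_cells()].  For cohort
#'   use it may carry `organoid_id` and `group` columns, in which case the
#'   summary is computed per organoid.
#' @param organoid_id,group Identifiers used when `cells` describes a
#'   single recording.
#' @return One row per organoid: `organoid_id`, `group`, `n_rois`,
#'   `n_active`, `active_cell_rate` (%), plus list-columns `frequency` and
#'   `amplitude` with the per-cell values entering the group statistics.
#' @export
summarize_organoids <- function(cells, organoid_id = "organoid", group = "all") {
  if (!nrow(cells)) abort("Empty cell record table.")
  if (!("organoid_id" %in% names(cells))) {
    cells$organoid_id <- organoid_id
    cells$group <- group
  }
  out <- cells |>
    dplyr::group_by(.data$organoid_id, .data$group) |>
    dplyr::summarise(
      n_rois = dplyr::n(),
      n_active = sum(.data$active),
      active_cell_rate = 100 * sum(.data$active) / dplyr::n(),
      frequency = list(.data$freq_per_min[!is.na(.data$freq_per_min)]),
      amplitude = list(.data$mean_amp[.data$active & !is.na(.data$mean_amp)]),
      .groups = "drop"
    )
  tibble::as_tibble(out)
}
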