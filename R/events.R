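#' Peak criteria for Ca2+ event detection
#'
#' The three criteria defining a Ca2+ event on a dF/F0 trace, with the
#' values used for jGCaMP7f organoid recordings as defaults: minimum peak
#' height 0.2 dF/F0, minimum peak separation 30 frames (1 s at 30 Hz) and
#' minimum peak width 15 frames.  Semantics mirror the reference MATLAB
#' peak finder: height is an absolute threshold on the dF/F0 value at the
#' peak; width is measured at half prominence (optionally at half height);
#' separation is enforced by taller-first greedy suppression.
#'
#' @param min_height Minimum peak height, dF/F0 units (> 0).
#' @param min_distance Minimum separation between retained peaks, frames
#'   (>= 1).  Peaks closer than this to a taller retained peak are
#'   discarded; a separation of exactly `min_distance` is allowed.
#' @param min_width Minimum peak width, frames (>= 1), measured at the
#'   `width_reference` level.
#' @param width_reference `"halfprom"` (default, the reference
#'   implementation's default) or `"halfheight"`.
#' @return A `peak_params` object.
#' @export
peak_params <- function(min_height = 0.2, min_distance = 30L,
                        min_width = 15L,
                        width_reference = c("halfprom", "halfheight")) {
  if (min_height <= 0) abort("`min_height` must be > 0.")
  if (min_distance < 1) abort("`min_distance` must be >= 1.")
  if (min_width < 1) abort("`min_width` must be >= 1.")
  structure(list(min_height = as.numeric(min_height),
                 min_distance = as.numeric(min_distance),
                 min_width = as.numeric(min_width),
                 width_reference = match.arg(width_reference)),
            class = "peak_params")
}

#' @export
print.peak_params <- function(x, ...) {
  cat(sprintf("<peak_params> height >= %g, width >= %g frames (%s), distance >= %g frames\n",
              x$min_height, x$min_width, x$width_reference, x$min_distance))
  invisible(x)
}

#' Find peaks in a numeric vector
#'
#' Findpeaks-compatible peak detection: (1) all strict local maxima are
#' enumerated (a plateau of equal values flanked by lower samples counts
#' once, positioned at its centre, left-of-centre for even plateaus;
#' endpoints are never peaks); (2) peaks below `min_height` are dropped;
#' (3) each peak's prominence is measured against the higher terrain on
#' either side, its width is the distance between the interpolated
#' crossings of the signal with the half-prominence (or half-height)
#' reference level, and peaks narrower than `min_width` are dropped;
#' (4) remaining peaks are scanned from tallest to smallest (ties: earlier
#' frame first) and any peak closer than `min_distance` frames to an
#' already retained peak is discarded.  Deterministic.
#'
#' @param x Numeric vector (typically a dF/F0 trace).
#' @param params A [peak_params()].
#' @return A tibble sorted by `peak_frame`: `peak_frame` (1-based),
#'   `height`, `prominence`, `width_frames`.
#' @examples
#' bump <- 0.5 * exp(-((1:200 - 100) / 18)^2 / 2)
#' find_peaks(bump, peak_params())
#' @export
find_peaks <- function(x, params = peak_params()) {
  n <- length(x)
  cand <- local_maxima(x)
  cand <- cand[x[cand] >= params$min_height]
  if (!length(cand)) return(empty_peaks())
  prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
  wid <- vapply(seq_along(cand), function(i) {
    peak_width(x, cand[i], prom[i], params$width_reference)
  }, numeric(1))
  keep <- wid >= params$min_width
  cand <- cand[keep]; prom <- prom[keep]; wid <- wid[keep]
  if (!length(cand)) return(empty_peaks())
  ord <- order(-x[cand], cand)
  retained <- integer(0)
  sel <- logical(length(cand))
  for (i in ord) {
    if (!length(retained) || all(abs(cand[i] - retained) >= params$min_distance)) {
      retained <- c(retained, cand[i])
      sel[i] <- TRUE
    }
  }
  out <- tibble::tibble(peak_frame = cand[sel], height = x[cand[sel]],
                        prominence = prom[sel], width_frames = wid[sel])
  dplyr::arrange(out, .data$peak_frame)
}

empty_peaks <- function() {
  tibble::tibble(peak_frame = integer(), height = numeric(),
                 prominence = numeric(), width_frames = numeric())
}

# strict local maxima with plateau handling; endpoints excluded
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  i <- 2:(k - 1L)
  is_peak <- r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]
  runs <- i[is_peak]
  as.integer(floor((starts[runs] + ends[runs]) / 2))
}

# prominence of the peak at index p: drop to the highest of the two lowest
# points between the peak and the nearest higher terrain (or trace end)
peak_prominence <- function(x, p) {
  n <- length(x)
  left_hi <- which(x[seq_len(p - 1L)] > x[p])
  lb <- if (length(left_hi)) max(left_hi) else 1L
  left_min <- min(x[lb:p])
  right_hi <- which(x[(p + 1L):n] > x[p])
  rb <- if (length(right_hi)) p + min(right_hi) else n
  right_min <- min(x[p:rb])
  x[p] - max(left_min, right_min)
}

# width at the reference level: distance between the linearly interpolated
# crossings on either side of the peak (clamped at the trace ends)
peak_width <- function(x, p, prominence, width_reference) {
  n <- length(x)
  ref <- if (width_reference == "halfprom") {
    x[p] - prominence / 2
  } else {
    x[p] / 2
  }
  left <- 1
  for (i in seq(p - 1L, 1L, by = -1L)) {
    if (x[i] < ref) {
      left <- i + (ref - x[i]) / (x[i + 1L] - x[i])
      break
    }
  }
  right <- n
  if (p < n) {
    for (i in seq(p + 1L, n, by = 1L)) {
      if (x[i] < ref) {
        right <- i - (ref - x[i]) / (x[i - 1L] - x[i])
        break
      }
    }
  }
  right - left
}

#' Detect Ca2+ events on processed traces
#'
#' Runs [find_peaks()] on the `dff` channel of each ROI and returns the
#' event table.
#'
#' @param traces Processed trace tibble (needs `dff`; see
#'   [process_traces()]).
#' @param params A [peak_params()].
#' @param frame_rate Hz; defaults to the `frame_rate` attribute of
#'   `traces`, falling back to `time_s` spacing.
#' @return Event tibble: `roi_id`, `peak_frame`, `peak_time_s`, `height`,
#'   `prominence`, `width_frames`, sorted by ROI then peak frame.  A trace
#'   with no qualifying peaks contributes no rows (an empty result is not
#'   an error).
#' @examples
#' rec <- simulate_recording(synth_config(n_cells = 2, seed = 8))
#' traces <- process_traces(rec$traces, processing_params(30, sg_width = 31))
#' detect_events(traces, peak_params())
#' @export
detect_events <- function(traces, params = peak_params(), frame_rate = NULL) {
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
    pk <- find_peaks(df$dff, params)
    if (!nrow(pk)) return(NULL)
    pk$roi_id <- if ("roi_id" %in% names(df)) df$roi_id[1L] else 1L
    pk$peak_time_s <- (pk$peak_frame - 1) / fr
    pk[, c("roi_id", "peak_frame", "peak_time_s", "height", "prominence",
           "width_frames")]
  })
  if (!nrow(out)) {
    out <- tibble::tibble(roi_id = integer(), peak_frame = integer(),
                          peak_time_s = numeric(), height = numeric(),
                          prominence = numeric(), width_frames = numeric())
  }
  dplyr::arrange(out, .data$roi_id, .data$peak_frame)
}

trace_frame_rate <- function(traces) {
  fr <- attr(traces, "frame_rate")
  if (!is.null(fr)) return(fr)
  if ("time_s" %in% names(traces) && nrow(traces) > 1L) {
    dt <- diff(traces$time_s[traces$roi_id == traces$roi_id[1L]][1:2] %||%
                 traces$time_s[1:2])
    if (length(dt) && dt > 0) return(1 / dt)
  }
  abort("Cannot determine the frame rate; pass `frame_rate`.")
}

#' Event frequency in events per minute
#'
#' @param events Event tibble (possibly empty).  If it has a `roi_id`
#'   column the rate is computed per ROI, otherwise overall.
#' @param duration_s Recording duration, seconds (> 0).
#' @return Tibble with `n_events` and `freq_per_min` (plus `roi_id` when
#'   grouped).
#' @examples
#' event_rate(tibble::tibble(peak_frame = c(10, 50, 90, 130)), 120)
#' @export
event_rate <- function(events, duration_s) {
  if (duration_s <= 0) abort("`duration_s` must be > 0.")
  if ("roi_id" %in% names(events) && nrow(events)) {
    out <- dplyr::summarise(dplyr::group_by(events, .data$roi_id),
                            n_events = dplyr::n(), .groups = "drop")
    out$freq_per_min <- out$n_events / (duration_s / 60)
    return(out)
  }
  tibble::tibble(n_events = nrow(events),
                 freq_per_min = nrow(events) / (duration_s / 60))
}

#' Mean event amplitude
#'
#' The mean peak height of all detected events, in dF/F0 units.  Undefined
#' (an error, not zero) for an empty event table.
#'
#' @param events Event tibble with a `height` column.
#' @return Tibble with `mean_amp` (plus `roi_id` when grouped).
#' @examples
#' mean_amplitude(tibble::tibble(height = c(0.4, 0.6)))
#' @export
mean_amplitude <- function(events) {
  if (!nrow(events)) {
    abort("Mean amplitude is undefined for zero events (not zero).")
  }
  if ("roi_id" %in% names(events)) {
    return(dplyr::summarise(dplyr::group_by(events, .data$roi_id),
                            mean_amp = mean(.data$height), .groups = "drop"))
  }
  tibble::tibble(mean_amp = mean(events$height))
}
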