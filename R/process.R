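#' Trace-processing parameters
#'
#' Parameters of the smoothing / baseline / dF/F0 stages.  The defaults
#' are the recording-scale settings used for organoid recordings acquired
#' at 30 Hz: a 301-frame Savitzky-Golay filter, and a 10th-percentile
#' baseline over a sliding window of duration `1 / baseline_cutoff`
#' (15 s, i.e. 450 frames at 30 Hz).  For synthetic fixtures with faster
#' transient kinetics, `sg_width` should be matched to the transient
#' timescale (see the methods vignette): a smoothing window much wider
#' than the transient attenuates it and measures a different quantity.
#'
#' @param frame_rate Acquisition rate, Hz.
#' @param sg_width Savitzky-Golay window, frames (odd; auto-shrunk with a
#'   warning for traces shorter than the window).
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param baseline_percentile Baseline percentile, in (0, 100).
#' @param baseline_cutoff Baseline cutoff frequency, Hz: the sliding
#'   window spans `round(frame_rate / baseline_cutoff)` frames.
#' @param baseline_mode `"window"` (default): sliding-window percentile of
#'   duration `1 / baseline_cutoff`.  `"percentile+butterworth"`:
#'   alternative reading in which the windowed percentile is followed by a
#'   2nd-order Butterworth low-pass at `baseline_cutoff` Hz
#'   (forward-backward, zero phase).
#' @param dff_numerator `"smoothed"` (default; smoothing precedes dF/F0)
#'   or `"raw"`.
#' @return A `processing_params` object.
#' @examples
#' processing_params(frame_rate = 30)
#' @export
processing_params <- function(frame_rate,
                              sg_width = 301L,
                              sg_polyorder = 3L,
                              baseline_percentile = 10,
                              baseline_cutoff = 1 / 15,
                              baseline_mode = c("window", "percentile+butterworth"),
                              dff_numerator = c("smoothed", "raw")) {
  if (frame_rate <= 0) abort("`frame_rate` must be > 0.")
  sg_width <- as.integer(sg_width)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_width %% 2L == 0L) abort("`sg_width` must be odd.")
  if (sg_width < sg_polyorder + 2L) {
    abort("`sg_width` must be >= sg_polyorder + 2.")
  }
  if (baseline_percentile <= 0 || baseline_percentile >= 100) {
    abort("`baseline_percentile` must lie strictly between 0 and 100.")
  }
  if (baseline_cutoff <= 0) abort("`baseline_cutoff` must be > 0.")
  structure(list(frame_rate = as.numeric(frame_rate),
                 sg_width = sg_width, sg_polyorder = sg_polyorder,
                 baseline_percentile = as.numeric(baseline_percentile),
                 baseline_cutoff = as.numeric(baseline_cutoff),
                 baseline_mode = match.arg(baseline_mode),
                 dff_numerator = match.arg(dff_numerator)),
            class = "processing_params")
}

#' @export
print.processing_params <- function(x, ...) {
  cat(sprintf(
    "<processing_params> SG %d/%d, baseline p%g over %d frames (%s), dF/F0 on %s\n",
    x$sg_width, x$sg_polyorder, x$baseline_percentile,
    baseline_window_frames(x), x$baseline_mode, x$dff_numerator))
  invisible(x)
}

baseline_window_frames <- function(params) {
  max(1L, as.integer(round(params$frame_rate / params$baseline_cutoff)))
}

# cache of SG projection coefficients, keyed by width/order
.sg_cache <- new.env(parent = emptyenv())

sg_coefficients <- function(width, polyorder) {
  key <- paste(width, polyorder)
  if (!is.null(.sg_cache[[key]])) return(.sg_cache[[key]])
  h <- (width - 1L) %/% 2L
  proj_row <- function(t_local, eval_at) {
    ord <- min(polyorder, length(t_local) - 1L)   # deficient edge windows
    A <- outer(t_local / max(h, 1L), 0:ord, `^`)
    e <- (eval_at / max(h, 1L))^(0:ord)
    drop(A %*% solve(crossprod(A), e))
  }
  central <- proj_row((-h):h, 0)
  edges <- lapply(seq_len(h), function(j) proj_row(seq_len(j + h) - j, 0))
  out <- list(h = h, central = central, edges = edges)
  .sg_cache[[key]] <- out
  out
}

#' Savitzky-Golay smoothing of a numeric vector
#'
#' Least-squares local polynomial smoothing.  Interior points use the
#' standard centred convolution; within half a window of either end the
#' polynomial is fitted on the truncated window actually available (no
#' padding), so a polynomial of degree `<= polyorder` is reproduced
#' exactly along the whole trace, edges included.
#'
#' @param x Numeric vector.
#' @param width Window length, frames (odd).
#' @param polyorder Polynomial order (`width >= polyorder + 2`).
#' @return Smoothed vector, same length.
#' @examples
#' x <- (1:100)^3
#' max(abs(sg_filter(x, 21, 3) - x))   # cubic reproduced exactly
#' @export
sg_filter <- function(x, width, polyorder = 3L) {
  n <- length(x)
  width <- as.integer(width); polyorder <- as.integer(polyorder)
  if (width %% 2L == 0L) abort("`width` must be odd.")
  if (width > n) {
    width <- if (n %% 2L == 1L) n else n - 1L
    if (width < polyorder + 2L) {
      abort("Trace too short for Savitzky-Golay smoothing at this order.")
    }
    warn(sprintf("Savitzky-Golay window auto-shrunk to %d frames.", width))
  }
  co <- sg_coefficients(width, polyorder)
  h <- co$h
  if (h == 0L) return(x)
  out <- stats::filter(x, co$central, method = "convolution", sides = 2L)
  out <- as.numeric(out)
  for (j in seq_len(h)) {
    w <- co$edges[[j]]
    out[j] <- sum(w * x[seq_len(j + h)])
    out[n + 1L - j] <- sum(w * x[n + 1L - seq_len(j + h)])
  }
  out
}

#' Sliding-window percentile
#'
#' For each frame, the given percentile of the values in a centred window
#' of `window` frames, truncated (not padded) at the trace ends.  Matches
#' `stats::quantile(type = 7)` exactly on every window.
#'
#' @param x Numeric vector.
#' @param window Window length, frames.
#' @param p Percentile in `[0, 100]`.
#' @return Numeric vector, same length as `x`.
#' @examples
#' running_percentile(c(rep(1, 10), 5, rep(1, 10)), 21, 10)
#' @export
running_percentile <- function(x, window, p) {
  .running_percentile_cpp(as.numeric(x), as.integer(window), p / 100)
}

#' Smooth the raw channel of a trace table
#'
#' Adds a `smoothed` column: Savitzky-Golay filtered `raw`, per ROI.
#'
#' @param traces Long trace tibble with columns `roi_id` (optional),
#'   `frame`, `raw`.
#' @param params A [processing_params()].
#' @return The trace tibble with a `smoothed` column.
#' @export
smooth_traces <- function(traces, params) {
  per_roi_mutate(traces, function(df) {
    df$smoothed <- sg_filter(df$raw, params$sg_width, params$sg_polyorder)
    df
  })
}

#' Estimate the baseline F0 of a trace table
#'
#' Adds an `f0` column: the running `baseline_percentile`-th percentile of
#' the smoothed channel over a window of `round(frame_rate /
#' baseline_cutoff)` frames (450 frames at 30 Hz for the default 1/15 Hz
#' cutoff).  In `"percentile+butterworth"` mode the windowed percentile is
#' additionally low-passed with a zero-phase 2nd-order Butterworth filter
#' at the cutoff frequency.  F0 must be strictly positive everywhere,
#' otherwise dF/F0 is undefined and an error asks for background offset
#' handling.
#'
#' @inheritParams smooth_traces
#' @return The trace tibble with an `f0` column.
#' @export
estimate_baseline <- function(traces, params) {
  if (!("smoothed" %in% names(traces))) {
    abort("`traces` has no `smoothed` channel; run smooth_traces() first.")
  }
  w <- baseline_window_frames(params)
  per_roi_mutate(traces, function(df) {
    f0 <- running_percentile(df$smoothed, w, params$baseline_percentile)
    if (params$baseline_mode == "percentile+butterworth") {
      f0 <- butter_lowpass(f0, params$baseline_cutoff, params$frame_rate)
    }
    if (any(f0 <= 0)) {
      abort(paste0(
        "Baseline F0 <= 0 at some frames: dF/F0 is undefined. ",
        "Subtract the camera/background offset (or add one) before processing."))
    }
    df$f0 <- f0
    df
  })
}

#' Compute dF/F0
#'
#' Adds a `dff` column: `(F - f0) / f0`, where `F` is the smoothed channel
#' (default) or the raw channel, per `params$dff_numerator`.
#'
#' @inheritParams smooth_traces
#' @return The trace tibble with a `dff` column.
#' @export
compute_dff <- function(traces, params = NULL) {
  for (ch in c("smoothed", "f0")) {
    if (!(ch %in% names(traces))) {
      abort(sprintf("`traces` has no `%s` channel; run the earlier stages first.", ch))
    }
  }
  if (any(traces$f0 <= 0)) abort("F0 must be > 0 wherever dF/F0 is computed.")
  numerator <- if (!is.null(params) && params$dff_numerator == "raw") {
    traces$raw
  } else {
    traces$smoothed
  }
  traces$dff <- (numerator - traces$f0) / traces$f0
  traces
}

#' Run the full trace-processing chain
#'
#' `smooth_traces()`, then [estimate_baseline()], then [compute_dff()].
#'
#' @inheritParams smooth_traces
#' @return The trace tibble with `smoothed`, `f0` and `dff` columns.
#' @examples
#' rec <- simulate_recording(synth_config(n_cells = 2, seed = 7))
#' params <- processing_params(frame_rate = 30, sg_width = 31)
#' processed <- process_traces(rec$traces, params)
#' @export
process_traces <- function(traces, params) {
  traces |>
    smooth_traces(params) |>
    estimate_baseline(params) |>
    compute_dff(params)
}

# zero-phase 2nd-order Butterworth low-pass; the series is mean-centred and
# odd-reflection padded before filtfilt so a constant passes through exactly
# and edge transients stay local
butter_lowpass <- function(x, cutoff, fs) {
  n <- length(x)
  W <- min(cutoff / (fs / 2), 0.99)
  bt <- signal::butter(2, W)
  mu <- mean(x)
  xc <- x - mu
  np <- min(n - 1L, as.integer(ceiling(3 / W)))
  left <- 2 * xc[1L] - xc[seq(np + 1L, 2L)]
  right <- 2 * xc[n] - xc[seq(n - 1L, n - np)]
  y <- as.numeric(signal::filtfilt(bt, c(left, xc, right)))
  y[(np + 1L):(np + n)] + mu
}

# apply a per-ROI transformation preserving attributes and row order
per_roi_mutate <- function(traces, f) {
  fr <- attr(traces, "frame_rate")
  out <- if ("roi_id" %in% names(traces)) {
    dplyr::bind_rows(lapply(split(traces, traces$roi_id), f))
  } else {
    f(traces)
  }
  if ("roi_id" %in% names(out)) out <- dplyr::arrange(out, .data$roi_id, .data$frame)
  attr(out, "frame_rate") <- fr
  out
}
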