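#' Simulate ground truth for one recording
#'
#' Draws the per-cell activity labels and event schedules that a simulated
#' recording will realise.  Exactly `floor(n_cells * active_fraction)`
#' cells (minimum 1 if the fraction is positive) are active; active cells
#' receive a zero-truncated Poisson number of events at
#' `event_rate_active` events/min, uniformly placed in time, with Gaussian
#' amplitudes; inactive cells receive exactly zero events.
#'
#' @param cfg A [synth_config()].
#' @return A tibble with one row per cell: `roi_id`, `active`, `n_events`,
#'   and `events`, a list-column of tibbles with `time_s` and `amplitude`
#'   (dF/F0 units).
#' @examples
#' simulate_truth(synth_config(n_cells = 4, active_fraction = 0.5, seed = 2))
#' @export
simulate_truth <- function(cfg) {
  validate_synth_config(cfg)
  withr::local_seed(cfg$seed)
  sim_truth_cells(cfg)
}

# draws labels + schedules from the current RNG state
sim_truth_cells <- function(cfg) {
  n_act <- if (identical(cfg$active_sampling, "binomial")) {
    stats::rbinom(1L, cfg$n_cells, cfg$active_fraction)
  } else {
    n_active_cells(cfg$n_cells, cfg$active_fraction)
  }
  active <- rep(FALSE, cfg$n_cells)
  if (n_act > 0L) active[sample.int(cfg$n_cells, n_act)] <- TRUE
  duration <- cfg$n_frames / cfg$frame_rate
  events <- lapply(seq_len(cfg$n_cells), function(i) {
    if (!active[i]) {
      return(tibble::tibble(time_s = numeric(), amplitude = numeric()))
    }
    lambda <- cfg$event_rate_active * duration / 60
    n_ev <- rpois(1L, lambda)
    tries <- 0L
    while (n_ev < 1L && tries < 1000L) {   # zero-truncated: active means >= 1
      n_ev <- rpois(1L, lambda)
      tries <- tries + 1L
    }
    n_ev <- max(n_ev, 1L)
    tibble::tibble(
      time_s = sort(runif(n_ev, 0, duration)),
      amplitude = pmax(rnorm(n_ev, cfg$amplitude_mean, cfg$amplitude_sd), 0.05)
    )
  })
  tibble::tibble(
    roi_id = seq_len(cfg$n_cells),
    active = active,
    n_events = vapply(events, nrow, integer(1)),
    events = events
  )
}

#' Simulate one fluorescence trace
#'
#' Builds a raw fluorescence trace as
#' `F(t) = B(t) * (1 + sum_i a_i k(t - t_i)) + noise`, where
#' `B(t) = baseline_level * (1 + drift(t))` is a slow sinusoidal baseline,
#' `k` is the peak-normalised transient kernel ([calcium_kernel()]) and
#' `a_i` are event amplitudes in dF/F0 units.  Because events scale the
#' local baseline multiplicatively, the true dF/F0 peak of an isolated
#' event equals its amplitude.
#'
#' @param cfg A [synth_config()].
#' @param events Optional event schedule: a tibble/data frame with columns
#'   `time_s` and `amplitude`.  If `NULL`, a schedule for one active cell
#'   is drawn from `cfg`.
#' @return A tibble with columns `frame` (1-based), `time_s` and `raw`,
#'   plus attributes `frame_rate` and `events` (the schedule used).
#' @examples
#' tr <- simulate_trace(
#'   synth_config(n_frames = 300, noise_sd = 0, drift_amplitude = 0, seed = 1),
#'   events = data.frame(time_s = 5, amplitude = 0.5)
#' )
#' max(tr$raw)
#' @export
simulate_trace <- function(cfg, events = NULL) {
  validate_synth_config(cfg)
  withr::local_seed(cfg$seed)
  if (is.null(events)) {
    one <- synth_config_replace(cfg, n_cells = 1L, active_fraction = 1)
    events <- sim_truth_cells(one)$events[[1L]]
  }
  sim_trace_raw(cfg, events)
}

# trace realisation from the current RNG state (no re-seeding)
sim_trace_raw <- function(cfg, events) {
  t <- (seq_len(cfg$n_frames) - 1) / cfg$frame_rate
  dff_true <- numeric(cfg$n_frames)
  if (nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      dff_true <- dff_true + events$amplitude[i] *
        calcium_kernel(t - events$time_s[i], cfg$rise_tau, cfg$decay_tau)
    }
  }
  drift <- if (cfg$drift_amplitude > 0) {
    phase <- runif(1L, 0, 2 * pi)
    cfg$drift_amplitude * sin(2 * pi * t / cfg$drift_period + phase)
  } else {
    numeric(cfg$n_frames)
  }
  baseline <- cfg$baseline_level * (1 + drift)
  noise <- if (cfg$noise_sd > 0) rnorm(cfg$n_frames, 0, cfg$noise_sd) else 0
  raw <- baseline * (1 + dff_true) + noise
  out <- tibble::tibble(frame = seq_len(cfg$n_frames), time_s = t, raw = raw)
  attr(out, "frame_rate") <- cfg$frame_rate
  attr(out, "events") <- events
  out
}

#' Simulate a bundle of traces with ground truth
#'
#' Simulates all cells of one recording at the trace level (no imaging
#' geometry): the per-cell fluorescence an ideal ROI extraction would
#' recover, plus the exact ground truth.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `ca_recording` with elements `traces` (long
#'   tibble: `roi_id`, `frame`, `time_s`, `raw`), `truth` (see
#'   [simulate_truth()]), `frame_rate` and `config`.
#' @examples
#' rec <- simulate_recording(synth_config(n_cells = 3, n_frames = 600, seed = 3))
#' dplyr::count(rec$traces, roi_id)
#' @export
simulate_recording <- function(cfg) {
  validate_synth_config(cfg)
  withr::local_seed(cfg$seed)
  truth <- sim_truth_cells(cfg)
  traces <- purrr::map(seq_len(cfg$n_cells), function(i) {
    tr <- sim_trace_raw(cfg, truth$events[[i]])
    tr$roi_id <- i
    tr
  })
  traces <- dplyr::bind_rows(traces)[, c("roi_id", "frame", "time_s", "raw")]
  attr(traces, "frame_rate") <- cfg$frame_rate
  structure(list(traces = traces, truth = truth,
                 frame_rate = cfg$frame_rate, config = cfg),
            class = "ca_recording")
}

#' @export
print.ca_recording <- function(x, ...) {
  cat(sprintf("<ca_recording> %d cells x %d frames @ %g Hz (%d active)\n",
              x$config$n_cells, x$config$n_frames, x$frame_rate,
              sum(x$truth$active)))
  invisible(x)
}

# modify a synth_config, revalidating
synth_config_replace <- function(cfg, ...) {
  new <- utils::modifyList(unclass(cfg), list(...))
  class(new) <- "synth_config"
  validate_synth_config(new)
  new
}
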