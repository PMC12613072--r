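#' Configuration for the synthetic-recording generator
#'
#' Describes one simulated recording: geometry, kinetics, event statistics,
#' baseline drift, noise and motion.  The defaults emulate a desk-scale
#' two-photon recording of a neural organoid expressing a fast GCaMP
#' indicator: 64 x 64 px at 30 Hz for 2 minutes, spontaneous transients on
#' a slowly drifting baseline, shot-like Gaussian noise, and a bounded
#' random-walk rigid motion.  The full acquisition size used for organoid
#' recordings (512 x 512 px at 30 Hz) is supported but not the default.
#'
#' Transients are modelled as a difference-of-exponentials kernel
#' `(1 - exp(-t/rise_tau)) * exp(-t/decay_tau)`, peak-normalised so that an
#' event's `amplitude` is its true peak height in dF/F0 units (see
#' [calcium_kernel()]).  The default kinetics (`rise_tau` 0.1 s,
#' `decay_tau` 1.5 s) describe the few-spike bursts that dominate
#' spontaneous organoid recordings rather than a single action potential;
#' single-spike kinetics can be requested explicitly.
#'
#' @param n_frames Number of frames (>= 1).
#' @param frame_rate Acquisition rate, Hz.
#' @param height,width Frame size in pixels (movies only).
#' @param n_cells Number of cells.
#' @param active_fraction Proportion of cells that are active, in `[0, 1]`.
#'   With `active_sampling = "fixed"` (default) the number of active cells
#'   is exactly `floor(n_cells * active_fraction)`, but at least 1 whenever
#'   `active_fraction > 0` — deterministic, so tests can assert counts.
#' @param active_sampling `"fixed"` (see `active_fraction`) or
#'   `"binomial"`, where each cell is active independently with probability
#'   `active_fraction`.  Binomial sampling reproduces the organoid-to-organoid
#'   variability of real cohorts and is what cohort-level statistics
#'   (which need within-group variance) should use.
#' @param event_rate_active Mean event rate of active cells, events/min.
#'   Active cells always receive at least one event (zero-truncated
#'   Poisson), so the ground-truth activity label is meaningful.
#' @param amplitude_mean,amplitude_sd Event peak amplitude distribution,
#'   dF/F0 units (Gaussian, floored at 0.05).
#' @param rise_tau,decay_tau Kernel time constants, seconds
#'   (`rise_tau < decay_tau`).
#' @param baseline_level Resting fluorescence, arbitrary units (> 0).
#' @param drift_amplitude Slow baseline drift, as a fraction of
#'   `baseline_level` (sinusoid, random phase).
#' @param drift_period Drift period, seconds.  Kept much longer than the
#'   15 s baseline window so the percentile baseline can track it.
#' @param noise_sd Additive Gaussian noise SD, fluorescence units.  Applied
#'   per sample for traces and per pixel for movies.
#' @param motion_max_shift Maximum rigid shift magnitude, pixels (movies).
#' @param cell_radius Cell disk radius, pixels (movies).
#' @param background_level Background intensity outside cells (movies).
#' @param seed Integer RNG seed; identical configurations produce
#'   byte-identical output.
#' @return A `synth_config` object (a named list).
#' @examples
#' cfg <- synth_config(n_cells = 10, active_fraction = 0.3, seed = 1)
#' cfg$n_frames
#' @export
synth_config <- function(n_frames = 3600L,
                         frame_rate = 30,
                         height = 64L,
                         width = 64L,
                         n_cells = 20L,
                         active_fraction = 0.3,
                         active_sampling = c("fixed", "binomial"),
                         event_rate_active = 2,
                         amplitude_mean = 0.6,
                         amplitude_sd = 0.1,
                         rise_tau = 0.1,
                         decay_tau = 1.5,
                         baseline_level = 100,
                         drift_amplitude = 0.05,
                         drift_period = 120,
                         noise_sd = 2,
                         motion_max_shift = 5L,
                         cell_radius = 3L,
                         background_level = 5,
                         seed = 1L) {
  cfg <- list(
    n_frames = as.integer(n_frames), frame_rate = as.numeric(frame_rate),
    height = as.integer(height), width = as.integer(width),
    n_cells = as.integer(n_cells), active_fraction = as.numeric(active_fraction),
    active_sampling = match.arg(active_sampling),
    event_rate_active = as.numeric(event_rate_active),
    amplitude_mean = as.numeric(amplitude_mean),
    amplitude_sd = as.numeric(amplitude_sd),
    rise_tau = as.numeric(rise_tau), decay_tau = as.numeric(decay_tau),
    baseline_level = as.numeric(baseline_level),
    drift_amplitude = as.numeric(drift_amplitude),
    drift_period = as.numeric(drift_period),
    noise_sd = as.numeric(noise_sd),
    motion_max_shift = as.integer(motion_max_shift),
    cell_radius = as.integer(cell_radius),
    background_level = as.numeric(background_level),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_frames < 1L) abort("`n_frames` must be >= 1.")
  if (cfg$frame_rate <= 0) abort("`frame_rate` must be > 0.")
  if (cfg$active_fraction < 0 || cfg$active_fraction > 1) {
    abort("`active_fraction` must lie in [0, 1].")
  }
  if (cfg$baseline_level <= 0) {
    abort("`baseline_level` must be > 0: dF/F0 is undefined for a non-positive baseline.")
  }
  if (cfg$amplitude_sd < 0 || cfg$noise_sd < 0) abort("SDs must be >= 0.")
  if (cfg$rise_tau >= cfg$decay_tau) abort("`rise_tau` must be < `decay_tau`.")
  if (cfg$rise_tau <= 0) abort("`rise_tau` must be > 0.")
  if (cfg$event_rate_active < 0) abort("`event_rate_active` must be >= 0.")
  if (cfg$n_cells < 1L) abort("`n_cells` must be >= 1.")
  if (cfg$motion_max_shift < 0L) abort("`motion_max_shift` must be >= 0.")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d frames @ %g Hz, %d x %d px, %d cells (%.0f%% active), seed %d\n",
    x$n_frames, x$frame_rate, x$height, x$width, x$n_cells,
    100 * x$active_fraction, x$seed))
  invisible(x)
}

# floor(n * fraction), but at least one active cell when fraction > 0
n_active_cells <- function(n_cells, active_fraction) {
  if (active_fraction <= 0) return(0L)
  max(1L, as.integer(floor(n_cells * active_fraction)))
}

#' Peak-normalised calcium transient kernel
#'
#' Difference-of-exponentials impulse response
#' `(1 - exp(-t/rise_tau)) * exp(-t/decay_tau)` for `t >= 0`, scaled to a
#' unit peak so that multiplying by an amplitude gives a transient whose
#' true dF/F0 peak equals that amplitude.  The peak occurs at
#' `t = rise_tau * log(1 + decay_tau/rise_tau)`.
#'
#' @param t Time since event onset, seconds (vector; negative values give 0).
#' @param rise_tau,decay_tau Time constants, seconds.
#' @return Kernel values, unit peak.
#' @examples
#' max(calcium_kernel(seq(0, 10, by = 1/30), 0.1, 1.5))
#' @export
calcium_kernel <- function(t, rise_tau, decay_tau) {
  stopifnot(rise_tau > 0, decay_tau > rise_tau)
  k <- numeric(length(t))
  pos <- t >= 0
  k[pos] <- (1 - exp(-t[pos] / rise_tau)) * exp(-t[pos] / decay_tau)
  t_peak <- rise_tau * log(1 + decay_tau / rise_tau)
  k / ((1 - exp(-t_peak / rise_tau)) * exp(-t_peak / decay_tau))
}
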