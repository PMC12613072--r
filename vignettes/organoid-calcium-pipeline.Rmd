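---
title: "Quantifying spontaneous activity in organoid calcium-imaging recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spontaneous activity in organoid calcium-imaging recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrace)
library(dplyr)
```

## The measurement problem

Two-photon recordings of neural organoids expressing a genetically encoded
calcium indicator (here modelled on jGCaMP7f) report neuronal activity as
transient increases in fluorescence.  Turning a raw movie into the summary
statistics a cohort comparison needs — the fraction of active cells per
organoid, and the frequency and amplitude of their Ca²⁺ events — takes a
chain of standard but fiddly steps, each with parameters that change the
answer.  `catrace` implements that chain as composable, tibble-first
functions, and ships a synthetic-recording generator with exact ground
truth so that every stage can be validated without access to raw
recordings.

The pipeline is:

1. **Rigid motion correction.**  Each frame's displacement `(dy, dx)`
   relative to a reference image is the argmax of the FFT-based
   cross-correlation of the mean-subtracted images, searched over
   `|dy|, |dx| ≤ max_shift`; frames are translated back by the negated
   shift with constant-fill 0 outside the field of view
   (`estimate_shifts()`, `apply_shifts()`).
2. **ROIs and traces.**  Cell ROIs come from a seeded region-growing step
   (`grow_roi()`), an automated surrogate for interactive cell outlining;
   a cell's raw trace is the mean intensity over its pixel set per frame
   (`extract_traces()`).
3. **Smoothing.**  Savitzky–Golay filtering of the raw trace
   (`smooth_traces()`), default width 301 frames, order 3.
4. **Baseline and ΔF/F0.**  F0 is the running 10th percentile of the
   smoothed trace over a window of duration `1 / cutoff` (15 s, i.e. 450
   frames at 30 Hz), and `ΔF/F0 = (F − F0) / F0`
   (`estimate_baseline()`, `compute_dff()`).
5. **Event detection.**  A Ca²⁺ event is a ΔF/F0 peak with height ≥ 0.2,
   width at half prominence ≥ 15 frames, and separation ≥ 30 frames from
   any taller retained peak (`detect_events()`; `find_peaks()` implements
   the findpeaks-compatible semantics).
6. **Active-cell classification.**  A cell is active iff, on its ΔF/F0
   series, skewness > 1.0 **and** SD > 0.04 **and** ≥ 1 event was
   detected — all strict inequalities (`classify_cells()`).
7. **Summaries and statistics.**  Per organoid: active cell rate
   `100 · n_active / n_rois`; groups are compared with a two-tailed
   Student's t test (organoid as the unit for the active cell rate), or
   one-way ANOVA plus Dunnett/Tukey for more than two groups
   (`summarize_organoids()`, `compare_groups()`).

```{r pipeline-demo}
cfg <- synth_config(n_cells = 10, active_fraction = 0.3, seed = 7)
rec <- simulate_recording(cfg)
res <- analyze_recording(rec$traces, processing_params(30, sg_width = 31))
res$cells
```

## What the generator emulates

`synth_config()` describes one simulated recording.  A cell's raw
fluorescence is

\[
F(t) \;=\; B(t)\,\bigl(1 + \textstyle\sum_i a_i\,k(t - t_i)\bigr) + \varepsilon(t),
\]

where `B(t)` is the baseline (default 100 a.u.) times a slow sinusoidal
drift (default ±5%, period 120 s — long relative to the 15-s baseline
window, so the percentile baseline can track it), `k` is the
peak-normalised difference-of-exponentials kernel
`(1 − e^{−t/τ_r}) e^{−t/τ_d}` (`calcium_kernel()`), `a_i` are event
amplitudes in ΔF/F0 units, and `ε` is i.i.d. Gaussian noise.  Because
events scale the baseline multiplicatively, the true ΔF/F0 peak of an
isolated event equals its programmed amplitude — which is what makes the
generator usable as an oracle for amplitude recovery.

Event schedules are homogeneous Poisson (default 2 events/min for active
cells), with one adjustment: an *active* cell resamples until it has at
least one event (zero-truncated Poisson), so the ground-truth activity
label always means something observable.  At the default rate and
duration this inflates the realised rate by 1.8%, far below the
estimator's validation band.  Inactive cells have exactly zero events.

Movies place non-overlapping disk cells on a dark background, drive each
disk's pixels with the cell's clean signal, shift every frame by a bounded
integer random walk, and add per-pixel noise; the returned ground truth
records labels, schedules, amplitudes, true ROI pixel sets and per-frame
shifts.

Two sampling rules for the number of active cells are provided.  The
default (`active_sampling = "fixed"`) uses `floor(n_cells ·
active_fraction)` (minimum 1 when the fraction is positive) so tests can
assert exact counts.  Cohort-level studies should use `"binomial"`, where
each cell is active independently with probability `active_fraction`:
real organoids vary widely around the mean rate, and a two-sample t test
on per-organoid rates is only meaningful when that within-group variance
exists.

What the generator does **not** emulate: optical point-spread blur,
neuropil contamination, photobleaching, shot-noise scaling with intensity,
overlapping cells, and spike-to-fluorescence biophysics.  Passing the
recovery studies therefore shows the *pipeline's contracts* are
implemented correctly, not that the pipeline is robust to every artefact
of real tissue.

## Transient kinetics and the choice of smoothing width

The kernel defaults are `τ_r = 0.1 s`, `τ_d = 1.5 s` — the few-spike
bursts that dominate spontaneous organoid activity, not a single action
potential (jGCaMP7f's single-spike decay is ~0.3 s).  This choice is
forced by the detection criteria themselves: a 0.05/0.5-s transient has a
width at half prominence of ~11 frames at 30 Hz, below the 15-frame
minimum width, so single-spike transients are rejected by construction;
and the recording-scale 301-frame smoother attenuates them to ~0.14× of
their true amplitude.  Events that the criteria are designed to count are
necessarily slower than single spikes.

The same reasoning governs the smoothing width used in the validation
studies.  A Savitzky–Golay window passes signals whose timescale is long
relative to the window and attenuates the rest; numerically, a
1.5-s-decay transient retains 96% of its peak under a 31-frame (~1 s)
window but only ~33% under 301 frames.  The 301-frame default is kept
because it is the recording-scale setting for data whose events are slow
network bursts spanning many seconds; the synthetic studies in this
package use `sg_width = 31`, matched to the synthetic kinetics, because a
smoother much wider than the transient measures a (well-defined but)
attenuated quantity, and the point of the studies is to recover the
programmed amplitudes.  When applying the pipeline to real data, choose
the width by the same rule: comfortably wider than the noise, comfortably
narrower than the events.

## Numerical choices

* **Savitzky–Golay edges.**  Interior points use the standard centred
  least-squares convolution.  Within half a window of either end the
  polynomial is fitted on the truncated window actually available (no
  padding), so polynomials up to the filter order are reproduced exactly
  along the entire trace; if a truncated window has fewer points than the
  order needs, the order drops to fit.  Traces shorter than the window
  auto-shrink it to the largest valid odd length, with a warning.
* **Baseline percentile.**  The sliding window is centred and truncated
  at the trace ends, and each window's percentile replicates
  `stats::quantile(type = 7)` bit for bit (verified against a brute-force
  oracle).  An alternative reading of a "low-pass percentile filter" —
  windowed percentile followed by a zero-phase 2nd-order Butterworth
  low-pass at the cutoff frequency — is available via
  `baseline_mode = "percentile+butterworth"`; the filtered series is
  mean-centred and reflection-padded so a constant baseline passes
  through exactly.  F0 must be strictly positive; a non-positive F0 is an
  error that asks for background-offset handling rather than a silent
  NaN.
* **ΔF/F0 numerator.**  The stated processing order is smooth first, then
  normalise; `dff_numerator = "raw"` switches the numerator if the
  unsmoothed convention is wanted.
* **Peak semantics.**  Height is an absolute threshold at the peak sample
  (≥, so the printed boundary value itself passes).  Prominence is
  measured against the higher terrain on either side; width is the
  distance between the interpolated crossings of the half-prominence
  reference (`width_reference = "halfheight"` switches the reference).
  Distance suppression scans peaks from tallest to smallest (ties: the
  earlier frame wins) and discards any peak closer than `min_distance`
  frames to an already retained one; a separation of exactly
  `min_distance` survives.  A plateau of equal samples counts as one
  peak at its centre (left of centre for even plateaus); trace endpoints
  are never peaks.  All of this is pinned test-by-test against an
  independent brute-force enumerator.
* **Classification boundaries.**  The three activity criteria are strict
  inequalities, so a cell sitting exactly at skewness 1.0 or SD 0.04 is
  inactive.  Skewness is the biased moment coefficient g1 (the common
  default in numerical environments; `adjust = TRUE` gives the corrected
  form) and SD uses the n−1 denominator.
* **Registration.**  The reference defaults to the mean image (stabler
  than any single frame; `"first"` or an index are available — note that
  shifts are only defined *relative to the reference*, so comparisons
  against a simulation's programmed shifts use `"first"`).  Correlation
  ties resolve to the first candidate in row-major order; out-of-field
  pixels are zero-filled rather than wrapped, since wrapped pixels would
  corrupt ROI traces.  Integer-pixel estimates are the default, with
  optional 3-point parabolic subpixel refinement.
* **Coordinates.**  In memory, pixels are 1-based (R convention); every
  file format reads and writes 0-based coordinates and frame indices.

## Statistics

For the active cell rate the statistical unit is the organoid (each
organoid contributes one rate); for event frequency and amplitude the
unit is the cell, pooled across the organoids of a group, and by default
only active cells contribute (`freq_active_only = TRUE`) — the convention
of per-cell activity figures in the organoid literature; the switch
documents rather than hides the choice.  Two groups: two-tailed Student's
t with equal variances.  More than two: one-way ANOVA, then Dunnett
against an explicitly named control (the control is never guessed) or
Tukey all-pairs.  Significance is 0.05 throughout.

```{r cohort-demo}
design <- tibble::tibble(
  organoid_id = sprintf("org%02d", 1:12),
  group = rep(c("NC", "MDS"), each = 6),
  active_fraction = rep(c(0.10, 0.03), each = 6)
)
coh <- simulate_cohort(design, synth_config(n_frames = 1200, n_cells = 20,
                                            active_sampling = "binomial",
                                            seed = 1))
res <- analyze_cohort(coh, processing_params(30, sg_width = 31))
gt <- compare_groups(res$summaries)
tidy(gt)
```

## Validation studies and their sizes

The test suite validates each stage against an independent oracle, at
desk-scale sizes chosen so the full suite runs in a few minutes on one
CPU:

* peak detector vs brute-force enumeration on 1,000 random traces of up
  to 2,000 frames, exact agreement;
* baseline vs per-frame brute-force percentile, exact; constant-trace,
  shift-equivariance and scale-invariance identities to 1e-9;
* cubic reproduction of the order-3 smoother to 1e-8;
* registration: exact recovery of programmed integer shifts without
  noise, ≥95% of frames within 1 px at 5% noise (64 × 64 px movies);
* classification: ≥95% label accuracy and the programmed active fraction
  recovered within 3 percentage points over 10 × 50-cell organoids;
* cohort contrast: programmed fractions 0.10 vs 0.03, 10 organoids per
  group, 50 cells each, 60-s recordings, binomial sampling — the t test
  is significant in ≥90% of 20 replicate cohorts (closed-form power at
  these sizes is ≈0.99);
* estimator recovery: programmed rate and amplitude recovered within 15%
  and 10% over 100 active cells.

`scripts/acceptance.R` re-runs the same computations from scratch and
writes the headline numbers as JSON.

## Known limitations

Merged events: two events closer than roughly the smoothed transient
width are detected as one peak, which biases rates down (≈ −10% at
2 events/min with matched smoothing) and amplitudes up (+5–10%); both
remain within the validation bands but would grow at higher rates.
Detected amplitudes are attenuated whenever the smoothing window is wide
relative to the true transient — at the recording-scale default this is a
property of the measurement definition, not an error.  Non-rigid motion,
z-drift, neuropil contamination and bleaching are out of scope, as are
synchrony/network metrics and mixed-effects modelling of cells nested in
organoids.
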