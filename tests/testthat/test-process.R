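make_trace <- function(x, frame_rate = 30) {
  out <- tibble::tibble(frame = seq_along(x),
                        time_s = (seq_along(x) - 1) / frame_rate,
                        raw = as.numeric(x))
  attr(out, "frame_rate") <- frame_rate
  out
}

test_that("an order-3 filter reproduces cubic polynomials along the whole trace", {
  t <- seq_len(800)
  x <- 2 + 0.5 * t - 1e-3 * t^2 + 5e-7 * t^3
  sm <- sg_filter(x, 301, 3)
  expect_lt(max(abs(sm - x)), 1e-8)
  expect_equal(sg_filter(rep(4.2, 500), 31, 3), rep(4.2, 500))
})

test_that("interior smoothing matches an established Savitzky-Golay implementation", {
  withr::with_seed(1, x <- rnorm(600, 100, 3))
  sm <- sg_filter(x, 31, 3)
  ref <- as.numeric(signal::sgolayfilt(x, p = 3, n = 31))
  interior <- 16:585
  expect_equal(sm[interior], ref[interior], tolerance = 1e-10)
})

test_that("smoothing shrinks white-noise variance and auto-shrinks on short traces", {
  withr::with_seed(2, x <- rnorm(3000))
  expect_lt(var(sg_filter(x, 301, 3)), 0.2 * var(x))
  expect_warning(sm <- sg_filter(rnorm(51), 301, 3), "auto-shrunk")
  expect_length(sm, 51)
  expect_error(suppressWarnings(sg_filter(rnorm(3), 301, 3)), "too short")
})

test_that("the windowed percentile baseline matches the brute-force oracle exactly", {
  withr::with_seed(3, {
    for (n in c(150, 1000, 2000)) {
      x <- rnorm(n, 100, 5) + 20 * exp(-((seq_len(n) - n / 2) / 30)^2)
      for (w in c(31, 450)) {
        expect_identical(running_percentile(x, w, 10),
                         oracle_running_percentile(x, w, 10))
      }
    }
  })
})

test_that("a brief transient leaves the percentile baseline untouched", {
  x <- rep(100, 1200)
  x[600:609] <- 200
  tr <- make_trace(x)
  tr$smoothed <- x  # bypass smoothing: test the baseline stage in isolation
  f0 <- estimate_baseline(tr, processing_params(30))$f0
  expect_equal(f0, rep(100, 1200))
})

test_that("F0 is shift-equivariant and dF/F0 is scale-invariant", {
  withr::with_seed(4, x <- rnorm(900, 100, 2))
  params <- processing_params(30, sg_width = 31)
  base <- process_traces(make_trace(x), params)
  shifted <- process_traces(make_trace(x + 37), params)
  expect_equal(shifted$f0, base$f0 + 37, tolerance = 1e-9)
  scaled <- process_traces(make_trace(3 * x), params)
  expect_equal(scaled$dff, base$dff, tolerance = 1e-9)
})

test_that("dF/F0 arithmetic and degenerate baselines behave as specified", {
  tr <- make_trace(rep(1, 100))
  tr$smoothed <- rep(150, 100)
  tr$f0 <- rep(100, 100)
  expect_equal(compute_dff(tr)$dff, rep(0.5, 100))
  tr$smoothed <- tr$f0
  expect_equal(compute_dff(tr)$dff, rep(0, 100))
  # constant trace: F0 equals the constant, dff is zero everywhere
  const <- process_traces(make_trace(rep(100, 700)),
                          processing_params(30, sg_width = 31))
  expect_equal(const$f0, rep(100, 700))
  expect_equal(const$dff, rep(0, 700))
  neg <- make_trace(rep(-5, 700))
  expect_error(process_traces(neg, processing_params(30, sg_width = 31)),
               "offset")
})

test_that("slow drift without events stays within the dead band of dF/F0", {
  cfg <- synth_config(n_frames = 3600, active_fraction = 0, n_cells = 1,
                      noise_sd = 0, drift_amplitude = 0.05,
                      drift_period = 120, seed = 6)
  rec <- simulate_recording(cfg)
  proc <- process_traces(rec$traces, processing_params(30))
  expect_lt(max(abs(proc$dff)), 0.05)
})

test_that("the butterworth baseline mode runs and tracks a constant trace", {
  params <- processing_params(30, sg_width = 31,
                              baseline_mode = "percentile+butterworth")
  proc <- process_traces(make_trace(rep(80, 900)), params)
  expect_equal(proc$f0, rep(80, 900), tolerance = 1e-6)
})

test_that("parameter validation rejects malformed processing settings", {
  expect_error(processing_params(30, sg_width = 300), "odd")
  expect_error(processing_params(30, sg_width = 3, sg_polyorder = 3), "polyorder")
  expect_error(processing_params(30, baseline_percentile = 0), "percentile")
  expect_error(processing_params(0), "frame_rate")
  expect_error(estimate_baseline(make_trace(1:10), processing_params(30)),
               "smoothed")
})
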