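gauss_bump <- function(n, centre, height, sigma) {
  height * exp(-((seq_len(n) - centre)^2) / (2 * sigma^2))
}

make_dff_trace <- function(dff, frame_rate = 30) {
  out <- tibble::tibble(frame = seq_along(dff),
                        time_s = (seq_along(dff) - 1) / frame_rate,
                        raw = NA_real_, smoothed = NA_real_, f0 = 1,
                        dff = as.numeric(dff))
  attr(out, "frame_rate") <- frame_rate
  out
}

test_that("flat and empty traces yield no events without erroring", {
  expect_equal(nrow(find_peaks(rep(0, 500))), 0L)
  expect_equal(nrow(detect_events(make_dff_trace(rep(0, 500)))), 0L)
  expect_error(detect_events(tibble::tibble(raw = 1:10)), "dff")
})

test_that("a single broad bump is one event with its construction height", {
  # FWHM = 2*sqrt(2*log(2))*sigma = 40 frames
  sigma <- 40 / (2 * sqrt(2 * log(2)))
  pk <- find_peaks(gauss_bump(400, 200, 0.5, sigma))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak_frame, 200L)
  expect_equal(pk$height, 0.5)
  expect_equal(pk$width_frames, 40, tolerance = 0.01)
  # same bump below the height criterion: rejected
  expect_equal(nrow(find_peaks(gauss_bump(400, 200, 0.15, sigma))), 0L)
})

test_that("of two close peaks only the taller survives distance suppression", {
  sigma <- 3
  x <- gauss_bump(300, 100, 0.5, sigma) + gauss_bump(300, 120, 0.4, sigma)
  params <- peak_params(min_width = 1)
  pk <- find_peaks(x, params)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak_frame, 100L)
  # same two peaks 31 frames apart: both kept
  x2 <- gauss_bump(300, 100, 0.5, sigma) + gauss_bump(300, 131, 0.4, sigma)
  expect_equal(find_peaks(x2, params)$peak_frame, c(100L, 131L))
})

test_that("plateau peaks are positioned at their centre", {
  x <- c(rep(0, 10), rep(0.5, 5), rep(0, 10))
  pk <- find_peaks(x, peak_params(min_width = 1))
  expect_equal(pk$peak_frame, 13L)  # centre of frames 11:15
  x_even <- c(rep(0, 10), rep(0.5, 4), rep(0, 10))
  expect_equal(find_peaks(x_even, peak_params(min_width = 1))$peak_frame, 12L)
})

test_that("the detector matches the brute-force enumerator on structured cases", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      x <- random_dff_trace(sample(200:1200, 1))
      h <- sample(c(0.15, 0.2, 0.3), 1)
      d <- sample(c(5, 30, 60), 1)
      w <- sample(c(1, 8, 15), 1)
      got <- find_peaks(x, peak_params(h, d, w))
      want <- oracle_find_peaks(x, h, d, w)
      expect_identical(got$peak_frame, want$peak_frame)
      expect_identical(got$height, want$height)
      expect_identical(got$prominence, want$prominence)
      expect_identical(got$width_frames, want$width_frames)
    }
  })
})

test_that("retained peaks are separated and counts fall as the height bar rises", {
  withr::with_seed(8, {
    for (rep in 1:10) {
      x <- random_dff_trace(800)
      pk <- find_peaks(x, peak_params(0.1, 30, 5))
      if (nrow(pk) > 1L) expect_true(all(diff(pk$peak_frame) >= 30))
      n_by_h <- vapply(c(0.1, 0.2, 0.3, 0.5),
                       function(h) nrow(find_peaks(x, peak_params(h, 30, 5))),
                       numeric(1))
      expect_true(all(diff(n_by_h) <= 0))
    }
  })
})

test_that("event rates and amplitudes follow their definitions", {
  ev <- tibble::tibble(peak_frame = c(10, 50, 90, 130),
                       height = c(0.4, 0.6, 0.5, 0.5))
  expect_equal(event_rate(ev, 120)$freq_per_min, 2)
  expect_equal(event_rate(ev[0, ], 120)$freq_per_min, 0)
  expect_error(event_rate(ev, 0), "duration")
  expect_equal(mean_amplitude(tibble::tibble(height = c(0.4, 0.6)))$mean_amp, 0.5)
  expect_equal(mean_amplitude(tibble::tibble(height = 0.7))$mean_amp, 0.7)
  expect_error(mean_amplitude(ev[0, ]), "undefined")
})

test_that("events are recovered with high recall and precision on well-separated schedules", {
  cfg <- synth_config(seed = 17)
  withr::local_seed(41)
  n_cells <- 30
  tp <- 0L; fn <- 0L; fp <- 0L
  for (i in seq_len(n_cells)) {
    dur <- cfg$n_frames / cfg$frame_rate
    # schedules at least 2 x min_peak_distance (60 frames = 2 s) apart
    times <- sort(runif(4, 2, dur - 4))
    while (length(times) > 1 && min(diff(times)) < 2) {
      times <- sort(runif(4, 2, dur - 4))
    }
    ev <- data.frame(time_s = times,
                     amplitude = pmax(rnorm(length(times), 0.6, 0.1), 0.4))
    tr <- simulate_trace(synth_config(seed = 100 + i), events = ev)
    det <- detect_events(process_traces(tr, synth_params()))
    matched <- logical(nrow(det))
    for (t0 in times) {
      hit <- which(!matched & abs(det$peak_time_s - t0) <= cfg$decay_tau)
      if (length(hit)) { matched[hit[1]] <- TRUE; tp <- tp + 1L }
      else fn <- fn + 1L
    }
    fp <- fp + sum(!matched)
  }
  expect_gte(tp / (tp + fn), 0.9)  # recall
  expect_gte(tp / (tp + fp), 0.9)  # precision
})
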