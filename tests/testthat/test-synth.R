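test_that("a configuration with no events, drift or noise gives a constant trace", {
  cfg <- synth_config(n_frames = 300, noise_sd = 0, drift_amplitude = 0,
                      baseline_level = 100, seed = 1)
  tr <- simulate_trace(cfg, events = data.frame(time_s = numeric(),
                                                amplitude = numeric()))
  expect_equal(tr$raw, rep(100, 300))
})

test_that("an isolated event peaks just after its onset at its programmed dF/F0", {
  cfg <- synth_config(n_frames = 900, noise_sd = 0, drift_amplitude = 0, seed = 1)
  tr <- simulate_trace(cfg, events = data.frame(time_s = 5, amplitude = 0.5))
  imax <- which.max(tr$raw)
  expect_gt(tr$time_s[imax], 5)
  expect_lt(tr$time_s[imax], 5 + cfg$decay_tau)
  # dF/F0 computed downstream with near-transparent smoothing
  dff <- process_traces(tr, processing_params(30, sg_width = 5))$dff
  expect_equal(max(dff), 0.5, tolerance = 0.05)
})

test_that("identical seeds reproduce traces, movies and truth bit for bit", {
  cfg <- synth_config(n_frames = 200, n_cells = 4, seed = 11)
  expect_identical(simulate_trace(cfg), simulate_trace(cfg))
  expect_identical(simulate_truth(cfg), simulate_truth(cfg))
  s1 <- simulate_movie(cfg); s2 <- simulate_movie(cfg)
  expect_identical(unclass(s1$movie), unclass(s2$movie))
  expect_identical(s1$shifts, s2$shifts)
})

test_that("inactive cells carry exactly zero events and the active count follows floor(n x f)", {
  truth <- simulate_truth(synth_config(n_cells = 10, active_fraction = 0.25,
                                       seed = 3))
  expect_equal(sum(truth$active), 2L)  # floor(10 * 0.25)
  expect_true(all(truth$n_events[!truth$active] == 0L))
  expect_true(all(truth$n_events[truth$active] >= 1L))
  dur <- 3600 / 30
  for (ev in truth$events) {
    expect_true(all(ev$time_s >= 0 & ev$time_s <= dur))
  }
  # at least one active cell whenever the fraction is positive
  t3 <- simulate_truth(synth_config(n_cells = 3, active_fraction = 1 / 3, seed = 4))
  expect_equal(sum(t3$active), 1L)
  t0 <- simulate_truth(synth_config(n_cells = 5, active_fraction = 0, seed = 4))
  expect_equal(sum(t0$active), 0L)
  t_small <- simulate_truth(synth_config(n_cells = 20, active_fraction = 0.01,
                                         seed = 4))
  expect_equal(sum(t_small$active), 1L)
})

test_that("with no noise or drift, events only ever add fluorescence", {
  cfg <- synth_config(n_frames = 1200, noise_sd = 0, drift_amplitude = 0,
                      active_fraction = 1, n_cells = 3, seed = 5)
  rec <- simulate_recording(cfg)
  expect_true(all(rec$traces$raw >= cfg$baseline_level - 1e-9))
})

test_that("simulate_trace rejects a non-positive baseline", {
  expect_error(synth_config(baseline_level = 0), "baseline")
})

test_that("movie ROI means reproduce the generated cell signals exactly when motion-free", {
  sim <- simulate_movie(synth_config(n_frames = 40, n_cells = 4,
                                     motion_max_shift = 0, noise_sd = 0,
                                     seed = 8))
  expect_true(all(sim$shifts$dy == 0 & sim$shifts$dx == 0))
  traces <- extract_traces(sim$movie, sim$rois)
  for (i in 1:4) {
    expect_equal(traces$raw[traces$roi_id == i], sim$cell_traces[[i]],
                 tolerance = 1e-12)
  }
})

test_that("impossible cell packing is rejected with a message naming the constraint", {
  expect_error(
    simulate_movie(synth_config(height = 20, width = 20, n_cells = 50,
                                n_frames = 5, seed = 1)),
    "non-overlapping|too small")
})

test_that("cohorts carry verbatim group labels and are reproducible on disk", {
  design <- data.frame(organoid_id = c("org-A", "org-B"),
                       group = c("line A", "line B"))
  cfg <- synth_config(n_frames = 150, n_cells = 3, seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- simulate_cohort(design, cfg, dir = d1)
  c2 <- simulate_cohort(design, cfg, dir = d2)
  expect_equal(nrow(c1$manifest), 2L)
  expect_identical(c1$manifest$group, c("line A", "line B"))
  for (f in basename(c1$manifest$path)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_error(simulate_cohort(data.frame(organoid_id = c("x", "x"),
                                          group = "g"), cfg),
               "Duplicate")
})

test_that("bright, clean active cells always clear the event height criterion end to end", {
  cfg <- synth_config(n_cells = 6, active_fraction = 1, amplitude_mean = 0.4,
                      amplitude_sd = 0, noise_sd = 2, seed = 31)
  rec <- simulate_recording(cfg)
  res <- analyze_recording(rec$traces, synth_params())
  expect_true(all(rec$truth$roi_id %in% res$events$roi_id))
  expect_true(all(res$events$height >= 0.2))
})
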