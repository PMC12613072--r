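# small structured frame used to build movies with known displacements
make_scene <- function(h = 48, w = 48, seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(5, h, w)
    for (k in 1:6) {
      r <- sample(10:(h - 10), 1); c <- sample(10:(w - 10), 1)
      img[(r - 2):(r + 2), (c - 2):(c + 2)] <- runif(1, 80, 120)
    }
    img
  })
}

roll2 <- function(m, dy, dx) {  # circular roll, independent of package code
  m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
    ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
}

test_that("a rolled frame is assigned exactly its displacement", {
  img <- make_scene()
  mov <- ca_movie(list(img, roll2(img, 3, -2)), frame_rate = 30)
  est <- estimate_shifts(mov, reference = "first", max_shift = 8)
  expect_equal(est$dy, c(0, 3))
  expect_equal(est$dx, c(0, -2))
})

test_that("identical frames give zero shifts everywhere", {
  img <- make_scene(seed = 2)
  mov <- ca_movie(list(img, img, img), frame_rate = 30)
  est <- estimate_shifts(mov, max_shift = 5)
  expect_true(all(est$dy == 0 & est$dx == 0))
})

test_that("ground-truth integer shifts are recovered exactly on noise-free movies", {
  sim <- simulate_movie(synth_config(n_frames = 40, n_cells = 5,
                                     motion_max_shift = 3, noise_sd = 0,
                                     drift_amplitude = 0, seed = 7))
  est <- estimate_shifts(sim$movie, reference = "first", max_shift = 6)
  expect_equal(est$dy, as.numeric(sim$shifts$dy))
  expect_equal(est$dx, as.numeric(sim$shifts$dx))
})

test_that("registering a noise-free integer-shift movie zeroes the re-estimated shifts", {
  sim <- simulate_movie(synth_config(n_frames = 30, n_cells = 5,
                                     motion_max_shift = 4, noise_sd = 0,
                                     drift_amplitude = 0, seed = 9))
  reg <- register_movie(sim$movie, reference = "first", max_shift = 8)
  est2 <- estimate_shifts(reg$movie, reference = "first", max_shift = 8)
  expect_true(all(est2$dy == 0 & est2$dx == 0))
})

test_that("shifting a whole movie by a constant offsets every estimated shift by it", {
  img <- make_scene(seed = 3)
  frames <- list(img, roll2(img, 1, 0), roll2(img, -2, 2))
  mov <- ca_movie(frames, 30)
  # same reference frame, every *other* frame offset by a constant (2, 1)
  mov_off <- ca_movie(list(img, roll2(frames[[2]], 2, 1),
                           roll2(frames[[3]], 2, 1)), 30)
  base <- estimate_shifts(mov, reference = "first", max_shift = 8)
  off <- estimate_shifts(mov_off, reference = "first", max_shift = 8)
  expect_equal(off$dy[2:3], base$dy[2:3] + 2)
  expect_equal(off$dx[2:3], base$dx[2:3] + 1)
})

test_that("apply_shifts with zero shifts is the identity and validates lengths", {
  img <- make_scene(seed = 4)
  mov <- ca_movie(list(img, img), 30)
  zero <- tibble::tibble(frame = 1:2, dy = 0, dx = 0)
  expect_equal(unclass(apply_shifts(mov, zero)), unclass(mov),
               ignore_attr = TRUE)
  one <- ca_movie(list(img), 30)
  expect_equal(unclass(apply_shifts(one, zero[1, ])), unclass(one),
               ignore_attr = TRUE)
  expect_error(apply_shifts(mov, zero[1, ]), "one row per frame")
})

test_that("degenerate inputs are flagged or rejected", {
  flat <- matrix(7, 32, 32)
  mov <- ca_movie(list(flat, make_scene(32, 32, 5)), 30)
  expect_warning(est <- estimate_shifts(mov, reference = 2, max_shift = 5),
                 "Zero-variance")
  expect_true(est$flagged[1] && !est$flagged[2])
  expect_equal(est$dy[1], 0)
  expect_error(estimate_shifts(mov, max_shift = 40), "max_shift")
})

test_that("estimates stay within 1 px of truth for most frames under 5% noise", {
  cfg <- synth_config(n_frames = 80, n_cells = 8, motion_max_shift = 4,
                      noise_sd = 5, drift_amplitude = 0, seed = 12)
  sim <- simulate_movie(cfg)
  est <- estimate_shifts(sim$movie, reference = "first", max_shift = 8)
  err <- pmax(abs(est$dy - sim$shifts$dy), abs(est$dx - sim$shifts$dx))
  expect_gte(mean(err <= 1), 0.95)
})

test_that("subpixel refinement stays within half a pixel of the integer optimum", {
  img <- make_scene(seed = 6)
  mov <- ca_movie(list(img, roll2(img, 2, 1)), 30)
  est <- estimate_shifts(mov, reference = "first", max_shift = 6,
                         subpixel = TRUE)
  expect_lt(abs(est$dy[2] - 2), 0.5)
  expect_lt(abs(est$dx[2] - 1), 0.5)
})
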