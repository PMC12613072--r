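#' Simulate a movie with ground truth
#'
#' Places `n_cells` non-overlapping disks on a dark background, drives each
#' disk's pixels with that cell's simulated trace (noise-free at this
#' stage), rigidly shifts every frame by a scheduled bounded random-walk
#' displacement, and finally adds per-pixel Gaussian noise.  The returned
#' ground truth records everything needed to validate downstream stages:
#' activity labels, event schedules, true ROI pixel sets and per-frame
#' shifts.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `ca_movie_sim` with elements `movie`
#'   ([ca_movie()]), `truth` (the cell table of [simulate_truth()]),
#'   `rois` (tibble `roi_id`, `row`, `col`; 1-based), `centers` (tibble
#'   `roi_id`, `row`, `col`), `shifts` (tibble `frame`, `dy`, `dx`),
#'   `cell_traces` (list of the clean per-cell signals driving each ROI,
#'   before motion and noise) and `config`.
#' @examples
#' sim <- simulate_movie(synth_config(n_frames = 60, n_cells = 4,
#'                                    motion_max_shift = 2, seed = 4))
#' sim$movie
#' @export
simulate_movie <- function(cfg) {
  validate_synth_config(cfg)
  withr::local_seed(cfg$seed)

  centers <- place_cells(cfg)
  rois <- disk_rois(centers, cfg$cell_radius, cfg$height, cfg$width)
  truth <- sim_truth_cells(cfg)
  cell_traces <- lapply(seq_len(cfg$n_cells), function(i) {
    noiseless <- synth_config_replace(cfg, noise_sd = 0)
    sim_trace_raw(noiseless, truth$events[[i]])$raw
  })
  shifts <- sim_shifts(cfg)

  frames <- array(cfg$background_level,
                  dim = c(cfg$height, cfg$width, cfg$n_frames))
  idx_by_cell <- lapply(seq_len(cfg$n_cells), function(i) {
    r <- rois[rois$roi_id == i, ]
    cbind(r$row, r$col)
  })
  for (t in seq_len(cfg$n_frames)) {
    fr <- frames[, , t]
    for (i in seq_len(cfg$n_cells)) {
      fr[idx_by_cell[[i]]] <- cell_traces[[i]][t]
    }
    if (shifts$dy[t] != 0 || shifts$dx[t] != 0) {
      fr <- translate_frame(fr, shifts$dy[t], shifts$dx[t],
                            fill = cfg$background_level)
    }
    frames[, , t] <- fr
  }
  if (cfg$noise_sd > 0) {
    frames <- frames + array(rnorm(length(frames), 0, cfg$noise_sd),
                             dim = dim(frames))
  }
  structure(list(movie = ca_movie(frames, cfg$frame_rate),
                 truth = truth, rois = rois, centers = centers,
                 shifts = shifts, cell_traces = cell_traces, config = cfg),
            class = "ca_movie_sim")
}

#' @export
print.ca_movie_sim <- function(x, ...) {
  cat("<ca_movie_sim>\n")
  print(x$movie)
  cat(sprintf("  %d cells (%d active), max |shift| %d px\n",
              x$config$n_cells, sum(x$truth$active),
              max(abs(c(x$shifts$dy, x$shifts$dx, 0L)))))
  invisible(x)
}

# rejection-sample non-overlapping disk centers, keeping cells clear of the
# border by radius + max shift so motion never clips a cell
place_cells <- function(cfg, max_tries = 5000L) {
  r <- cfg$cell_radius
  margin <- r + cfg$motion_max_shift + 1L
  lo_row <- margin + 1L; hi_row <- cfg$height - margin
  lo_col <- margin + 1L; hi_col <- cfg$width - margin
  if (hi_row < lo_row || hi_col < lo_col) {
    abort(sprintf(
      "Cannot place cells: frame %d x %d too small for radius %d + max shift %d.",
      cfg$height, cfg$width, r, cfg$motion_max_shift))
  }
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centers) < cfg$n_cells && tries < max_tries) {
    cand <- c(sample(lo_row:hi_row, 1L), sample(lo_col:hi_col, 1L))
    ok <- nrow(centers) == 0L ||
      all(sqrt(rowSums((t(t(centers) - cand))^2)) > 2 * r + 1)
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1L
  }
  if (nrow(centers) < cfg$n_cells) {
    abort(sprintf(
      "Cannot place %d non-overlapping cells of radius %d in a %d x %d frame.",
      cfg$n_cells, r, cfg$height, cfg$width))
  }
  tibble::tibble(roi_id = seq_len(cfg$n_cells),
                 row = as.integer(centers[, 1]),
                 col = as.integer(centers[, 2]))
}

# pixel sets of disks of the given radius (Euclidean)
disk_rois <- function(centers, radius, height, width) {
  purrr::map_dfr(seq_len(nrow(centers)), function(i) {
    cr <- centers$row[i]; cc <- centers$col[i]
    rows <- max(1L, cr - radius):min(height, cr + radius)
    cols <- max(1L, cc - radius):min(width, cc + radius)
    grid <- expand.grid(row = rows, col = cols)
    keep <- (grid$row - cr)^2 + (grid$col - cc)^2 <= radius^2
    tibble::tibble(roi_id = centers$roi_id[i],
                   row = as.integer(grid$row[keep]),
                   col = as.integer(grid$col[keep]))
  })
}

# bounded integer random walk, (0,0) at the first frame
sim_shifts <- function(cfg) {
  n <- cfg$n_frames
  m <- cfg$motion_max_shift
  dy <- integer(n); dx <- integer(n)
  if (m > 0L && n > 1L) {
    for (t in 2:n) {
      dy[t] <- min(max(dy[t - 1L] + sample(-1L:1L, 1L), -m), m)
      dx[t] <- min(max(dx[t - 1L] + sample(-1L:1L, 1L), -m), m)
    }
  }
  tibble::tibble(frame = seq_len(n), dy = dy, dx = dx)
}
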