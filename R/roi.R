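#' Grow a region of interest from a seed pixel
#'
#' Automated stand-in for manual cell outlining: starting from a seed
#' pixel, grows a 4-connected region over pixels whose intensity lies
#' within `tolerance * m` of `m`, the mean intensity of the 3 x 3
#' neighbourhood around the seed, clipped to a maximum Euclidean radius.
#' Deterministic: the result depends only on the image and arguments.
#'
#' @param frame 2-D intensity matrix (e.g. a mean image or single frame).
#' @param seed Seed pixel `c(row, col)`, 1-based.
#' @param radius_max Maximum radius around the seed, pixels (>= 1).
#' @param radius_min Minimum acceptable equivalent radius: growing fewer
#'   than the pixel count of a disk of this radius is an error.
#' @param tolerance Relative intensity tolerance (fraction of the seed
#'   neighbourhood mean).
#' @param min_intensity Absolute intensity floor: a seed neighbourhood
#'   dimmer than this is background and raises an error.  Default: 2 x the
#'   image median.
#' @return A tibble of ROI pixels: `row`, `col` (1-based).
#' @examples
#' img <- matrix(0, 32, 32)
#' img[14:18, 14:18] <- 100
#' nrow(grow_roi(img, c(16, 16), radius_max = 6))
#' @export
grow_roi <- function(frame, seed, radius_max = 8L, radius_min = 1L,
                     tolerance = 0.3, min_intensity = NULL) {
  stopifnot(is.matrix(frame), length(seed) == 2L, radius_min >= 1L,
            radius_max >= radius_min)
  d <- dim(frame)
  sr <- as.integer(seed[1L]); sc <- as.integer(seed[2L])
  if (sr < 1L || sr > d[1L] || sc < 1L || sc > d[2L]) {
    abort("Seed lies outside the frame.")
  }
  hood <- frame[max(1L, sr - 1L):min(d[1L], sr + 1L),
                max(1L, sc - 1L):min(d[2L], sc + 1L)]
  m <- mean(hood)
  if (is.null(min_intensity)) min_intensity <- 2 * stats::median(frame)
  if (m < min_intensity) {
    abort(sprintf(
      "Seed neighbourhood mean (%.3g) is below the background floor (%.3g): empty ROI.",
      m, min_intensity))
  }
  accept <- abs(frame - m) <= tolerance * m
  visited <- matrix(FALSE, d[1L], d[2L])
  queue <- matrix(c(sr, sc), ncol = 2L)
  visited[sr, sc] <- TRUE
  pixels <- matrix(integer(0), ncol = 2L)
  while (nrow(queue) > 0L) {
    p <- queue[1L, , drop = TRUE]
    queue <- queue[-1L, , drop = FALSE]
    if (!accept[p[1L], p[2L]]) next
    pixels <- rbind(pixels, p)
    for (step in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      q <- p + step
      if (q[1L] < 1L || q[1L] > d[1L] || q[2L] < 1L || q[2L] > d[2L]) next
      if (visited[q[1L], q[2L]]) next
      if ((q[1L] - sr)^2 + (q[2L] - sc)^2 > radius_max^2) next
      visited[q[1L], q[2L]] <- TRUE
      queue <- rbind(queue, q)
    }
  }
  span <- (-radius_min):radius_min
  min_pixels <- sum(outer(span^2, span^2, "+") <= radius_min^2)
  if (nrow(pixels) < min_pixels) {
    abort(sprintf("Grown ROI has %d pixels, fewer than a radius-%d disk (%d).",
                  nrow(pixels), radius_min, min_pixels))
  }
  out <- tibble::tibble(row = as.integer(pixels[, 1L]),
                        col = as.integer(pixels[, 2L]))
  dplyr::arrange(out, .data$row, .data$col)
}

#' Grow several ROIs and enforce disjointness
#'
#' @param frame 2-D intensity matrix.
#' @param seeds Tibble/data frame with columns `roi_id`, `seed_row`,
#'   `seed_col` (1-based).
#' @param ... Passed to [grow_roi()].
#' @return ROI tibble: `roi_id`, `row`, `col`.  Overlapping ROIs are an
#'   error: within one recording every pixel belongs to at most one cell.
#' @export
grow_rois <- function(frame, seeds, ...) {
  rois <- purrr::map_dfr(seq_len(nrow(seeds)), function(i) {
    px <- grow_roi(frame, c(seeds$seed_row[i], seeds$seed_col[i]), ...)
    px$roi_id <- seeds$roi_id[i]
    px[, c("roi_id", "row", "col")]
  })
  assert_disjoint_rois(rois)
  rois
}

assert_disjoint_rois <- function(rois) {
  key <- paste(rois$row, rois$col)
  if (anyDuplicated(key)) {
    dup <- rois[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    abort(sprintf("ROIs overlap: %d pixel(s) shared between ROIs {%s}.",
                  sum(duplicated(key)),
                  paste(sort(unique(dup$roi_id)), collapse = ", ")))
  }
  invisible(rois)
}

#' Extract per-ROI fluorescence traces from a movie
#'
#' The raw trace of an ROI at frame `t` is the mean intensity over its
#' pixel set (mean, not sum, so the trace is invariant to ROI size and
#' commensurate across cells).
#'
#' @param movie A [ca_movie()] (ideally motion-corrected).
#' @param rois ROI tibble with columns `roi_id`, `row`, `col` (1-based),
#'   e.g. from [grow_rois()] or a simulation's ground truth.
#' @return Long trace tibble: `roi_id`, `frame`, `time_s`, `raw`, with a
#'   `frame_rate` attribute.
#' @examples
#' sim <- simulate_movie(synth_config(n_frames = 30, n_cells = 3,
#'                                    motion_max_shift = 0, seed = 6))
#' traces <- extract_traces(sim$movie, sim$rois)
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "ca_movie"))
  if (nrow(rois) == 0L) abort("Empty ROI table.")
  d <- dim(movie)
  if (any(rois$row < 1L | rois$row > d[1L] | rois$col < 1L | rois$col > d[2L])) {
    abort("ROI pixels outside the frame bounds.")
  }
  assert_disjoint_rois(rois)
  flat <- matrix(unclass(movie), nrow = d[1L] * d[2L], ncol = d[3L])
  t_s <- (seq_len(d[3L]) - 1) / frame_rate(movie)
  out <- purrr::map_dfr(split(rois, rois$roi_id), function(r) {
    idx <- r$row + (r$col - 1L) * d[1L]
    raw <- if (length(idx) == 1L) flat[idx, ] else colMeans(flat[idx, , drop = FALSE])
    tibble::tibble(roi_id = r$roi_id[1L], frame = seq_len(d[3L]),
                   time_s = t_s, raw = raw)
  })
  out <- dplyr::arrange(out, .data$roi_id, .data$frame)
  attr(out, "frame_rate") <- frame_rate(movie)
  out
}

#' ROI file I/O
#'
#' Seed lists travel as CSV with columns `roi_id,seed_row,seed_col`
#' (0-based in the file, converted to 1-based in memory); full ROI pixel
#' sets travel as a 16-bit label-image TIFF in which pixel value `k`
#' marks ROI `k` (0 = background).
#'
#' @param path File path.
#' @param rois ROI tibble (`roi_id`, `row`, `col`, 1-based).
#' @param height,width Label image size in pixels.
#' @return Readers return tibbles (1-based coordinates); writers return
#'   `path` invisibly.
#' @export
read_roi_seeds_csv <- function(path) {
  df <- utils::read.csv(path)
  tibble::tibble(roi_id = as.integer(df$roi_id),
                 seed_row = as.integer(df$seed_row) + 1L,
                 seed_col = as.integer(df$seed_col) + 1L)
}

#' @rdname read_roi_seeds_csv
#' @param seeds Seed tibble (`roi_id`, `seed_row`, `seed_col`, 1-based).
#' @export
write_roi_seeds_csv <- function(seeds, path) {
  out <- data.frame(roi_id = seeds$roi_id,
                    seed_row = seeds$seed_row - 1L,
                    seed_col = seeds$seed_col - 1L)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_roi_seeds_csv
#' @export
write_roi_mask_tiff <- function(rois, height, width, path) {
  mask <- matrix(0L, height, width)
  mask[cbind(rois$row, rois$col)] <- rois$roi_id
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname read_roi_seeds_csv
#' @export
read_roi_mask_tiff <- function(path) {
  mask <- round(tiff::readTIFF(path) * 65535)
  px <- which(mask > 0, arr.ind = TRUE)
  out <- tibble::tibble(roi_id = as.integer(mask[px]),
                        row = as.integer(px[, 1L]),
                        col = as.integer(px[, 2L]))
  dplyr::arrange(out, .data$roi_id, .data$row, .data$col)
}
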