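#' Estimate rigid frame shifts by cross-correlation
#'
#' Estimates, for every frame, the rigid displacement `(dy, dx)` of its
#' content relative to a reference image, as the argmax of the FFT-based
#' cross-correlation of the mean-subtracted images over all shifts with
#' `|dy|, |dx| <= max_shift`.  A frame whose content sits `(dy, dx)` away
#' from the reference gets shift `(dy, dx)`; [apply_shifts()] then
#' translates it back by the negated shift.
#'
#' @param movie A [ca_movie()].
#' @param reference `"mean"` (default; the pixelwise mean image, stabler
#'   than any single frame), `"first"`, or a frame index.
#' @param max_shift Maximum shift magnitude searched, pixels; must be
#'   smaller than half the frame size.
#' @param subpixel If `TRUE`, refine each integer shift by a parabolic fit
#'   through the correlation peak (3-point, per axis).
#' @return A tibble with one row per frame: `frame`, `dy`, `dx`, and
#'   `flagged` (`TRUE` for zero-variance frames, which get shift 0 with a
#'   warning).
#' @examples
#' sim <- simulate_movie(synth_config(n_frames = 20, n_cells = 4,
#'                                    motion_max_shift = 2, noise_sd = 0,
#'                                    seed = 5))
#' est <- estimate_shifts(sim$movie, max_shift = 4)
#' all(est$dy == sim$shifts$dy)
#' @export
estimate_shifts <- function(movie, reference = "mean", max_shift = 20L,
                            subpixel = FALSE) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie)
  if (d[3L] < 2L) abort("Shift estimation needs at least 2 frames.")
  if (max_shift >= min(d[1L], d[2L]) / 2) {
    abort("`max_shift` must be smaller than half the frame size.")
  }
  ref <- reference_image(movie, reference)
  if (sd(ref) == 0) {
    warn("Reference image has zero variance; all shifts set to (0, 0).")
    return(tibble::tibble(frame = seq_len(d[3L]), dy = 0, dx = 0,
                          flagged = TRUE))
  }
  ref0 <- ref - mean(ref)
  fref <- stats::fft(ref0)
  dy <- dx <- numeric(d[3L]); flagged <- logical(d[3L])
  any_flat <- FALSE
  for (t in seq_len(d[3L])) {
    fr <- movie[, , t]
    if (sd(fr) == 0) {
      flagged[t] <- TRUE; any_flat <- TRUE
      next
    }
    cc <- Re(stats::fft(stats::fft(fr - mean(fr)) * Conj(fref),
                        inverse = TRUE))
    s <- argmax_shift(cc, max_shift, subpixel)
    dy[t] <- s[1L]; dx[t] <- s[2L]
  }
  if (any_flat) warn("Zero-variance frame(s) encountered; their shift is (0, 0).")
  tibble::tibble(frame = seq_len(d[3L]), dy = dy, dx = dx, flagged = flagged)
}

reference_image <- function(movie, reference) {
  if (is.numeric(reference)) {
    return(get_frame(movie, as.integer(reference)))
  }
  switch(match.arg(reference, c("mean", "first")),
         mean = apply(unclass(movie), c(1L, 2L), mean),
         first = get_frame(movie, 1L))
}

# argmax of a circular correlation surface over |dy|,|dx| <= max_shift;
# ties broken toward the first candidate in row-major order (deterministic)
argmax_shift <- function(cc, max_shift, subpixel) {
  d <- dim(cc)
  offs <- (-max_shift):max_shift
  idx_row <- (offs %% d[1L]) + 1L
  idx_col <- (offs %% d[2L]) + 1L
  sub <- cc[idx_row, idx_col, drop = FALSE]
  best <- arrayInd(which.max(sub), dim(sub))
  dy <- offs[best[1L]]; dx <- offs[best[2L]]
  if (subpixel) {
    off_y <- parabolic_offset(cc_at(cc, dy - 1L, dx), cc_at(cc, dy, dx),
                              cc_at(cc, dy + 1L, dx))
    off_x <- parabolic_offset(cc_at(cc, dy, dx - 1L), cc_at(cc, dy, dx),
                              cc_at(cc, dy, dx + 1L))
    return(c(dy + off_y, dx + off_x))
  }
  c(dy, dx)
}

cc_at <- function(cc, dy, dx) {
  d <- dim(cc)
  cc[(dy %% d[1L]) + 1L, (dx %% d[2L]) + 1L]
}

parabolic_offset <- function(cm, c0, cp) {
  denom <- cm - 2 * c0 + cp
  if (denom == 0) return(0)
  off <- 0.5 * (cm - cp) / denom
  max(min(off, 0.5), -0.5)
}

#' Apply rigid shifts to a movie
#'
#' Translates every frame by the negation of its estimated shift, so a
#' frame whose content sat `(dy, dx)` away from the reference is moved
#' back on top of it.  Pixels translated in from outside the field of view
#' are filled with the constant 0 (wrapping would corrupt ROI traces).
#' Fractional shifts are applied by bilinear interpolation.
#'
#' @param movie A [ca_movie()].
#' @param shifts Tibble with columns `frame`, `dy`, `dx` (one row per
#'   frame), as returned by [estimate_shifts()].
#' @return A registered [ca_movie()].
#' @export
apply_shifts <- function(movie, shifts) {
  stopifnot(inherits(movie, "ca_movie"))
  if (nrow(shifts) != n_frames(movie)) {
    abort("`shifts` must have exactly one row per frame.")
  }
  out <- unclass(movie)
  for (t in seq_len(n_frames(movie))) {
    if (shifts$dy[t] != 0 || shifts$dx[t] != 0) {
      out[, , t] <- translate_frame(out[, , t], -shifts$dy[t], -shifts$dx[t],
                                    fill = 0)
    }
  }
  ca_movie(out, frame_rate(movie))
}

#' @rdname estimate_shifts
#' @param ... Passed to [estimate_shifts()].
#' @return `register_movie()` returns a list with the registered `movie`
#'   and the estimated `shifts`.
#' @export
register_movie <- function(movie, ...) {
  shifts <- estimate_shifts(movie, ...)
  list(movie = apply_shifts(movie, shifts), shifts = shifts)
}

# translate a matrix so content moves by (+dy, +dx); out(y, x) = in(y-dy, x-dx),
# constant fill outside the field; bilinear for fractional shifts
translate_frame <- function(fr, dy, dx, fill = 0) {
  d <- dim(fr)
  if (dy == round(dy) && dx == round(dx)) {
    dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
    out <- matrix(fill, d[1L], d[2L])
    src_rows <- seq_len(d[1L]) - dy
    src_cols <- seq_len(d[2L]) - dx
    ok_r <- src_rows >= 1L & src_rows <= d[1L]
    ok_c <- src_cols >= 1L & src_cols <= d[2L]
    out[ok_r, ok_c] <- fr[src_rows[ok_r], src_cols[ok_c]]
    return(out)
  }
  src_y <- seq_len(d[1L]) - dy
  src_x <- seq_len(d[2L]) - dx
  y0 <- floor(src_y); wy <- src_y - y0
  x0 <- floor(src_x); wx <- src_x - x0
  at <- function(rows, cols) {
    ok_r <- rows >= 1 & rows <= d[1L]
    ok_c <- cols >= 1 & cols <= d[2L]
    m <- matrix(fill, d[1L], d[2L])
    m[ok_r, ok_c] <- fr[rows[ok_r], cols[ok_c]]
    m
  }
  (1 - wy) %o% (1 - wx) * at(y0, x0) +
    (1 - wy) %o% wx       * at(y0, x0 + 1) +
    wy %o% (1 - wx)       * at(y0 + 1, x0) +
    wy %o% wx             * at(y0 + 1, x0 + 1)
}
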