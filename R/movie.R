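#' Movie container
#'
#' A `ca_movie` is an ordered stack of 2-D fluorescence frames with a frame
#' rate, stored as a numeric array with dimensions `height x width x
#' n_frames` (image row/column convention) and a `frame_rate` attribute in
#' Hz.  Pixel intensities are arbitrary fluorescence units.
#'
#' @param frames Numeric array `height x width x n_frames`, or a list of
#'   equally sized matrices (stacked in order).
#' @param frame_rate Acquisition rate in Hz (> 0).
#' @return A `ca_movie` object.
#' @examples
#' mov <- ca_movie(array(1, dim = c(8, 8, 5)), frame_rate = 30)
#' n_frames(mov)
#' @export
ca_movie <- function(frames, frame_rate) {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1L) {
      abort("All frames must have the same shape.")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(shapes[[1L]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a height x width x n_frames array or a list of matrices.")
  }
  if (dim(frames)[3L] < 1L) abort("A movie needs at least one frame.")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    abort("`frame_rate` must be a single positive number (Hz).")
  }
  structure(frames, frame_rate = as.numeric(frame_rate),
            class = c("ca_movie", "array"))
}

#' @rdname ca_movie
#' @param movie A `ca_movie`.
#' @export
n_frames <- function(movie) dim(movie)[3L]

#' @rdname ca_movie
#' @export
frame_rate <- function(movie) attr(movie, "frame_rate")

#' @rdname ca_movie
#' @param i Frame index.
#' @export
get_frame <- function(movie, i) {
  stopifnot(i >= 1L, i <= n_frames(movie))
  movie[, , i, drop = TRUE]
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ca_movie> %d x %d px, %d frames @ %.4g Hz (%.1f s)\n",
              d[1L], d[2L], d[3L], frame_rate(x), d[3L] / frame_rate(x)))
  invisible(x)
}

#' Read and write movies as multi-page TIFF
#'
#' Movies are stored as 16-bit multi-page grayscale TIFF.  Intensities are
#' rounded to the nearest integer on write and clipped to `[0, 65535]`;
#' `read_movie_tiff()` returns them on the original integer scale.  The
#' frame rate is not stored by the format and must be supplied on read.
#'
#' @param movie A [ca_movie()].
#' @param path File path.
#' @param frame_rate Frame rate in Hz for the movie being read.
#' @return `write_movie_tiff()` returns `path` invisibly;
#'   `read_movie_tiff()` returns a [ca_movie()].
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "ca_movie"))
  vals <- pmin(pmax(round(unclass(movie)), 0), 65535)
  pages <- lapply(seq_len(n_frames(movie)),
                  function(i) vals[, , i, drop = TRUE] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, frame_rate) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) round(p * 65535))
  ca_movie(pages, frame_rate = frame_rate)
}
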