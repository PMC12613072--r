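# Independent brute-force oracles used across the suite.  These deliberately
# re-derive each contract with naive scans rather than reusing package code.

# --- peak detection oracle ---------------------------------------------------
# Enumerate all local maxima (plateaus count once, centred, left-of-centre for
# even plateaus; endpoints excluded), apply the height then width filters,
# then greedy taller-first distance suppression (ties: earlier frame first).
oracle_find_peaks <- function(x, min_height, min_distance, min_width,
                              width_reference = "halfprom") {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L  # plateau [i, j]
    if (x[i] > x[i - 1L] && j < n && x[j + 1L] < x[i]) {
      cand <- c(cand, as.integer(floor((i + j) / 2)))
    }
    i <- j + 1L
  }
  cand <- cand[x[cand] >= min_height]
  rows <- list()
  for (p in cand) {
    # prominence: walk out to the nearest strictly higher sample on each side
    lb <- p
    while (lb > 1L && x[lb - 1L] <= x[p]) lb <- lb - 1L
    if (lb > 1L) lb <- lb - 1L else lb <- 1L
    left_min <- min(x[lb:p])
    rb <- p
    while (rb < n && x[rb + 1L] <= x[p]) rb <- rb + 1L
    if (rb < n) rb <- rb + 1L else rb <- n
    right_min <- min(x[p:rb])
    prom <- x[p] - max(left_min, right_min)
    ref <- if (width_reference == "halfprom") x[p] - prom / 2 else x[p] / 2
    left <- 1
    if (p > 1L) for (k in (p - 1L):1L) {
      if (x[k] < ref) { left <- k + (ref - x[k]) / (x[k + 1L] - x[k]); break }
    }
    right <- n
    if (p < n) for (k in (p + 1L):n) {
      if (x[k] < ref) { right <- k - (ref - x[k]) / (x[k - 1L] - x[k]); break }
    }
    wid <- right - left
    if (wid >= min_width) {
      rows[[length(rows) + 1L]] <- c(p, x[p], prom, wid)
    }
  }
  if (!length(rows)) {
    return(data.frame(peak_frame = integer(), height = numeric(),
                      prominence = numeric(), width_frames = numeric()))
  }
  m <- do.call(rbind, rows)
  # greedy suppression: repeatedly take the tallest remaining peak
  remaining <- seq_len(nrow(m))
  kept <- integer(0)
  while (length(remaining)) {
    hs <- m[remaining, 2L]
    fs <- m[remaining, 1L]
    pick <- remaining[order(-hs, fs)[1L]]
    kept <- c(kept, pick)
    remaining <- setdiff(remaining,
                         remaining[abs(m[remaining, 1L] - m[pick, 1L]) <
                                     min_distance])
  }
  kept <- kept[order(m[kept, 1L])]
  data.frame(peak_frame = as.integer(m[kept, 1L]), height = m[kept, 2L],
             prominence = m[kept, 3L], width_frames = m[kept, 4L])
}

# --- baseline oracle ---------------------------------------------------------
oracle_running_percentile <- function(x, window, p) {
  n <- length(x)
  hl <- (window - 1L) %/% 2L
  hr <- (window - 1L) - hl
  vapply(seq_len(n), function(i) {
    stats::quantile(x[max(1L, i - hl):min(n, i + hr)], p / 100,
                    type = 7, names = FALSE)
  }, numeric(1))
}

# --- random dF/F0-like traces for oracle-equivalence sweeps ------------------
# low-pass filtered noise plus sparse bumps, so the peak population spans the
# height/width/distance criteria from both sides
random_dff_trace <- function(n) {
  x <- stats::filter(rnorm(n, 0, 0.12), rep(1 / 7, 7), sides = 2)
  x[is.na(x)] <- 0
  n_bump <- rpois(1, 3)
  if (n_bump > 0) {
    for (b in seq_len(n_bump)) {
      centre <- sample(n, 1)
      sigma <- runif(1, 2, 20)
      amp <- runif(1, 0.1, 0.8)
      idx <- seq_len(n)
      x <- x + amp * exp(-((idx - centre)^2) / (2 * sigma^2))
    }
  }
  as.numeric(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# matched-smoothing processing parameters for synthetic-kinetics studies
synth_params <- function(frame_rate = 30) {
  processing_params(frame_rate, sg_width = 31)
}
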