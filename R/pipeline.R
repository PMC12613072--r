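#' Analyse one recording from traces
#'
#' Chains processing, event detection and classification on an extracted
#' trace table.
#'
#' @param traces Long trace tibble (`roi_id`, `frame`, `time_s`, `raw`).
#' @param proc_params A [processing_params()]; default: recording-scale
#'   parameters at the trace's frame rate.
#' @param peak_par A [peak_params()].
#' @param ... Passed to [classify_cells()].
#' @return A list of class `ca_analysis`: `traces` (with `smoothed`, `f0`,
#'   `dff`), `events`, `cells`.
#' @examples
#' rec <- simulate_recording(synth_config(n_cells = 3, seed = 10))
#' res <- analyze_recording(rec$traces,
#'                          processing_params(30, sg_width = 31))
#' res$cells
#' @export
analyze_recording <- function(traces,
                              proc_params = processing_params(trace_frame_rate(traces)),
                              peak_par = peak_params(), ...) {
  processed <- process_traces(traces, proc_params)
  events <- detect_events(processed, peak_par,
                          frame_rate = proc_params$frame_rate)
  cells <- classify_cells(processed, events,
                          frame_rate = proc_params$frame_rate, ...)
  structure(list(traces = processed, events = events, cells = cells),
            class = "ca_analysis")
}

#' @export
print.ca_analysis <- function(x, ...) {
  cat(sprintf("<ca_analysis> %d ROI(s), %d event(s), %d active cell(s)\n",
              nrow(x$cells), nrow(x$events), sum(x$cells$active)))
  invisible(x)
}

#' Analyse a movie end to end
#'
#' Registration (optional), ROI definition from seeds (or user-supplied
#' pixel sets), trace extraction, then [analyze_recording()].
#'
#' @param movie A [ca_movie()].
#' @param rois ROI tibble (`roi_id`, `row`, `col`), or `NULL` to grow ROIs
#'   from `seeds`.
#' @param seeds Seed tibble (`roi_id`, `seed_row`, `seed_col`) used when
#'   `rois` is `NULL`; ROIs are grown on the mean registered image.
#' @param register Run rigid motion correction first.
#' @param max_shift Registration search radius, pixels.
#' @param proc_params,peak_par See [analyze_recording()].
#' @param ... Passed to [grow_rois()].
#' @return A `ca_analysis` with extra elements `shifts` and `rois`.
#' @export
analyze_movie <- function(movie, rois = NULL, seeds = NULL, register = TRUE,
                          max_shift = 20L,
                          proc_params = processing_params(frame_rate(movie)),
                          peak_par = peak_params(), ...) {
  shifts <- NULL
  if (register) {
    reg <- register_movie(movie, max_shift = max_shift)
    movie <- reg$movie
    shifts <- reg$shifts
  }
  if (is.null(rois)) {
    if (is.null(seeds)) abort("Provide either `rois` or `seeds`.")
    mean_img <- apply(unclass(movie), c(1L, 2L), mean)
    rois <- grow_rois(mean_img, seeds, ...)
  }
  traces <- extract_traces(movie, rois)
  out <- analyze_recording(traces, proc_params, peak_par)
  out$shifts <- shifts
  out$rois <- rois
  out
}

#' Analyse a simulated or on-disk cohort
#'
#' Runs [analyze_recording()] on every organoid of a cohort and assembles
#' per-cell records and per-organoid summaries ready for
#' [compare_groups()].
#'
#' @param cohort A `ca_cohort` from [simulate_cohort()], or the path of a
#'   manifest CSV (`organoid_id,group,path,truth_path`) whose `path`
#'   column names wide trace CSVs.
#' @param proc_params A [processing_params()].
#' @param peak_par A [peak_params()].
#' @param ... Passed to [classify_cells()].
#' @return A list of class `ca_cohort_analysis`: `cells` (per-cell records
#'   with `organoid_id` and `group`), `summaries` (per-organoid, from
#'   [summarize_organoids()]).
#' @examples
#' design <- data.frame(organoid_id = c("a", "b", "c", "d"),
#'                      group = rep(c("NC", "MDS"), 2),
#'                      active_fraction = rep(c(0.3, 0.1), 2))
#' coh <- simulate_cohort(design, synth_config(n_cells = 6, seed = 11))
#' res <- analyze_cohort(coh, processing_params(30, sg_width = 31))
#' res$summaries
#' @export
analyze_cohort <- function(cohort,
                           proc_params = NULL,
                           peak_par = peak_params(), ...) {
  if (is.character(cohort)) {
    manifest <- tibble::as_tibble(utils::read.csv(cohort))
    base <- dirname(cohort)
    recordings <- lapply(seq_len(nrow(manifest)), function(i) {
      p <- manifest$path[i]
      if (!file.exists(p)) p <- file.path(base, basename(p))
      list(traces = read_traces_csv(p))
    })
    names(recordings) <- manifest$organoid_id
  } else {
    manifest <- cohort$manifest
    recordings <- cohort$recordings
  }
  cells_all <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    traces <- recordings[[i]]$traces
    pp <- proc_params %||% processing_params(trace_frame_rate(traces))
    res <- analyze_recording(traces, pp, peak_par, ...)
    res$cells$organoid_id <- manifest$organoid_id[i]
    res$cells$group <- manifest$group[i]
    res$cells
  })
  summaries <- summarize_organoids(cells_all)
  structure(list(cells = cells_all, summaries = summaries),
            class = "ca_cohort_analysis")
}

#' @export
print.ca_cohort_analysis <- function(x, ...) {
  cat(sprintf("<ca_cohort_analysis> %d organoids, %d cells (%d active)\n",
              nrow(x$summaries), nrow(x$cells), sum(x$cells$active)))
  invisible(x)
}
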