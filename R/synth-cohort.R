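#' Simulate a cohort of organoid recordings
#'
#' Simulates one recording per organoid and assembles a manifest, standing
#' in for a multi-organoid imaging study (e.g. a control line versus a
#' disease line).  Each row of `design` describes one organoid; columns
#' other than `organoid_id` and `group` override fields of `cfg` for that
#' organoid (most usefully `active_fraction`).  Per-organoid seeds are
#' derived as `cfg$seed + row index` unless a `seed` column is supplied, so
#' a cohort is fully reproducible from its design and base configuration.
#'
#' @param design A data frame with columns `organoid_id` (unique) and
#'   `group`, plus optional [synth_config()] field overrides.
#' @param cfg Base [synth_config()] shared by all organoids.
#' @param dir Optional output directory.  When given, each organoid's
#'   traces are written as a wide CSV (`frame`,`time_s`,`roi_1`,... with
#'   0-based `frame`), its ground truth as JSON, and the manifest as
#'   `manifest.csv` with columns `organoid_id,group,path,truth_path`.
#' @return A list of class `ca_cohort`: `manifest` (tibble `organoid_id`,
#'   `group`, `path`, `truth_path`; paths are `NA` when `dir` is `NULL`)
#'   and `recordings` (named list of [simulate_recording()] results).
#' @examples
#' design <- data.frame(organoid_id = c("o1", "o2"), group = "NC")
#' coh <- simulate_cohort(design, synth_config(n_frames = 300, n_cells = 4))
#' coh$manifest
#' @export
simulate_cohort <- function(design, cfg = synth_config(), dir = NULL) {
  design <- tibble::as_tibble(design)
  if (!all(c("organoid_id", "group") %in% names(design))) {
    abort("`design` needs columns `organoid_id` and `group`.")
  }
  if (anyDuplicated(design$organoid_id)) {
    abort("Duplicate organoid ids in `design`.")
  }
  override_cols <- setdiff(names(design), c("organoid_id", "group"))
  bad <- setdiff(override_cols, names(unclass(cfg)))
  if (length(bad)) {
    abort(paste0("Unknown synth_config fields in `design`: ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  recordings <- vector("list", nrow(design))
  names(recordings) <- as.character(design$organoid_id)
  paths <- truth_paths <- rep(NA_character_, nrow(design))
  for (i in seq_len(nrow(design))) {
    overrides <- as.list(design[i, override_cols, drop = FALSE])
    if (!("seed" %in% override_cols)) overrides$seed <- cfg$seed + i
    cfg_i <- do.call(synth_config_replace, c(list(cfg), overrides))
    rec <- simulate_recording(cfg_i)
    recordings[[i]] <- rec
    if (!is.null(dir)) {
      id <- design$organoid_id[i]
      paths[i] <- file.path(dir, paste0(id, "_traces.csv"))
      truth_paths[i] <- file.path(dir, paste0(id, "_truth.json"))
      write_traces_csv(rec$traces, paths[i])
      write_truth_json(rec$truth, truth_paths[i])
    }
  }
  manifest <- tibble::tibble(organoid_id = as.character(design$organoid_id),
                             group = as.character(design$group),
                             path = paths, truth_path = truth_paths)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  structure(list(manifest = manifest, recordings = recordings),
            class = "ca_cohort")
}

#' @export
print.ca_cohort <- function(x, ...) {
  cat(sprintf("<ca_cohort> %d organoids in %d group(s)\n",
              nrow(x$manifest), length(unique(x$manifest$group))))
  print(dplyr::count(x$manifest, .data$group))
  invisible(x)
}

#' Trace table I/O
#'
#' Traces travel as a wide CSV with columns `frame` (0-based in the file),
#' `time_s` and one `roi_<id>` column per cell; in memory they are long
#' tibbles (`roi_id`, `frame` 1-based, `time_s`, `raw`).
#'
#' @param traces Long trace tibble.
#' @param path File path.
#' @return `write_traces_csv()` returns `path` invisibly;
#'   `read_traces_csv()` returns a long trace tibble with a `frame_rate`
#'   attribute inferred from `time_s`.
#' @export
write_traces_csv <- function(traces, path) {
  wide <- tidyr::pivot_wider(traces[, c("roi_id", "frame", "time_s", "raw")],
                             names_from = "roi_id", values_from = "raw",
                             names_prefix = "roi_")
  wide$frame <- wide$frame - 1L   # 0-based on disk
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  wide <- utils::read.csv(path, check.names = FALSE)
  wide$frame <- wide$frame + 1L
  long <- tidyr::pivot_longer(tibble::as_tibble(wide),
                              cols = dplyr::starts_with("roi_"),
                              names_to = "roi_id", values_to = "raw",
                              names_prefix = "roi_")
  long$roi_id <- as.integer(long$roi_id)
  out <- dplyr::arrange(long, .data$roi_id, .data$frame)[,
           c("roi_id", "frame", "time_s", "raw")]
  if (nrow(out) > 1L && out$time_s[2L] > out$time_s[1L]) {
    attr(out, "frame_rate") <- 1 / (out$time_s[2L] - out$time_s[1L])
  }
  out
}

#' Ground-truth JSON I/O
#'
#' Serialises a ground-truth cell table (activity labels and event
#' schedules) so simulated cohorts on disk carry their oracle.
#'
#' @param truth Cell table from [simulate_truth()].
#' @param path File path.
#' @return `write_truth_json()` returns `path` invisibly;
#'   `read_truth_json()` returns the cell table.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(cells = lapply(seq_len(nrow(truth)), function(i) {
    list(roi_id = truth$roi_id[i],
         active = truth$active[i],
         event_times_s = truth$events[[i]]$time_s,
         event_amplitudes = truth$events[[i]]$amplitude)
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  cells <- payload$cells
  events <- lapply(cells, function(c) {
    tibble::tibble(time_s = as.numeric(unlist(c$event_times_s)),
                   amplitude = as.numeric(unlist(c$event_amplitudes)))
  })
  tibble::tibble(
    roi_id = vapply(cells, function(c) as.integer(c$roi_id), integer(1)),
    active = vapply(cells, function(c) as.logical(c$active), logical(1)),
    n_events = vapply(events, nrow, integer(1)),
    events = events
  )
}
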