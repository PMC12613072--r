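#' Compare groups of organoid summaries
#'
#' Group statistics in the design used for organoid cohorts: for the
#' active cell rate the statistical unit is the organoid; for event
#' frequency and amplitude it is the (active) cell, pooled across the
#' organoids of a group.  Two groups are compared with a two-tailed
#' Student's t test (equal variances); more than two groups with one-way
#' ANOVA followed by Dunnett's test against a named control (or Tukey's
#' all-pairs test).  Significance threshold 0.05 throughout.
#'
#' @param summaries Organoid summary tibble from [summarize_organoids()].
#' @param measure `"active_cell_rate"` (per organoid), `"frequency"` or
#'   `"amplitude"` (per cell).
#' @param design `"auto"` (t test for two groups, ANOVA + Dunnett
#'   otherwise), `"two-group"`, `"vs-control"` (Dunnett) or
#'   `"all-pairs"` (Tukey).
#' @param control Control group label, required for Dunnett.
#' @return A `ca_group_test` object; see [tidy.ca_group_test()] and
#'   [glance.ca_group_test()].
#' @examples
#' sums <- tibble::tibble(
#'   organoid_id = paste0("o", 1:8),
#'   group = rep(c("NC", "MDS"), each = 4),
#'   n_rois = 10, n_active = c(3, 2, 3, 4, 1, 0, 1, 1),
#'   active_cell_rate = 10 * c(3, 2, 3, 4, 1, 0, 1, 1),
#'   frequency = list(numeric(0)), amplitude = list(numeric(0))
#' )
#' compare_groups(sums)
#' @export
compare_groups <- function(summaries,
                           measure = c("active_cell_rate", "frequency",
                                       "amplitude"),
                           design = c("auto", "two-group", "vs-control",
                                      "all-pairs"),
                           control = NULL) {
  measure <- match.arg(measure)
  design <- match.arg(design)
  data <- measure_values(summaries, measure)
  groups <- unique(data$group)
  if (length(groups) < 2L) abort("Need at least 2 groups.")
  n_per <- table(data$group)
  if (any(n_per < 2L)) {
    abort(sprintf("Fewer than 2 units in group(s): %s.",
                  paste(names(n_per)[n_per < 2L], collapse = ", ")))
  }
  if (design == "auto") {
    design <- if (length(groups) == 2L) "two-group" else "vs-control"
  }
  if (design == "two-group" && length(groups) != 2L) {
    abort("`design = \"two-group\"` requires exactly 2 groups.")
  }

  group_stats <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")

  if (design == "two-group") {
    tt <- t.test(value ~ group, data = data, var.equal = TRUE)
    ord <- levels(factor(data$group))
    comparisons <- tibble::tibble(
      comparison = paste(ord[1L], "-", ord[2L]),
      estimate = unname(diff(rev(tt$estimate))),
      statistic = unname(tt$statistic),
      p.value = tt$p.value
    )
    fit <- tt
    overall_p <- tt$p.value
    method <- "Student's t (two-tailed, equal variances)"
  } else {
    data$group <- factor(data$group)
    if (design == "vs-control") {
      if (is.null(control)) abort("Dunnett comparisons need a `control` label.")
      if (!(control %in% levels(data$group))) {
        abort(sprintf("Control group '%s' not present.", control))
      }
      data$group <- stats::relevel(data$group, ref = control)
    }
    fit <- aov(value ~ group, data = data)
    mc_type <- if (design == "vs-control") "Dunnett" else "Tukey"
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(group = mc_type))
    sm <- summary(glht_fit)
    comparisons <- tibble::tibble(
      comparison = names(sm$test$coefficients),
      estimate = unname(sm$test$coefficients),
      statistic = unname(sm$test$tstat),
      p.value = unname(sm$test$pvalues)
    )
    overall_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    method <- sprintf("One-way ANOVA + %s", mc_type)
  }

  structure(list(measure = measure, design = design, method = method,
                 control = control, data = data, group_stats = group_stats,
                 comparisons = comparisons, overall_p = overall_p,
                 fit = fit),
            class = "ca_group_test")
}

measure_values <- function(summaries, measure) {
  if (measure == "active_cell_rate") {
    return(tibble::tibble(unit = as.character(summaries$organoid_id),
                          group = as.character(summaries$group),
                          value = summaries$active_cell_rate))
  }
  col <- if (measure == "frequency") "frequency" else "amplitude"
  out <- summaries |>
    dplyr::select("organoid_id", "group", dplyr::all_of(col)) |>
    tidyr::unnest(cols = dplyr::all_of(col))
  names(out)[names(out) == col] <- "value"
  out <- out[!is.na(out$value), , drop = FALSE]
  tibble::tibble(unit = paste0(out$organoid_id, "_cell", seq_len(nrow(out))),
                 group = as.character(out$group), value = out$value)
}

#' @export
print.ca_group_test <- function(x, ...) {
  cat(sprintf("<ca_group_test> %s on %s (%d units)\n", x$method, x$measure,
              nrow(x$data)))
  print(as.data.frame(x$group_stats), row.names = FALSE)
  print(as.data.frame(x$comparisons), row.names = FALSE)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `ca_group_test`.
#' @param ... Unused.
#' @return `tidy()`: one row per comparison (`comparison`, `estimate`,
#'   `statistic`, `p.value`, `significant` at 0.05).  `glance()`: one row
#'   with `measure`, `method`, `n_groups`, `n_units`, `p.value` (overall).
#' @export
tidy.ca_group_test <- function(x, ...) {
  out <- x$comparisons
  out$significant <- out$p.value < 0.05
  out
}

#' @rdname tidy.ca_group_test
#' @export
glance.ca_group_test <- function(x, ...) {
  tibble::tibble(measure = x$measure, method = x$method,
                 n_groups = nrow(x$group_stats), n_units = nrow(x$data),
                 p.value = x$overall_p)
}
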