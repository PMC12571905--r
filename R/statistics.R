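# Cohort event statistics: extrusion/shrink rates, HES incidence fractions
# and condition fold-changes with percentile-bootstrap intervals.

#' Summarise called events for one cohort
#'
#' Takes a per-cell roster (one row per filmed cell) carrying the event
#' class and the HES call, and computes the cohort's headline statistics:
#' extrusion rate per 1,000 (or 10,000) cells, the fraction of live-cell
#' extrusions preceded by HES, the analogous apoptotic fraction, the
#' overall shrink incidence and the count of cells that shrank without
#' extruding.  Percentile-bootstrap confidence intervals are computed by
#' resampling cells.
#'
#' Cells present in fewer than `coverage_min` of the filmed frames (per
#' their ROI `frame_first` / `frame_last`, when provided together with
#' `n_frames`) are excluded from denominators and reported as dropouts.
#'
#' @param cells data frame with one row per cell: `cell_id`, `event_class`
#'   (`"LCE"`, `"apoptotic_extrusion"`, `"division"`, `"none"`), logical
#'   `called_hes`; optional `frame_first`, `frame_last`.
#' @param condition cohort label.
#' @param n_boot bootstrap resamples (default 2,000).
#' @param seed bootstrap seed.
#' @param rate_per report extrusion rate per this many cells (1,000 or
#'   10,000).
#' @param conf confidence level.
#' @param n_frames movie length in frames (enables the coverage filter).
#' @param coverage_min minimum fraction of frames a cell must be present.
#' @return object of class `hes_cohort` with the point estimates, a `ci`
#'   data frame and the (filtered) `cells` roster.
#' @export
summarize_cohort <- function(cells, condition = "control", n_boot = 2000L,
                             seed = 1L, rate_per = 1000, conf = 0.95,
                             n_frames = NULL, coverage_min = 0.5) {
  stopifnot(nrow(cells) > 0, all(c("event_class", "called_hes") %in% names(cells)))
  n_dropout <- 0L
  if (!is.null(n_frames) && all(c("frame_first", "frame_last") %in% names(cells))) {
    cov <- (cells$frame_last - cells$frame_first + 1L) / n_frames
    n_dropout <- sum(cov < coverage_min)
    cells <- cells[cov >= coverage_min, , drop = FALSE]
  }
  est <- cohort_stats(cells, rate_per)

  ci <- NULL
  if (n_boot > 0L) {
    stats_mat <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        unlist(cohort_stats(cells[sample.int(nrow(cells), replace = TRUE), ,
                                  drop = FALSE], rate_per))
      }, unlist(est))
    })
    a <- (1 - conf) / 2
    ci <- data.frame(
      statistic = names(est),
      estimate = unlist(est),
      lower = apply(stats_mat, 1, quantile, probs = a, na.rm = TRUE, names = FALSE),
      upper = apply(stats_mat, 1, quantile, probs = 1 - a, na.rm = TRUE, names = FALSE),
      row.names = NULL
    )
  }

  structure(c(list(condition = condition, n_cells = nrow(cells),
                   n_dropout = n_dropout, rate_per = rate_per,
                   ci = ci, cells = cells, seed = seed),
              est),
            class = "hes_cohort")
}

# Point estimates for a cell roster.
cohort_stats <- function(cells, rate_per) {
  is_lce <- cells$event_class == "LCE"
  is_apo <- cells$event_class == "apoptotic_extrusion"
  n_ext <- sum(is_lce | is_apo)
  list(
    n_extrusions = n_ext,
    n_lce = sum(is_lce),
    n_apoptotic = sum(is_apo),
    extrusion_rate = rate_per * n_ext / nrow(cells),
    hes_fraction_lce = if (sum(is_lce) > 0) 100 * sum(cells$called_hes[is_lce]) / sum(is_lce) else NA_real_,
    hes_fraction_apoptotic = if (sum(is_apo) > 0) 100 * sum(cells$called_hes[is_apo]) / sum(is_apo) else NA_real_,
    shrink_incidence = 100 * sum(cells$called_hes) / nrow(cells),
    shrink_no_extrude_count = sum(cells$called_hes & !(is_lce | is_apo))
  )
}

#' @export
print.hes_cohort <- function(x, ...) {
  cat(sprintf("cohort '%s': %d cells (%d dropouts excluded)\n",
              x$condition, x$n_cells, x$n_dropout))
  cat(sprintf("  extrusions: %d (%d LCE, %d apoptotic); rate %.2f per %d cells\n",
              x$n_extrusions, x$n_lce, x$n_apoptotic, x$extrusion_rate, x$rate_per))
  cat(sprintf("  HES fraction: LCE %.1f%%, apoptotic %.1f%%; shrink incidence %.2f%%\n",
              x$hes_fraction_lce, x$hes_fraction_apoptotic, x$shrink_incidence))
  invisible(x)
}

#' Fold-change of a statistic between two cohorts
#'
#' Ratio of the named statistic, cohort `b` over cohort `a`, with a
#' percentile-bootstrap confidence interval obtained by resampling cells
#' independently within each cohort.
#'
#' @param summary_a,summary_b [summarize_cohort()] results (denominator
#'   first).
#' @param statistic statistic name (e.g. `"shrink_incidence"`,
#'   `"extrusion_rate"`).
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return list of class `hes_fold_change`: `statistic`, `ratio`, `ci`,
#'   `conditions`.
#' @export
fold_change <- function(summary_a, summary_b, statistic = "shrink_incidence",
                        n_boot = 2000L, seed = 1L, conf = 0.95) {
  va <- summary_a[[statistic]]
  vb <- summary_b[[statistic]]
  if (is.null(va) || is.null(vb)) stop("unknown statistic: ", statistic, call. = FALSE)
  if (!is.finite(va) || va == 0) {
    stop("statistic is zero (or undefined) in the denominator cohort; report raw counts instead",
         call. = FALSE)
  }
  ratios <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ra <- cohort_stats(summary_a$cells[sample.int(nrow(summary_a$cells), replace = TRUE), ,
                                         drop = FALSE], summary_a$rate_per)[[statistic]]
      rb <- cohort_stats(summary_b$cells[sample.int(nrow(summary_b$cells), replace = TRUE), ,
                                         drop = FALSE], summary_b$rate_per)[[statistic]]
      if (is.na(ra) || ra == 0) NA_real_ else rb / ra
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  structure(list(statistic = statistic, ratio = vb / va,
                 ci = quantile(ratios, c(a, 1 - a), na.rm = TRUE, names = FALSE),
                 conditions = c(summary_a$condition, summary_b$condition)),
            class = "hes_fold_change")
}

#' @export
print.hes_fold_change <- function(x, ...) {
  cat(sprintf("fold-change of %s (%s / %s): %.2f [%.2f, %.2f]\n",
              x$statistic, x$conditions[2], x$conditions[1],
              x$ratio, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Cohort report
#'
#' Builds a machine-readable summary table (one row per cohort), a
#' fold-change table for every cohort against the first, and a plain-text
#' rendering.  Regenerating the report from the same inputs and seed is
#' byte-identical.
#'
#' @param cohorts list of [summarize_cohort()] results; fold-changes are
#'   taken against the first cohort.
#' @param dir optional output directory for `cohort_summary.csv`,
#'   `fold_changes.csv` and `report.txt`.
#' @param statistic statistic used for fold-changes.
#' @param seed bootstrap seed for the fold-change intervals.
#' @return list with `summary`, `fold_changes` (data frames) and `text`.
#' @export
report <- function(cohorts, dir = NULL, statistic = "shrink_incidence",
                   seed = 1L) {
  stopifnot(length(cohorts) >= 1L)
  stat_names <- c("n_extrusions", "n_lce", "n_apoptotic", "extrusion_rate",
                  "hes_fraction_lce", "hes_fraction_apoptotic",
                  "shrink_incidence", "shrink_no_extrude_count")
  summary <- do.call(rbind, lapply(cohorts, function(co) {
    row <- data.frame(condition = co$condition, n_cells = co$n_cells,
                      n_dropout = co$n_dropout, rate_per = co$rate_per,
                      stringsAsFactors = FALSE)
    for (s in stat_names) row[[s]] <- co[[s]]
    row$config_hash <- text_hash(paste(co$condition, co$n_cells, co$seed))
    row$seed <- co$seed
    row
  }))

  fc <- data.frame(statistic = character(0), condition_num = character(0),
                   condition_den = character(0), ratio = numeric(0),
                   ci_lower = numeric(0), ci_upper = numeric(0))
  if (length(cohorts) > 1L) {
    base <- cohorts[[1]]
    ok <- is.finite(base[[statistic]]) && base[[statistic]] != 0
    if (ok) {
      fc <- do.call(rbind, lapply(cohorts[-1], function(co) {
        f <- fold_change(base, co, statistic, seed = seed)
        data.frame(statistic = statistic, condition_num = co$condition,
                   condition_den = base$condition, ratio = f$ratio,
                   ci_lower = f$ci[1], ci_upper = f$ci[2],
                   stringsAsFactors = FALSE)
      }))
    }
  }

  txt <- c("Cohort summary",
           paste(utils::capture.output(print(summary, row.names = FALSE)), collapse = "\n"),
           if (nrow(fc)) "Fold changes" else NULL,
           if (nrow(fc)) paste(utils::capture.output(print(fc, row.names = FALSE)), collapse = "\n") else NULL)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write.csv(summary, file.path(dir, "cohort_summary.csv"), row.names = FALSE)
    write.csv(fc, file.path(dir, "fold_changes.csv"), row.names = FALSE)
    writeLines(txt, file.path(dir, "report.txt"))
  }
  list(summary = summary, fold_changes = fc, text = txt)
}

# Small deterministic text hash (31-bit polynomial rolling hash) used to
# tag reports.
text_hash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
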