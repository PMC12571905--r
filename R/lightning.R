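# The lightning assay: junctional-brightness thresholding around cells,
# suprathreshold-area tracking, baseline normalisation and HES calling.

#' Crop the analysis window around a cell
#'
#' Extracts a `window_px` x `window_px` crop centred on the ROI centroid,
#' clipped at the image borders; the realised offset and extent are
#' recorded so the crop can be re-embedded exactly.
#'
#' @param stack an [hes_stack()] (`H x W x T`).
#' @param roi one row of a ROI table (needs `centroid_x`, `centroid_y`,
#'   0-based pixel coordinates).
#' @param params a [lightning_params()].
#' @return an [hes_stack()] crop with attributes `offset_x`, `offset_y`
#'   (0-based) recording its position in the parent image.
#' @export
crop_window <- function(stack, roi, params = lightning_params()) {
  d <- dim(stack)
  H <- d[1]; W <- d[2]
  cx <- roi$centroid_x; cy <- roi$centroid_y
  if (is.na(cx) || is.na(cy) || cx < 0 || cx >= W || cy < 0 || cy >= H) {
    stop("ROI centroid outside the image", call. = FALSE)
  }
  w <- params$window_px
  x0 <- max(0L, min(W - 1L, as.integer(round(cx - w / 2))))
  y0 <- max(0L, min(H - 1L, as.integer(round(cy - w / 2))))
  x1 <- min(W, x0 + w)
  y1 <- min(H, y0 + w)
  sub <- stack[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE]
  out <- hes_stack(sub, attr(stack, "pixel_size"), attr(stack, "frame_interval"),
                   channel = attr(stack, "channel"))
  attr(out, "offset_x") <- x0
  attr(out, "offset_y") <- y0
  out
}

#' Select the movie-wide intensity threshold
#'
#' The threshold is the `threshold_percentile`-th percentile (inverse
#' empirical CDF, i.e. the value an exhaustive sort would return) of the
#' pooled pixel intensities of the baseline frames.  A single scalar is
#' returned and reused for every frame of the movie.  A constant baseline
#' yields a threshold equal to that constant and is flagged degenerate
#' (downstream suprathreshold area is then zero under the strict-greater
#' rule).
#'
#' @param crop an [hes_stack()] (`H x W x T`).
#' @param baseline_frames integer vector of 1-based frame indices.
#' @param params a [lightning_params()].
#' @return scalar threshold with attribute `degenerate`.
#' @export
select_threshold <- function(crop, baseline_frames, params = lightning_params()) {
  stopifnot(length(baseline_frames) >= params$baseline_window)
  px <- as.numeric(crop[, , baseline_frames])
  thr <- percentile_type1(px, params$threshold_percentile)
  attr(thr, "degenerate") <- (max(px) == min(px))
  thr
}

#' Suprathreshold area per frame
#'
#' Counts pixels strictly above the threshold in each frame and converts to
#' um^2.  No morphological filtering is applied.
#'
#' @param crop an [hes_stack()] or `H x W x T` array.
#' @param threshold scalar intensity threshold.
#' @param pixel_size um per pixel (defaults to the stack calibration).
#' @param mask optional logical `H x W` matrix restricting the counted
#'   region (used to attribute junctional area to a focal cell).
#' @return numeric vector, um^2 per frame.
#' @export
measure_area_series <- function(crop, threshold, pixel_size = NULL, mask = NULL) {
  stopifnot(is.finite(threshold))
  pixel_size <- pixel_size %||% attr(crop, "pixel_size")
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  d <- dim(crop)
  Tn <- d[3]
  m <- matrix(as.numeric(crop), d[1] * d[2], Tn)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), d[1:2]))
    m <- m[as.vector(mask), , drop = FALSE]
  }
  colSums(m > threshold) * pixel_size^2
}

#' Normalise a series to its pre-event baseline
#'
#' Divides the series by the arithmetic mean of the baseline frames (the
#' `baseline_window` frames immediately preceding the event search span).
#' The mean of the normalised series over the baseline window is 1 to
#' within 1e-9 by construction.
#'
#' @param series numeric vector (area, intensity or volume per frame).
#' @param baseline_frames 1-based indices of the baseline frames.
#' @return normalised numeric vector with attributes `baseline_mean` and
#'   `baseline_frames`.
#' @export
normalize_series <- function(series, baseline_frames) {
  stopifnot(all(baseline_frames >= 1), all(baseline_frames <= length(series)))
  b <- mean(series[baseline_frames])
  if (!is.finite(b) || b <= 0) {
    stop("baseline mean must be positive (degenerate threshold?)", call. = FALSE)
  }
  out <- series / b
  attr(out, "baseline_mean") <- b
  attr(out, "baseline_frames") <- baseline_frames
  out
}

#' Detect a homeostatic-early-shrinkage event in a normalised trace
#'
#' Scans the event search span (frames after the baseline window, up to the
#' last frame before `t_extrusion` when an extrusion time is provided,
#' otherwise the full movie).  Shrink onset is the first frame of at least
#' `min_consecutive` consecutive frames at or above `1 + onset_delta`;
#' relaxation is the first later frame at or below `1 + relax_delta`.  When
#' the trace never relaxes before a known extrusion, the relaxation time is
#' truncated at `t_extrusion` and flagged.  `called_hes` is `TRUE` iff an
#' onset exists (before `t_extrusion` when provided).
#'
#' @param trace normalised trace from [normalize_series()].
#' @param params a [lightning_params()].
#' @param frame_interval minutes per frame.
#' @param t_extrusion extrusion time in minutes, or `NA`.
#' @param cell_id identifier copied into the result.
#' @return one-row data frame with `cell_id`, `threshold_value` (`NA` here;
#'   filled by [run_lightning()]), `peak_percent_change`,
#'   `t_shrink_onset_min`, `t_relaxation_min`, `t_extrusion_min`,
#'   `shrink_duration_min`, `called_hes`, `relax_truncated`.
#' @export
detect_hes <- function(trace, params = lightning_params(), frame_interval,
                       t_extrusion = NA_real_, cell_id = NA) {
  bl <- params$baseline_window
  Tn <- length(trace)
  if (Tn <= bl + params$min_consecutive) {
    stop("trace shorter than baseline window plus the onset run", call. = FALSE)
  }
  # search span: first frame after the baseline up to the frame before
  # extrusion (frame f, 0-based, has time f * frame_interval)
  f_end <- if (!is.na(t_extrusion)) {
    min(Tn, frame_at(t_extrusion, frame_interval) - 1L)
  } else Tn
  f_start <- bl + 1L

  onset_i <- NA_integer_
  if (f_end >= f_start + params$min_consecutive - 1L) {
    hi <- trace >= 1 + params$onset_delta
    run <- 0L
    for (f in f_start:f_end) {
      run <- if (hi[f]) run + 1L else 0L
      if (run == params$min_consecutive) {
        onset_i <- f - params$min_consecutive + 1L
        break
      }
    }
  }

  res <- data.frame(cell_id = cell_id, threshold_value = NA_real_,
                    peak_percent_change = NA_real_,
                    t_shrink_onset_min = NA_real_, t_relaxation_min = NA_real_,
                    t_extrusion_min = t_extrusion,
                    shrink_duration_min = NA_real_,
                    called_hes = FALSE, relax_truncated = FALSE,
                    stringsAsFactors = FALSE)

  if (is.na(onset_i)) {
    span <- f_start:max(f_start, f_end)
    res$peak_percent_change <- (max(trace[span]) - 1) * 100
    return(res)
  }

  res$called_hes <- TRUE
  res$t_shrink_onset_min <- (onset_i - 1L) * frame_interval

  relax_i <- NA_integer_
  if (f_end > onset_i) {
    lo <- which(trace[(onset_i + 1L):f_end] <= 1 + params$relax_delta)
    if (length(lo)) relax_i <- onset_i + lo[1]
  }
  if (is.na(relax_i)) {
    if (!is.na(t_extrusion)) {
      res$t_relaxation_min <- t_extrusion
      res$relax_truncated <- TRUE
    }
  } else {
    res$t_relaxation_min <- (relax_i - 1L) * frame_interval
  }
  if (!is.na(res$t_relaxation_min)) {
    res$shrink_duration_min <- res$t_relaxation_min - res$t_shrink_onset_min
  }
  peak_end <- if (!is.na(relax_i)) relax_i else f_end
  res$peak_percent_change <- (max(trace[onset_i:peak_end]) - 1) * 100
  res
}

#' Run the lightning assay over a dataset
#'
#' Computes, per cell, the junctional suprathreshold-area series, its
#' baseline-normalised trace and the HES call.  Two measurement modes are
#' provided:
#'
#' * `"partition"` (default for batch work): each pixel of the field is
#'   attributed to the nearest cell (the monolayer's Voronoi partition), a
#'   per-cell threshold is set from the cell's own baseline pixels, and the
#'   area series counts only that cell's pixels.  This keeps simultaneous
#'   events in neighbouring cells from contaminating each other's traces,
#'   which is what allows dense cohorts to be scored automatically.
#' * `"crop"`: the published single-cell protocol -- one `window_px` crop
#'   centred on the cell, one threshold from the pooled baseline pixels of
#'   the crop, area counted over the whole crop.  Appropriate when events
#'   are isolated, as in hand-picked ROI videos.
#'
#' The baseline is the first `baseline_window` frames of the movie; the
#' event search span runs from the following frame to the frame before the
#' cell's extrusion time when one is supplied (via `dataset$truth` or
#' `event_times`).
#'
#' @param dataset an `hes_dataset`, or an [hes_stack()] phase movie (then
#'   `rois` must be given and the partition is derived from ROI centroids).
#' @param params a [lightning_params()].
#' @param mode `"partition"` or `"crop"`.
#' @param rois ROI table when `dataset` is a bare stack.
#' @param event_times optional data frame (`cell_id`, `t_extrusion`)
#'   overriding the extrusion annotations taken from `dataset$truth`.
#' @param return_traces if `TRUE`, attach the per-cell normalised traces as
#'   attribute `traces`.
#' @return data frame with one row per ROI (see [detect_hes()] for
#'   columns).
#' @export
run_lightning <- function(dataset, params = lightning_params(),
                          mode = c("partition", "crop"),
                          rois = NULL, event_times = NULL,
                          return_traces = FALSE) {
  mode <- match.arg(mode)
  if (inherits(dataset, "hes_dataset")) {
    stack <- dataset$channels$phase
    if (is.null(stack)) stop("dataset has no phase channel", call. = FALSE)
    rois <- dataset$rois
    part <- dataset$partition
    if (is.null(event_times) && nrow(dataset$truth)) {
      event_times <- dataset$truth[, c("cell_id", "t_extrusion")]
    }
  } else {
    stack <- dataset
    if (is.null(rois)) stop("ROI table required when passing a bare stack", call. = FALSE)
    part <- partition_from_rois(dim(stack)[1:2], rois)
  }
  if (nrow(rois) == 0L) {
    out <- detect_hes(rep(1, params$baseline_window + params$min_consecutive + 1L),
                      params, 1)[0, ]
    return(out)
  }

  dt <- attr(stack, "frame_interval")
  px <- attr(stack, "pixel_size")
  bl_frames <- seq_len(params$baseline_window)
  ext_of <- function(id) {
    if (is.null(event_times)) return(NA_real_)
    i <- match(id, event_times$cell_id)
    if (is.na(i)) NA_real_ else event_times$t_extrusion[i]
  }

  results <- vector("list", nrow(rois))
  traces <- if (return_traces) vector("list", nrow(rois)) else NULL

  if (mode == "partition") {
    d <- dim(stack)
    Tn <- d[3]
    m <- matrix(as.numeric(stack), d[1] * d[2], Tn)
    pv <- as.vector(part)
    ids <- rois$cell_id
    idx_by_cell <- split(seq_along(pv), factor(pv, levels = ids))
    thr <- vapply(seq_along(ids), function(k) {
      percentile_type1(as.numeric(m[idx_by_cell[[k]], bl_frames]),
                       params$threshold_percentile)
    }, numeric(1))
    thr_px <- thr[match(pv, ids)]
    counts <- matrix(0, length(ids), Tn)
    fpv <- factor(pv, levels = ids)
    for (t in seq_len(Tn)) {
      ab <- m[, t] > thr_px
      counts[, t] <- tabulate(as.integer(fpv)[ab], nbins = length(ids))
    }
    areas <- counts * px^2
    for (k in seq_along(ids)) {
      tr <- normalize_series(areas[k, ], bl_frames)
      r <- detect_hes(tr, params, dt, t_extrusion = ext_of(ids[k]),
                      cell_id = ids[k])
      r$threshold_value <- thr[k]
      results[[k]] <- r
      if (return_traces) traces[[k]] <- tr
    }
  } else {
    for (k in seq_len(nrow(rois))) {
      roi <- rois[k, ]
      crop <- crop_window(stack, roi, params)
      thr <- select_threshold(crop, bl_frames, params)
      area <- measure_area_series(crop, thr, px)
      tr <- normalize_series(area, bl_frames)
      r <- detect_hes(tr, params, dt, t_extrusion = ext_of(roi$cell_id),
                      cell_id = roi$cell_id)
      r$threshold_value <- as.numeric(thr)
      results[[k]] <- r
      if (return_traces) traces[[k]] <- tr
    }
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  if (return_traces) {
    names(traces) <- rois$cell_id
    attr(out, "traces") <- traces
  }
  out
}

# Nearest-centroid partition of an image grid from a ROI table; used when
# the lightning assay is run on external data without a label map.
partition_from_rois <- function(dims, rois) {
  H <- dims[1]; W <- dims[2]
  px_x <- rep(seq_len(W) - 0.5, each = H)
  px_y <- rep(seq_len(H) - 0.5, times = W)
  best <- rep(Inf, H * W)
  part <- integer(H * W)
  for (k in seq_len(nrow(rois))) {
    d <- (px_x - rois$centroid_x[k])^2 + (px_y - rois$centroid_y[k])^2
    upd <- d < best
    best[upd] <- d[upd]
    part[upd] <- rois$cell_id[k]
  }
  matrix(part, H, W)
}

#' Write lightning results to CSV
#'
#' @param results data frame from [run_lightning()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lightning_results <- function(results, path) {
  write.csv(results[, c("cell_id", "threshold_value", "peak_percent_change",
                        "t_shrink_onset_min", "t_relaxation_min",
                        "t_extrusion_min", "shrink_duration_min", "called_hes")],
            path, row.names = FALSE)
  invisible(path)
}
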