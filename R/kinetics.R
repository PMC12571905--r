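# Per-cell fluorescence kinetics: ROI traces, baseline normalisation,
# directional onset detection and cross-channel lag estimation.

#' Mean-intensity trace of a ROI
#'
#' Per-frame mean pixel intensity inside the ROI bounding box.
#'
#' @param stack an [hes_stack()] (`H x W x T`).
#' @param roi one ROI row (`x_min`, `y_min`, `x_max`, `y_max`; 0-based,
#'   half-open).
#' @return numeric vector, one value per frame.
#' @export
extract_trace <- function(stack, roi) {
  d <- dim(stack)
  r0 <- roi$y_min + 1L; r1 <- roi$y_max
  c0 <- roi$x_min + 1L; c1 <- roi$x_max
  if (r1 < r0 || c1 < c0 || r0 < 1 || c0 < 1 || r1 > d[1] || c1 > d[2]) {
    stop("empty or out-of-bounds ROI", call. = FALSE)
  }
  apply(stack[r0:r1, c0:c1, , drop = FALSE], 3, mean)
}

#' Detect a directional onset in a normalised trace
#'
#' Scans frames after the baseline window for the first run of at least
#' `min_consecutive` consecutive frames at or beyond `1 + delta` (direction
#' `"up"`) or `1 - delta` (direction `"down"`).  Returns no onset when no
#' such run exists.
#'
#' @param trace normalised trace (see [normalize_series()]).
#' @param direction `"up"` or `"down"`.
#' @param delta fractional deviation from baseline defining the onset
#'   level.
#' @param min_consecutive consecutive frames required.
#' @param frame_interval minutes per frame.
#' @param baseline_window frames excluded from the search (default: the
#'   baseline recorded on the trace, else 10).
#' @param channel,cell_id identifiers copied into the result.
#' @param exclude_frames optional frame indices (e.g. user-marked medium
#'   changes) excluded from onset runs: a run may not span them.
#' @return one-row data frame: `cell_id`, `channel`, `direction`,
#'   `t_onset_min` (`NA` if none), `effect_size` (peak |normalised - 1|
#'   after the baseline).
#' @export
detect_onset <- function(trace, direction = c("up", "down"), delta = 0.10,
                         min_consecutive = 2L, frame_interval = 1,
                         baseline_window = NULL, channel = "",
                         cell_id = NA, exclude_frames = integer(0)) {
  direction <- match.arg(direction)
  bl <- baseline_window %||% {
    bf <- attr(trace, "baseline_frames")
    if (!is.null(bf)) max(bf) else 10L
  }
  Tn <- length(trace)
  if (Tn <= bl + min_consecutive) {
    stop("trace shorter than baseline window plus the onset run", call. = FALSE)
  }
  hit <- if (direction == "up") trace >= 1 + delta else trace <= 1 - delta
  hit[exclude_frames] <- FALSE
  onset_i <- NA_integer_
  run <- 0L
  for (f in (bl + 1L):Tn) {
    run <- if (hit[f]) run + 1L else 0L
    if (run == min_consecutive) { onset_i <- f - min_consecutive + 1L; break }
  }
  data.frame(cell_id = cell_id, channel = channel, direction = direction,
             t_onset_min = if (is.na(onset_i)) NA_real_ else (onset_i - 1L) * frame_interval,
             effect_size = max(abs(trace[(bl + 1L):Tn] - 1)),
             stringsAsFactors = FALSE)
}

#' Onset calls for every cell of a dataset channel
#'
#' Extracts per-cell mean-intensity traces over each cell's own pixel
#' region (the monolayer partition, so a neighbour's signal cannot bleed
#' into the trace as it would with bounding boxes in a confluent sheet),
#' normalises to the first `baseline_window` frames and runs
#' [detect_onset()] per cell.
#'
#' @param dataset an `hes_dataset`.
#' @param channel channel name.
#' @inheritParams detect_onset
#' @return data frame of onset calls, one row per ROI.
#' @export
channel_onsets <- function(dataset, channel, direction = "up", delta = 0.10,
                           min_consecutive = 2L, baseline_window = 10L) {
  stack <- dataset$channels[[channel]]
  if (is.null(stack)) stop("channel not rendered: ", channel, call. = FALSE)
  dt <- attr(stack, "frame_interval")
  d <- dim(stack)
  m <- matrix(as.numeric(stack), d[1] * d[2], d[3])
  ids <- dataset$rois$cell_id
  fpv <- factor(as.vector(dataset$partition), levels = ids)
  means <- rowsum(m, fpv) / as.vector(table(fpv))
  rows <- lapply(seq_along(ids), function(k) {
    tr <- normalize_series(means[k, ], seq_len(baseline_window))
    detect_onset(tr, direction, delta, min_consecutive, dt,
                 baseline_window, channel, ids[k])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lag between two sets of onset calls
#'
#' Per-cell lag `t_onset(b) - t_onset(a)` over cells with both onsets;
#' cells missing either onset are counted but not imputed.
#'
#' @param calls_a,calls_b onset-call data frames (earlier channel first).
#' @return list of class `hes_lag`: `channel_pair`, `lags` (per-cell,
#'   minutes), `mean_lag`, `sd_lag`, `n_cells`, `n_missing`.
#' @export
estimate_lag <- function(calls_a, calls_b) {
  m <- merge(calls_a[, c("cell_id", "t_onset_min")],
             calls_b[, c("cell_id", "t_onset_min")],
             by = "cell_id", suffixes = c("_a", "_b"))
  both <- m[!is.na(m$t_onset_min_a) & !is.na(m$t_onset_min_b), ]
  if (nrow(both) == 0L) {
    stop("no cells with onsets in both channels", call. = FALSE)
  }
  lags <- both$t_onset_min_b - both$t_onset_min_a
  structure(list(
    channel_pair = c(earlier = unique(calls_a$channel)[1],
                     later = unique(calls_b$channel)[1]),
    lags = lags,
    mean_lag = mean(lags),
    sd_lag = if (length(lags) > 1L) sd(lags) else NA_real_,
    n_cells = nrow(both),
    n_missing = nrow(m) - nrow(both)
  ), class = "hes_lag")
}

#' @export
print.hes_lag <- function(x, ...) {
  cat(sprintf("lag %s -> %s: %.2f min (sd %.2f, n = %d; %d cells lacked an onset)\n",
              x$channel_pair[1], x$channel_pair[2], x$mean_lag,
              x$sd_lag, x$n_cells, x$n_missing))
  invisible(x)
}

#' Normalise a trace to a single pre-crowding reference
#'
#' Divides the series by the value at one reference frame taken before
#' crowding (not by a baseline-window mean), as used for crowding
#' experiments where a single pre-crowding measurement anchors the scale.
#'
#' @param trace raw intensity series.
#' @param reference_frame 1-based index of the pre-crowding frame.
#' @return normalised numeric vector.
#' @export
normalize_to_precrowding <- function(trace, reference_frame = 1L) {
  stopifnot(reference_frame >= 1L, reference_frame <= length(trace))
  ref <- trace[reference_frame]
  if (!is.finite(ref) || ref <= 0) {
    stop("pre-crowding reference value must be positive", call. = FALSE)
  }
  trace / ref
}
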