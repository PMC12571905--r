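# Cell-volume quantification: 3-D reporter voxel counting, the Calcein
# quench proxy, percent-shrink scoring and the extrude/stay classifier.

#' Cell volume from a 3-D reporter z-stack
#'
#' Per frame, an Otsu threshold is computed from the voxels inside the
#' bounding box of the cell mask (after rescaling to the frame's intensity
#' range, so the split is invariant to positive rescaling), and the volume
#' is the count of in-mask voxels above that threshold times the voxel
#' volume.
#'
#' @param zstack an `H x W x Z x T` (or `H x W x Z` for a single frame)
#'   [hes_stack()] or array.
#' @param mask logical `H x W` footprint of the cell (applied to every
#'   frame), or an `H x W x T` array of per-frame masks.
#' @param voxel_dims c(dx, dy, dz) in um; defaults to the stack
#'   calibration.
#' @return numeric vector of um^3 per frame.
#' @export
volume_from_zstack <- function(zstack, mask, voxel_dims = NULL) {
  d <- dim(zstack)
  if (length(d) == 3L) { dim(zstack) <- c(d, 1L); d <- dim(zstack) }
  stopifnot(length(d) == 4L)
  if (is.null(voxel_dims)) {
    voxel_dims <- c(attr(zstack, "pixel_size"), attr(zstack, "pixel_size"),
                    attr(zstack, "z_step"))
  }
  stopifnot(length(voxel_dims) == 3L, all(voxel_dims > 0))
  per_frame_mask <- length(dim(mask)) == 3L
  if (!per_frame_mask) stopifnot(identical(dim(mask), d[1:2]))
  vox_vol <- prod(voxel_dims)

  vapply(seq_len(d[4]), function(t) {
    mk <- if (per_frame_mask) mask[, , t] else mask
    if (!any(mk)) stop("empty cell mask", call. = FALSE)
    rows <- range(which(rowSums(mk) > 0))
    cols <- range(which(colSums(mk) > 0))
    box <- zstack[rows[1]:rows[2], cols[1]:cols[2], , t]
    rng <- range(box)
    if (rng[1] == rng[2]) {
      stop("degenerate frame: constant intensity, empty segmentation", call. = FALSE)
    }
    thr01 <- EBImage::otsu(EBImage::Image((box - rng[1]) / (rng[2] - rng[1])))
    thr <- rng[1] + thr01 * (rng[2] - rng[1])
    inmask <- zstack[rows[1]:rows[2], cols[1]:cols[2], , t] > thr
    mk_box <- mk[rows[1]:rows[2], cols[1]:cols[2]]
    sum(inmask & array(mk_box, dim = dim(inmask))) * vox_vol
  }, numeric(1))
}

#' Calcein quench proxy for relative cell volume
#'
#' Calcein fluorescence is quenched as cells lose water; under an assumed
#' linear fluorescence-volume relation the baseline-normalised intensity
#' series is interpreted directly as relative volume.  Results are flagged
#' `method = "calcein_proxy"`.
#'
#' @param trace per-frame Calcein intensity of one cell.
#' @param baseline_frames 1-based indices of the pre-event baseline.
#' @return normalised numeric vector with attribute `method`.
#' @export
calcein_proxy <- function(trace, baseline_frames = seq_len(10L)) {
  out <- normalize_series(trace, baseline_frames)
  attr(out, "method") <- "calcein_proxy"
  out
}

#' Percent volume shrinkage
#'
#' `(1 - min(normalised volume over the event span)) x 100`, clipped at 0.
#'
#' @param trace normalised volume trace.
#' @param span 1-based frame indices of the event span (default: everything
#'   after the baseline window recorded on the trace, or the whole trace).
#' @return percent shrinkage (scalar, >= 0).
#' @export
percent_shrink <- function(trace, span = NULL) {
  if (is.null(span)) {
    bf <- attr(trace, "baseline_frames")
    span <- if (!is.null(bf)) seq.int(max(bf) + 1L, length(trace)) else seq_along(trace)
  }
  stopifnot(all(span >= 1), all(span <= length(trace)))
  max(0, (1 - min(trace[span])) * 100)
}

#' Classify extrude vs stay from percent shrinkage
#'
#' Strict-greater rule at the configured volume-loss threshold: a cell
#' shrinking more than `threshold` percent is predicted to extrude; exactly
#' `threshold` resolves to stay.
#'
#' @param percent_shrink numeric vector of percent volume losses.
#' @param threshold percent threshold (default 17).
#' @param cell_id optional identifiers.
#' @return data frame with `cell_id`, `percent_shrink`, `threshold`,
#'   `predicted_outcome` (`"extrude"` / `"stay"`).
#' @export
classify_outcome <- function(percent_shrink, threshold = 17,
                             cell_id = seq_along(percent_shrink)) {
  stopifnot(all(is.finite(percent_shrink)), is.finite(threshold))
  data.frame(cell_id = cell_id, percent_shrink = percent_shrink,
             threshold = threshold,
             predicted_outcome = ifelse(percent_shrink > threshold,
                                        "extrude", "stay"),
             stringsAsFactors = FALSE)
}

#' Per-cell volume traces from a 2-D reporter channel
#'
#' Integrates reporter (or Calcein) intensity over each cell's pixel region
#' per frame; since reporter fluorescence scales linearly with cell volume,
#' the baseline-normalised integral tracks relative volume.  The event span
#' for percent-shrink scoring is `[t_shrink_onset, t_extrusion)` taken from
#' supplied lightning results (detected onsets) or from the ground-truth
#' table, else everything after the baseline.
#'
#' @param dataset an `hes_dataset` containing the channel.
#' @param channel `"volume_reporter"` or `"calcein"`.
#' @param lightning optional [run_lightning()] results supplying per-cell
#'   event spans.
#' @param baseline_window frames defining normalised volume = 1.
#' @return data frame with `cell_id`, `percent_shrink`, `method`; the
#'   normalised traces are attached as attribute `traces`.
#' @export
reporter_volume_shrink <- function(dataset, channel = "volume_reporter",
                                   lightning = NULL, baseline_window = 10L) {
  stack <- dataset$channels[[channel]]
  if (is.null(stack)) stop("channel not rendered: ", channel, call. = FALSE)
  d <- dim(stack)
  Tn <- d[3]
  dt <- attr(stack, "frame_interval")
  m <- matrix(as.numeric(stack), d[1] * d[2], Tn)
  pv <- as.vector(dataset$partition)
  ids <- dataset$rois$cell_id
  fpv <- factor(pv, levels = ids)
  totals <- rowsum(m, fpv)                       # integrated intensity per cell
  bl <- seq_len(baseline_window)

  span_of <- function(id) {
    t_on <- t_ext <- NA_real_
    if (!is.null(lightning)) {
      i <- match(id, lightning$cell_id)
      if (!is.na(i)) {
        t_on <- lightning$t_shrink_onset_min[i]
        t_ext <- lightning$t_extrusion_min[i]
      }
    } else if (nrow(dataset$truth)) {
      i <- match(id, dataset$truth$cell_id)
      if (!is.na(i)) {
        t_on <- dataset$truth$t_shrink_onset[i]
        t_ext <- dataset$truth$t_extrusion[i]
      }
    }
    f0 <- if (!is.na(t_on)) frame_at(t_on, dt) else baseline_window + 1L
    f1 <- if (!is.na(t_ext)) frame_at(t_ext, dt) - 1L else Tn
    seq.int(max(1L, min(f0, Tn)), max(1L, min(f1, Tn)))
  }

  traces <- vector("list", length(ids))
  ps <- numeric(length(ids))
  for (k in seq_along(ids)) {
    tr <- normalize_series(totals[k, ], bl)
    traces[[k]] <- tr
    ps[k] <- percent_shrink(tr, span_of(ids[k]))
  }
  out <- data.frame(cell_id = ids, percent_shrink = ps,
                    method = if (channel == "calcein") "calcein_proxy" else "reporter_2d",
                    stringsAsFactors = FALSE)
  names(traces) <- ids
  attr(out, "traces") <- traces
  out
}
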