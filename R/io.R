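# Dataset and stack I/O.
#
# Stacks are written as multi-page TIFF (32-bit float samples, one page per
# frame, z fastest for z-resolved stacks) with the physical calibration and
# an intensity scale recorded in a JSON sidecar (metadata.json at dataset
# level, <file>.json for single stacks).  The tiff writer stores samples in
# [0, 1], so pixel values are divided by a fixed scale (65536) on write and
# multiplied back on read; values are exact to 32-bit float precision.

.intensity_scale <- 65536

#' Write / read a single image stack
#'
#' @param stack an [hes_stack()].
#' @param path output TIFF path; the calibration sidecar is written next to
#'   it as `<path>.json`.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [hes_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "hes_stack"))
  d <- dim(stack)
  zres <- length(d) == 4L
  H <- d[1]; W <- d[2]
  npage <- prod(d[-c(1, 2)])
  flat <- array(as.numeric(stack), dim = c(H, W, npage))
  offset <- min(0, floor(min(flat)))   # read noise can take pixels below 0
  pages <- lapply(seq_len(npage),
                  function(i) (flat[, , i] - offset) / .intensity_scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    axes = if (zres) "TZYX" else "TYX",
    size_y = H, size_x = W,
    size_z = if (zres) d[3] else 1L,
    size_t = d[length(d)],
    pixel_size_um = attr(stack, "pixel_size"),
    frame_interval_min = attr(stack, "frame_interval"),
    z_step_um = attr(stack, "z_step"),
    channel = attr(stack, "channel"),
    intensity_scale = .intensity_scale,
    intensity_offset = offset
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  off <- meta$intensity_offset %||% 0
  arr <- array(0, dim = c(meta$size_y, meta$size_x, length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * meta$intensity_scale + off
  if (meta$axes == "TZYX") {
    dim(arr) <- c(meta$size_y, meta$size_x, meta$size_z, meta$size_t)
  }
  hes_stack(arr, meta$pixel_size_um, meta$frame_interval_min,
            z_step = if (is.null(meta$z_step_um)) NA_real_ else meta$z_step_um,
            channel = meta$channel %||% "")
}

#' Write a synthetic dataset to a directory
#'
#' Writes one TIFF per channel, the label and partition maps, `rois.csv`,
#' `truth.csv` and `config.json`.  The file set round-trips losslessly (to
#' 32-bit float pixel precision) through [read_dataset()].
#'
#' @param dataset an `hes_dataset` from [simulate_dataset()] /
#'   [render_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "hes_dataset"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  }
  for (ch in names(dataset$channels)) {
    write_stack(dataset$channels[[ch]], file.path(dir, paste0(ch, ".tif")))
  }
  lab <- dataset$label
  write_stack(hes_stack(array(lab, dim = c(dim(lab), 1L)),
                        dataset$config$pixel_size, dataset$config$frame_interval,
                        channel = "label"),
              file.path(dir, "label.tif"))
  write_stack(hes_stack(array(dataset$partition, dim = c(dim(lab), 1L)),
                        dataset$config$pixel_size, dataset$config$frame_interval,
                        channel = "partition"),
              file.path(dir, "partition.tif"))
  write.csv(dataset$rois, file.path(dir, "rois.csv"), row.names = FALSE)
  write.csv(dataset$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write_config(dataset$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return an `hes_dataset`.
#' @export
read_dataset <- function(dir) {
  cfg <- read_config(file.path(dir, "config.json"))
  tifs <- list.files(dir, pattern = "\\.tif$", full.names = FALSE)
  chans <- setdiff(sub("\\.tif$", "", tifs), c("label", "partition"))
  channels <- lapply(chans, function(ch) read_stack(file.path(dir, paste0(ch, ".tif"))))
  names(channels) <- chans
  label <- read_stack(file.path(dir, "label.tif"))
  partition <- read_stack(file.path(dir, "partition.tif"))
  lab <- matrix(as.integer(round(label)), dim(label)[1], dim(label)[2])
  part <- matrix(as.integer(round(partition)), dim(partition)[1], dim(partition)[2])
  rois <- read.csv(file.path(dir, "rois.csv"))
  truth <- read.csv(file.path(dir, "truth.csv"))
  if (nrow(truth)) truth$event_class <- as.character(truth$event_class)
  structure(list(channels = channels, label = lab, partition = part,
                 junction = lab == 0L, rois = rois, truth = truth, config = cfg),
            class = "hes_dataset")
}
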