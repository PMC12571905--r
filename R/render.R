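#' Image stacks with physical calibration
#'
#' A thin S3 container for a single-channel time-lapse: a numeric array of
#' dimension `H x W x T` (or `H x W x Z x T` for z-resolved stacks) with
#' pixel size (um/px), frame interval (min/frame) and, where applicable,
#' z spacing (um) attached.
#'
#' @param data numeric array, `H x W x T` or `H x W x Z x T`.
#' @param pixel_size um per pixel.
#' @param frame_interval minutes per frame.
#' @param z_step um per z slice (`NA` for 2-D stacks).
#' @param channel channel name.
#' @return object of class `hes_stack`.
#' @export
hes_stack <- function(data, pixel_size, frame_interval, z_step = NA_real_,
                      channel = "") {
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L),
            pixel_size > 0, frame_interval > 0)
  structure(data, pixel_size = pixel_size, frame_interval = frame_interval,
            z_step = z_step, channel = channel,
            class = c("hes_stack", "array"))
}

#' @export
print.hes_stack <- function(x, ...) {
  d <- dim(x)
  cat("hes_stack '", attr(x, "channel"), "': ",
      paste(d, collapse = " x "),
      if (length(d) == 4L) " (H x W x Z x T)" else " (H x W x T)",
      ", ", attr(x, "pixel_size"), " um/px, ",
      attr(x, "frame_interval"), " min/frame\n", sep = "")
  invisible(x)
}

n_frames_of <- function(stack) {
  d <- dim(stack)
  d[length(d)]
}

# Rendering constants (intensity units before noise).  Phase: interiors sit
# at the background level, junction pixels carry a fixed spatially graded
# brightness spread wide enough that a percentile threshold cuts it where
# the intensity histogram is sparse (stable suprathreshold areas under shot
# noise).  The shrink halo and the extrusion flash sit above the junction
# range so they are suprathreshold for any baseline-derived threshold.
.render_const <- list(
  phase_bg = 100, junction_lo = 150, junction_hi = 600,
  ring_intensity = 600, flash_intensity = 600, division_intensity = 300,
  ring_full_loss = 35,      # percent volume loss that recruits the full halo band
  fluor_base = c(volume_reporter = 150, calcein = 150, dibac = 100,
                 corona = 100, atp = 100),
  dibac_step = 0.5, corona_step = 0.5, corona_crowd = 0.08, atp_drop = 0.45
)

.all_channels <- c("phase", "volume_reporter", "calcein", "dibac", "corona", "atp")

#' Render a synthetic multi-channel dataset
#'
#' Renders the movie implied by a monolayer geometry and a ground-truth
#' event table.  The phase channel shows a bright junction skeleton; while
#' a cell shrinks, a halo of bright pixels is recruited along the inside of
#' its boundary (the widening perijunctional gap), with the recruited area
#' proportional to the instantaneous fractional volume loss, so the
#' suprathreshold junctional area around the cell rises during
#' `[t_shrink_onset, t_relaxation]` in proportion to `true_vol_loss`.
#' Extruding cells flash bright at `t_extrusion` and vanish from the
#' fluorescence channels afterwards.  Volume-reporter and Calcein
#' intensities scale linearly with the instantaneous relative cell volume;
#' DiBAC steps up at `t_depol`; CoroNa rises slightly across the monolayer
#' at crowding and steps up at `t_na_entry` (remaining high only in
#' extruders); the ATP reporter declines from `t_atp_decline`.  Per-pixel
#' noise is shot noise (Gaussian approximation of Poisson counting at the
#' simulated photon budget, sd `sqrt(I / photon_gain)`) plus Gaussian read
#' noise.  The result is bit-reproducible for a fixed seed, and each
#' channel's noise depends only on the seed and the channel, not on which
#' other channels are rendered.
#'
#' @param config an [generator_config()].
#' @param mono a [build_monolayer()] result.
#' @param truth a [sample_events()] table.
#' @param channels channels to render (subset of `phase`,
#'   `volume_reporter`, `calcein`, `dibac`, `corona`, `atp`).
#' @return a list of class `hes_dataset`: `channels` (named list of
#'   [hes_stack()]), `label`, `partition`, `junction`, `rois`, `truth`,
#'   `config`.
#' @export
render_dataset <- function(config, mono, truth, channels = .all_channels) {
  stopifnot(inherits(config, "hes_config"), inherits(mono, "hes_monolayer"))
  channels <- match.arg(channels, .all_channels, several.ok = TRUE)
  need <- list(dibac = "t_depol", corona = "t_na_entry", atp = "t_atp_decline",
               volume_reporter = "t_shrink_onset", calcein = "t_shrink_onset")
  for (ch in channels) {
    if (!is.null(need[[ch]]) && !need[[ch]] %in% names(truth)) {
      stop(sprintf("channel '%s' requested but truth lacks column '%s'",
                   ch, need[[ch]]), call. = FALSE)
    }
  }

  H <- config$image_size[1]; W <- config$image_size[2]
  npx <- H * W
  Tn <- config$n_frames
  dt <- config$frame_interval

  geo <- mono$geometry %||% monolayer_geometry(mono, config)
  out <- vector("list", length(channels))
  names(out) <- channels
  for (ch in channels) {
    chan_seed <- config$seed + 2L + match(ch, .all_channels)
    arr <- with_seed(chan_seed, {
      m <- render_channel(ch, config, mono, truth, geo, npx, Tn, dt)
      add_noise(m, config$noise)
    })
    dim(arr) <- c(H, W, Tn)
    out[[ch]] <- hes_stack(arr, config$pixel_size, dt, channel = ch)
  }

  structure(list(channels = out, label = mono$label, partition = mono$partition,
                 junction = mono$junction, rois = mono$rois, truth = truth,
                 config = config),
            class = "hes_dataset")
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [build_monolayer()] + [sample_events()] +
#' [render_dataset()].
#'
#' @inheritParams render_dataset
#' @param config an [generator_config()].
#' @return an `hes_dataset`.
#' @export
simulate_dataset <- function(config, channels = .all_channels) {
  mono <- build_monolayer(config)
  truth <- sample_events(config, mono$rois)
  render_dataset(config, mono, truth, channels = channels)
}

#' @export
print.hes_dataset <- function(x, ...) {
  cat("hes_dataset:", nrow(x$rois), "cells,", x$config$n_frames, "frames,",
      "channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat("  events:", nrow(x$truth), "(",
      sum(x$truth$event_class == "LCE"), "LCE,",
      sum(x$truth$event_class == "apoptotic_extrusion"), "apoptotic,",
      sum(x$truth$event_class == "none"), "shrink-only,",
      sum(x$truth$event_class == "division"), "division )\n")
  invisible(x)
}

# Per-cell pixel geometry used by the renderer: linear indices of each
# cell's Voronoi region and interior, plus the interior boundary band
# (interior pixels within ~2 px of the junction), ordered outermost-first.
monolayer_geometry <- function(mono, config) {
  H <- nrow(mono$label); W <- ncol(mono$label)
  part <- as.vector(mono$partition)
  lab <- as.vector(mono$label)
  ids <- mono$rois$cell_id
  region_idx <- split(seq_len(H * W), factor(part, levels = ids))
  interior_idx <- split(which(lab > 0L), factor(lab[lab > 0L], levels = ids))

  # interior minus a 2-px erosion gives the boundary band
  kern <- matrix(1, 5, 5)
  band_idx <- vector("list", length(ids))
  rows <- arrayInd(seq_len(H * W), c(H, W))
  for (k in seq_along(ids)) {
    idx <- interior_idx[[k]]
    rc <- arrayInd(idx, c(H, W))
    r0 <- min(rc[, 1]); r1 <- max(rc[, 1]); c0 <- min(rc[, 2]); c1 <- max(rc[, 2])
    hh <- r1 - r0 + 1L; ww <- c1 - c0 + 1L
    m <- matrix(0L, hh, ww)
    m[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)] <- 1L
    er <- EBImage::erode(m, kern)
    band_local <- which(m == 1L & er == 0L)
    blc <- arrayInd(band_local, c(hh, ww))
    gr <- blc[, 1] + r0 - 1L; gc <- blc[, 2] + c0 - 1L
    gidx <- (gc - 1L) * H + gr
    cy <- mono$rois$centroid_y[k] + 0.5; cx <- mono$rois$centroid_x[k] + 0.5
    d2 <- (gr - cy)^2 + (gc - cx)^2
    band_idx[[k]] <- gidx[order(-d2, gidx)]
  }

  junction_which <- which(as.vector(mono$junction))
  list(ids = ids, region_idx = region_idx, interior_idx = interior_idx,
       band_idx = band_idx, junction_which = junction_which)
}

# frame index (1-based) of the first frame at or after time t (minutes)
frame_at <- function(t, dt) as.integer(ceiling(round(t / dt, 9))) + 1L

render_channel <- function(ch, config, mono, truth, geo, npx, Tn, dt) {
  if (ch == "phase") {
    render_phase(config, truth, geo, npx, Tn, dt)
  } else {
    render_fluor(ch, config, truth, geo, npx, Tn, dt)
  }
}

render_phase <- function(config, truth, geo, npx, Tn, dt) {
  cst <- .render_const
  base <- rep(cst$phase_bg, npx)
  # fixed spatial brightness texture of the junction skeleton
  base[geo$junction_which] <- cst$junction_lo +
    (cst$junction_hi - cst$junction_lo) * runif(length(geo$junction_which))

  m <- matrix(base, npx, Tn)

  for (j in seq_len(nrow(truth))) {
    ev <- truth[j, ]
    k <- match(ev$cell_id, geo$ids)
    if (isTRUE(ev$has_shrink)) {
      band <- geo$band_idx[[k]]
      peak <- min(length(band),
                  ceiling(ev$true_vol_loss / cst$ring_full_loss * length(band)))
      on_i <- frame_at(ev$t_shrink_onset, dt)
      end_i <- if (!is.na(ev$t_extrusion)) frame_at(ev$t_extrusion, dt) - 1L
               else frame_at(ev$t_relaxation, dt) - 1L
      if (peak > 0L && end_i >= on_i) {
        half <- ceiling(peak / 2)
        m[band[seq_len(half)], on_i] <- cst$ring_intensity
        if (end_i > on_i) {
          m[band[seq_len(peak)], seq.int(on_i + 1L, end_i)] <- cst$ring_intensity
        }
      }
    }
    if (!is.na(ev$t_extrusion)) {
      ext_i <- frame_at(ev$t_extrusion, dt)
      if (ext_i <= Tn) m[geo$interior_idx[[k]], ext_i] <- cst$flash_intensity
    }
    if (!is.na(ev$t_division)) {
      div_i <- frame_at(ev$t_division, dt)
      fr <- intersect(c(div_i, div_i + 1L), seq_len(Tn))
      if (length(fr)) m[geo$interior_idx[[k]], fr] <- cst$division_intensity
    }
  }
  m
}

# Piecewise-linear relative cell volume over frame times.
volume_profile <- function(ev, times, dt) {
  v <- rep(1, length(times))
  if (isTRUE(ev$has_shrink)) {
    loss <- ev$true_vol_loss / 100
    t_on <- ev$t_shrink_onset
    t_end <- if (!is.na(ev$t_extrusion)) ev$t_extrusion else ev$t_relaxation
    dur <- t_end - t_on
    fall <- min(2.5, dur / 2)
    t_trough <- t_on + fall
    falling <- times > t_on & times < t_trough
    v[falling] <- 1 - loss * (times[falling] - t_on) / fall
    if (is.na(ev$t_extrusion)) {
      rec <- min(2.5, dur / 3)
      t_rec <- ev$t_relaxation - rec
      hold <- times >= t_trough & times <= t_rec
      v[hold] <- 1 - loss
      rising <- times > t_rec & times < ev$t_relaxation
      v[rising] <- 1 - loss * (ev$t_relaxation - times[rising]) / rec
    } else {
      v[times >= t_trough & times <= ev$t_extrusion] <- 1 - loss
    }
  }
  if (!is.na(ev$t_extrusion)) {
    ext_i <- frame_at(ev$t_extrusion, dt)
    if (ext_i < length(times)) v[seq.int(ext_i + 1L, length(times))] <- 0
  }
  v
}

render_fluor <- function(ch, config, truth, geo, npx, Tn, dt) {
  cst <- .render_const
  base <- cst$fluor_base[[ch]]
  times <- (seq_len(Tn) - 1L) * dt
  settle <- 10L * dt

  # per-cell intensity profile, defaults to the channel baseline
  prof_default <- rep(base, Tn)
  if (ch == "corona") {
    prof_default <- base * (1 + cst$corona_crowd * (times >= settle))
  }

  m <- matrix(rep(prof_default, each = npx), npx, Tn)

  for (j in seq_len(nrow(truth))) {
    ev <- truth[j, ]
    k <- match(ev$cell_id, geo$ids)
    prof <- prof_default
    ext_i <- if (!is.na(ev$t_extrusion)) frame_at(ev$t_extrusion, dt) else NA_integer_

    if (ch %in% c("volume_reporter", "calcein")) {
      prof <- base * volume_profile(ev, times, dt)
    } else if (ch == "dibac") {
      if (!is.na(ev$t_depol)) {
        hi <- times >= ev$t_depol
        if (is.na(ev$t_extrusion)) hi <- hi & times < ev$t_relaxation
        prof <- base * (1 + cst$dibac_step * hi)
      }
    } else if (ch == "corona") {
      if (!is.na(ev$t_na_entry)) {
        hi <- times >= ev$t_na_entry
        if (is.na(ev$t_extrusion)) hi <- hi & times < ev$t_relaxation
        prof <- prof_default * (1 + cst$corona_step * hi)
      }
    } else if (ch == "atp") {
      if (!is.na(ev$t_atp_decline) && !is.na(ev$t_extrusion)) {
        frac <- pmin(1, pmax(0, (times - ev$t_atp_decline) /
                                  (ev$t_extrusion - ev$t_atp_decline)))
        prof <- base * (1 - cst$atp_drop * frac)
      }
    }

    if (!is.na(ext_i) && ext_i < Tn) prof[seq.int(ext_i + 1L, Tn)] <- 0
    if (!identical(prof, prof_default)) {
      m[geo$region_idx[[k]], ] <-
        matrix(rep(prof, each = length(geo$region_idx[[k]])),
               length(geo$region_idx[[k]]), Tn)
    }
  }
  m
}

add_noise <- function(m, noise) {
  g <- noise$photon_gain
  rs <- noise$read_sd
  shot_var <- if (is.finite(g)) m / g else 0
  sdv <- sqrt(shot_var + rs^2)
  if (all(sdv == 0)) return(m)
  m + sdv * rnorm(length(m))
}

#' Render a synthetic 3-D reporter z-stack for one cell
#'
#' Builds a noiseless (optionally noisy) confocal-style z-stack of a single
#' cell expressing a cytoplasmic volume reporter: an ellipsoid of bright
#' voxels over a dark background whose linear dimensions scale with the
#' cube root of the relative volume, so the bright-voxel count tracks the
#' prescribed volume.  Used to exercise 3-D volumetry.
#'
#' @param rel_volume numeric vector of relative volumes (1 = baseline), one
#'   per frame.
#' @param radius_um lateral cell radius at baseline (um).
#' @param height_um axial semi-height at baseline (um).
#' @param voxel voxel dimensions c(dx, dy, dz) in um.
#' @param intensity c(cell, background) intensity levels.
#' @param noise_sd additive Gaussian noise sd.
#' @param frame_interval minutes per frame.
#' @param seed RNG seed for the noise.
#' @return list with `stack` (an `H x W x Z x T` [hes_stack()]), `mask`
#'   (logical footprint), and `true_voxels` (bright-voxel count per frame).
#' @export
render_cell_zstack <- function(rel_volume, radius_um = 8, height_um = 4,
                               voxel = c(0.2125, 0.2125, 0.4),
                               intensity = c(200, 10), noise_sd = 0,
                               frame_interval = 0.5, seed = 1L) {
  rx <- radius_um / voxel[1]
  ry <- radius_um / voxel[2]
  rz <- height_um / voxel[3]
  H <- 2L * ceiling(ry) + 9L
  W <- 2L * ceiling(rx) + 9L
  Z <- 2L * ceiling(rz) + 5L
  cy <- (H + 1) / 2; cx <- (W + 1) / 2; cz <- (Z + 1) / 2

  gy <- rep(seq_len(H), times = W * Z)
  gx <- rep(rep(seq_len(W), each = H), times = Z)
  gz <- rep(seq_len(Z), each = H * W)

  Tn <- length(rel_volume)
  arr <- array(intensity[2], dim = c(H, W, Z, Tn))
  true_vox <- integer(Tn)
  for (t in seq_len(Tn)) {
    s <- rel_volume[t]^(1 / 3)
    inside <- ((gy - cy) / (ry * s))^2 + ((gx - cx) / (rx * s))^2 +
      ((gz - cz) / (rz * s))^2 <= 1
    slice <- array(intensity[2], dim = c(H, W, Z))
    slice[inside] <- intensity[1]
    arr[, , , t] <- slice
    true_vox[t] <- sum(inside)
  }
  if (noise_sd > 0) {
    arr <- with_seed(seed, arr + rnorm(length(arr), 0, noise_sd))
  }
  mask <- ((matrix(gy[seq_len(H * W)], H, W) - cy) / (ry * 1.05))^2 +
    ((matrix(gx[seq_len(H * W)], H, W) - cx) / (rx * 1.05))^2 <= 1
  list(stack = hes_stack(arr, voxel[1], frame_interval, z_step = voxel[3],
                         channel = "volume_reporter"),
       mask = mask, true_voxels = true_vox)
}
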