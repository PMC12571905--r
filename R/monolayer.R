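#' Build a confluent polygonal monolayer
#'
#' Generates a space-filling tessellation emulating a confluent epithelial
#' sheet: cell centres are placed by blue-noise (best-candidate) sampling,
#' every pixel is assigned to its nearest centre (a Voronoi partition), and
#' pixels whose 4-neighbourhood touches another cell form a 1-2 px
#' junction skeleton.  Deterministic for a fixed `config$seed`.
#'
#' @param config an [generator_config()] object.
#' @param max_retries number of regeneration attempts on degenerate
#'   geometry (coincident centres).
#' @return a list of class `hes_monolayer` with elements
#'   \describe{
#'     \item{label}{integer matrix (H x W); cell id per pixel, 0 on the
#'       junction skeleton.}
#'     \item{partition}{integer matrix; full nearest-centre partition with
#'       no junction pixels removed.  Used to attribute junctional signal
#'       to individual cells.}
#'     \item{junction}{logical matrix; the junction skeleton.}
#'     \item{rois}{data frame of per-cell bounding boxes and centroids
#'       (pixel units, 0-based, half-open intervals).}
#'     \item{seeds}{matrix of cell-centre coordinates.}
#'   }
#' @export
build_monolayer <- function(config, max_retries = 5L) {
  stopifnot(inherits(config, "hes_config"))
  H <- config$image_size[1]
  W <- config$image_size[2]
  n <- config$n_cells

  with_seed(config$seed, {
    for (attempt in seq_len(max_retries)) {
      seeds <- lloyd_relax(blue_noise_seeds(n, W, H), W, H)
      if (anyDuplicated(round(seeds, 6)) == 0L) break
      if (attempt == max_retries) {
        stop("degenerate monolayer geometry: coincident cell centres after ",
             max_retries, " attempts", call. = FALSE)
      }
    }

    # Nearest-centre assignment on the pixel grid (pixel centres at
    # 0-based coordinates c - 0.5, r - 0.5).
    px_x <- rep(seq_len(W) - 0.5, each = H)
    px_y <- rep(seq_len(H) - 0.5, times = W)
    best_d <- rep(Inf, H * W)
    part <- integer(H * W)
    for (i in seq_len(n)) {
      d <- (px_x - seeds[i, 1])^2 + (px_y - seeds[i, 2])^2
      upd <- d < best_d
      best_d[upd] <- d[upd]
      part[upd] <- i
    }
    partition <- matrix(part, H, W)

    junction <- neighbour_mismatch(partition)
    label <- partition
    label[junction] <- 0L

    rois <- rois_from_label(label, config)

    structure(list(label = label, partition = partition, junction = junction,
                   rois = rois, seeds = seeds),
              class = "hes_monolayer")
  })
}

# Best-candidate (Mitchell) blue-noise sampling: each new point is the
# candidate farthest from all existing points, giving near-uniform Voronoi
# cell areas.
blue_noise_seeds <- function(n, W, H, k = 24L) {
  pts <- matrix(NA_real_, n, 2)
  pts[1, ] <- c(runif(1, 0, W), runif(1, 0, H))
  for (i in seq_len(n)[-1]) {
    cand <- cbind(runif(k, 0, W), runif(k, 0, H))
    have <- pts[seq_len(i - 1L), , drop = FALSE]
    # min squared distance from each candidate to the existing set
    dmin <- vapply(seq_len(k), function(j) {
      min((have[, 1] - cand[j, 1])^2 + (have[, 2] - cand[j, 2])^2)
    }, numeric(1))
    pts[i, ] <- cand[which.max(dmin), ]
  }
  pts
}

# Lloyd relaxation towards a centroidal Voronoi tessellation -- the
# standard model of confluent epithelial packings -- run on a coarse grid
# for speed.  Keeps per-cell areas near-uniform, as in a mature monolayer.
lloyd_relax <- function(seeds, W, H, iters = 3L, step = 4) {
  gx <- seq(step / 2, W - step / 2, by = step)
  gy <- seq(step / 2, H - step / 2, by = step)
  px_x <- rep(gx, each = length(gy))
  px_y <- rep(gy, times = length(gx))
  n <- nrow(seeds)
  for (it in seq_len(iters)) {
    best <- rep(Inf, length(px_x))
    part <- integer(length(px_x))
    for (i in seq_len(n)) {
      d <- (px_x - seeds[i, 1])^2 + (px_y - seeds[i, 2])^2
      upd <- d < best
      best[upd] <- d[upd]
      part[upd] <- i
    }
    nx <- vapply(seq_len(n), function(i) mean(px_x[part == i]), numeric(1))
    ny <- vapply(seq_len(n), function(i) mean(px_y[part == i]), numeric(1))
    keep <- is.finite(nx) & is.finite(ny)
    seeds[keep, 1] <- nx[keep]
    seeds[keep, 2] <- ny[keep]
  }
  seeds
}

# Pixels whose 4-neighbourhood contains a different label.
neighbour_mismatch <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  dv <- m[-H, , drop = FALSE] != m[-1, , drop = FALSE]
  out[-H, ] <- out[-H, ] | dv
  out[-1, ] <- out[-1, ] | dv
  dh <- m[, -W, drop = FALSE] != m[, -1, drop = FALSE]
  out[, -W] <- out[, -W] | dh
  out[, -1] <- out[, -1] | dh
  out
}

rois_from_label <- function(label, config) {
  ids <- sort(unique(label[label > 0L]))
  H <- nrow(label)
  rows <- row(label); cols <- col(label)
  out <- lapply(ids, function(i) {
    sel <- label == i
    r <- rows[sel]; c <- cols[sel]
    data.frame(
      cell_id = i,
      frame_first = 0L,
      frame_last = config$n_frames - 1L,
      x_min = min(c) - 1L, y_min = min(r) - 1L,
      x_max = max(c), y_max = max(r),
      centroid_x = mean(c) - 0.5, centroid_y = mean(r) - 0.5
    )
  })
  do.call(rbind, out)
}

#' @export
print.hes_monolayer <- function(x, ...) {
  cat("hes_monolayer:", nrow(x$rois), "cells on a",
      paste(dim(x$label), collapse = "x"), "px grid;",
      sum(x$junction), "junction px\n")
  invisible(x)
}
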