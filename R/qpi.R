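# Quantitative-phase-imaging dry mass: background correction, phase-to-mass
# conversion and trend classification of mass trajectories.

#' Dry-mass conversion parameters
#'
#' @param wavelength illumination wavelength in um (default 0.623, red
#'   LED).
#' @param alpha specific refractive increment in um^3/pg (default 0.185,
#'   equivalent to 0.185 mL/g, the standard value for cellular dry matter).
#' @param pixel_area pixel area in um^2.
#' @return list of class `hes_qpi_params`.
#' @export
dry_mass_params <- function(wavelength = 0.623, alpha = 0.185, pixel_area) {
  stopifnot(wavelength > 0, alpha > 0, pixel_area > 0)
  structure(list(wavelength = wavelength, alpha = alpha,
                 pixel_area = pixel_area),
            class = "hes_qpi_params")
}

#' Background-correct a phase map
#'
#' Subtracts the mean phase shift of the empty (cell-free) region from the
#' whole field of view.
#'
#' @param phase numeric matrix of phase shifts (radians).
#' @param empty_mask logical matrix marking empty space.
#' @return corrected phase matrix.
#' @export
background_correct <- function(phase, empty_mask) {
  stopifnot(identical(dim(phase), dim(empty_mask)))
  if (!any(empty_mask)) stop("empty-space mask has no pixels", call. = FALSE)
  phase - mean(phase[empty_mask])
}

#' Convert a background-corrected phase map to dry mass
#'
#' Optical path difference per pixel is `phi * lambda / (2 pi)`; dry mass
#' is the OPD integral over the region divided by the specific refractive
#' increment: `mass = lambda / (2 pi alpha) * sum(phi) * pixel_area`,
#' in picograms for `lambda`, `alpha`, `pixel_area` in um, um^3/pg, um^2.
#'
#' @param phase background-corrected phase matrix (radians).
#' @param mask logical matrix selecting the cell or island region.
#' @param params a [dry_mass_params()].
#' @return dry mass in pg (scalar).
#' @export
phase_to_mass <- function(phase, mask, params) {
  stopifnot(inherits(params, "hes_qpi_params"),
            identical(dim(phase), dim(mask)))
  params$wavelength / (2 * pi * params$alpha) *
    sum(phase[mask]) * params$pixel_area
}

#' Dry-mass trajectory of a region
#'
#' Applies [background_correct()] and [phase_to_mass()] per frame.
#'
#' @param stack phase stack (`H x W x T`, radians).
#' @param mask logical region mask (`H x W`).
#' @param empty_mask logical empty-space mask.
#' @param params a [dry_mass_params()].
#' @return numeric vector of pg per frame.
#' @export
dry_mass_trace <- function(stack, mask, empty_mask, params) {
  d <- dim(stack)
  vapply(seq_len(d[3]), function(t) {
    phase_to_mass(background_correct(stack[, , t], empty_mask), mask, params)
  }, numeric(1))
}

#' Classify a dry-mass trend
#'
#' Least-squares slope over a trailing window; `increasing` if the slope
#' exceeds `+ flat_tolerance x mean mass` per hour, `decreasing` below the
#' negative of that, else `flat`.  Dry mass stays flat before extrusion and
#' rises before division, so this separates the two fates.
#'
#' @param mass_series pg per frame.
#' @param window number of trailing frames (>= 3) used for the fit.
#' @param flat_tolerance fractional mass change per hour bounding "flat"
#'   (default 0.05).
#' @param frame_interval minutes per frame.
#' @return list of class `hes_trend`: `slope` (pg/h), `trend_class`,
#'   `window`, `mean_mass`.
#' @export
classify_trend <- function(mass_series, window = NULL, flat_tolerance = 0.05,
                           frame_interval = 2) {
  n <- length(mass_series)
  window <- window %||% n
  if (window < 3L || window > n) {
    stop("trend window must span 3 to length(mass_series) frames", call. = FALSE)
  }
  idx <- seq.int(n - window + 1L, n)
  t_h <- (idx - 1L) * frame_interval / 60
  fit <- lm(mass_series[idx] ~ t_h)
  slope <- unname(coef(fit)[2])
  mu <- mean(mass_series[idx])
  lim <- flat_tolerance * mu
  cls <- if (slope > lim) "increasing" else if (slope < -lim) "decreasing" else "flat"
  structure(list(slope = slope, trend_class = cls, window = window,
                 mean_mass = mu),
            class = "hes_trend")
}

#' Simulate dry-mass trajectories for extruding and dividing cells
#'
#' Synthetic per-cell mass series: flat (pre-extrusion) or linearly ramped
#' (pre-division, default +8 %/h) around a baseline mass, with Gaussian
#' noise.  Used to benchmark [classify_trend()].
#'
#' @param n number of cells.
#' @param kind `"pre_extrusion"` (flat) or `"pre_division"` (ramped).
#' @param n_frames,frame_interval series length and spacing (min).
#' @param base_mass baseline mass in pg.
#' @param growth_per_h fractional mass growth per hour for dividing cells.
#' @param noise_sd Gaussian noise sd in pg.
#' @param seed RNG seed.
#' @return matrix `n x n_frames` of pg values.
#' @export
simulate_mass_traces <- function(n, kind = c("pre_extrusion", "pre_division"),
                                 n_frames = 90L, frame_interval = 2,
                                 base_mass = 250, growth_per_h = 0.08,
                                 noise_sd = 3, seed = 1L) {
  kind <- match.arg(kind)
  t_h <- (seq_len(n_frames) - 1L) * frame_interval / 60
  with_seed(seed, {
    base <- rnorm(n, base_mass, base_mass * 0.1)
    slope <- if (kind == "pre_division") base * growth_per_h else rep(0, n)
    sweep(outer(slope, t_h), 1, base, "+") +
      matrix(rnorm(n * n_frames, 0, noise_sd), n, n_frames)
  })
}
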