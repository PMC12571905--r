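#' Sample ground-truth events for a synthetic monolayer
#'
#' Draws the event roster that the renderer and the analysis pipeline are
#' validated against.  Extruding cells are drawn at the configured
#' extrusion rate; each live-cell extrusion (LCE) is preceded by
#' homeostatic early shrinkage (HES) with probability `p_hes_given_lce`
#' and each apoptotic extrusion with probability
#' `p_shrink_given_apoptotic`.  For shrinking cells the signalling chain is
#' laid out backwards from extrusion: shrink onset precedes extrusion by
#' the shrink duration, depolarisation precedes shrink onset, sodium entry
#' precedes depolarisation and ATP decline precedes sodium entry, each lag
#' drawn from a zero-truncated Gaussian (sd = `jitter_frac` x mean).
#' Volume losses are drawn from the extruder or the non-extruder
#' distribution.  Cells may also shrink without extruding
#' (`p_shrink_no_extrude`, scaled under drug conditions so that the total
#' shrink incidence is `shrink` times the untreated incidence) or divide.
#'
#' Events whose sampled chain cannot fit into the movie span are dropped
#' and recorded in the `dropped` attribute of the result.
#'
#' @param config an [generator_config()] object.
#' @param rois ROI table from [build_monolayer()].
#' @return data frame of ground-truth events, one row per cell *with* an
#'   event: columns `cell_id`, `event_class` (`LCE`,
#'   `apoptotic_extrusion`, `division`, `none` for shrink-without-extrusion),
#'   `has_shrink`, the event times in minutes (`t_atp_decline`,
#'   `t_na_entry`, `t_depol`, `t_shrink_onset`, `t_relaxation`,
#'   `t_extrusion`, `t_division`; `NA` where inapplicable) and
#'   `true_vol_loss` (percent).
#' @export
sample_events <- function(config, rois) {
  stopifnot(inherits(config, "hes_config"))
  with_seed(config$seed + 1L, sample_events_impl(config, rois))
}

sample_events_impl <- function(config, rois) {
  dt <- config$frame_interval
  movie_min <- (config$n_frames - 1L) * dt
  dur_h <- config$n_frames * dt / 60

  mult <- config$condition_multipliers[[config$condition]]
  p_ext_base <- min(1, config$extrusion_rate / 1000 * dur_h)
  p_ext <- min(1, p_ext_base * mult$extrusion)
  shrink_frac_ext <- (1 - config$apoptotic_fraction) * config$p_hes_given_lce +
    config$apoptotic_fraction * config$p_shrink_given_apoptotic
  s_untreated <- p_ext_base * shrink_frac_ext + config$p_shrink_no_extrude
  s_target <- mult$shrink * s_untreated
  p_sne <- s_target - p_ext * shrink_frac_ext
  if (p_sne < 0) p_sne <- 0
  if (p_ext + p_sne > 1) {
    stop(sprintf(paste0("condition '%s' requires total shrink incidence %.2f ",
                        "which cannot fit a monolayer; reduce extrusion_rate ",
                        "or the shrink multiplier"),
                 config$condition, s_target), call. = FALSE)
  }

  # Earliest allowed signal time: a 10-frame settling period so that every
  # analysis baseline precedes the first event.
  settle <- 10L * dt
  min_span <- settle +
    config$shrink_duration_mean + config$lag_depol_to_shrink +
    config$lag_na_to_depol + config$lag_atp_to_na + 3 * dt
  if (movie_min < min_span && (p_ext > 0 || p_sne > 0)) {
    stop(sprintf("movie too short for the full event chain: %.1f min filmed, at least %.1f min required",
                 movie_min, min_span), call. = FALSE)
  }

  n <- nrow(rois)
  u <- runif(n)
  is_ext <- u < p_ext
  is_sne <- !is_ext & u < p_ext + p_sne
  is_div <- !is_ext & !is_sne & (runif(n) < config$p_division)

  rows <- list()
  dropped <- 0L

  blank <- function(cell_id, class) {
    data.frame(cell_id = cell_id, event_class = class, has_shrink = FALSE,
               t_atp_decline = NA_real_, t_na_entry = NA_real_,
               t_depol = NA_real_, t_shrink_onset = NA_real_,
               t_relaxation = NA_real_, t_extrusion = NA_real_,
               t_division = NA_real_, true_vol_loss = NA_real_,
               stringsAsFactors = FALSE)
  }

  for (i in which(is_ext)) {
    apo <- runif(1) < config$apoptotic_fraction
    class <- if (apo) "apoptotic_extrusion" else "LCE"
    p_shr <- if (apo) config$p_shrink_given_apoptotic else config$p_hes_given_lce
    shrink <- runif(1) < p_shr
    r <- blank(rois$cell_id[i], class)
    r$has_shrink <- shrink
    if (shrink) {
      dur <- rtrunc_norm(1, config$shrink_duration_mean, config$shrink_duration_sd,
                         lower = 2 * dt)
      l1 <- rtrunc_norm(1, config$lag_depol_to_shrink,
                        config$jitter_frac * config$lag_depol_to_shrink)
      l2 <- rtrunc_norm(1, config$lag_na_to_depol,
                        config$jitter_frac * config$lag_na_to_depol)
      l3 <- rtrunc_norm(1, config$lag_atp_to_na,
                        config$jitter_frac * config$lag_atp_to_na)
      lo <- settle + dur + l1 + l2 + l3 + dt
      hi <- movie_min - 2 * dt
      if (lo >= hi) { dropped <- dropped + 1L; next }
      t_ext <- runif(1, lo, hi)
      r$t_extrusion <- t_ext
      r$t_shrink_onset <- t_ext - dur
      r$t_relaxation <- t_ext
      r$t_depol <- r$t_shrink_onset - l1
      r$t_na_entry <- r$t_depol - l2
      r$t_atp_decline <- r$t_na_entry - l3
      r$true_vol_loss <- rtrunc_norm(1, config$vol_loss_extrude_mean,
                                     config$vol_loss_extrude_sd)
    } else {
      r$t_extrusion <- runif(1, settle + dt, movie_min - 2 * dt)
      r$true_vol_loss <- 0
    }
    rows[[length(rows) + 1L]] <- r
  }

  for (i in which(is_sne)) {
    r <- blank(rois$cell_id[i], "none")
    r$has_shrink <- TRUE
    dur <- rtrunc_norm(1, config$shrink_duration_mean, config$shrink_duration_sd,
                       lower = 2 * dt)
    l1 <- rtrunc_norm(1, config$lag_depol_to_shrink,
                      config$jitter_frac * config$lag_depol_to_shrink)
    l2 <- rtrunc_norm(1, config$lag_na_to_depol,
                      config$jitter_frac * config$lag_na_to_depol)
    lo <- settle + l1 + l2 + dt
    hi <- movie_min - dur - 2 * dt
    if (lo >= hi) { dropped <- dropped + 1L; next }
    t_on <- runif(1, lo, hi)
    r$t_shrink_onset <- t_on
    r$t_relaxation <- t_on + dur
    r$t_depol <- t_on - l1
    r$t_na_entry <- r$t_depol - l2
    r$true_vol_loss <- rtrunc_norm(1, config$vol_loss_stay_mean,
                                   config$vol_loss_stay_sd)
    rows[[length(rows) + 1L]] <- r
  }

  for (i in which(is_div)) {
    if (settle + dt >= movie_min - 2 * dt) { dropped <- dropped + 1L; next }
    r <- blank(rois$cell_id[i], "division")
    r$t_division <- runif(1, settle + dt, movie_min - 2 * dt)
    rows[[length(rows) + 1L]] <- r
  }

  truth <- if (length(rows)) do.call(rbind, rows) else blank(NA_integer_, NA_character_)[0, ]
  attr(truth, "dropped") <- dropped
  attr(truth, "p_extrude") <- p_ext
  attr(truth, "p_shrink_no_extrude") <- p_sne
  truth
}

#' Minimum movie span required for the full event chain
#'
#' @param config an [generator_config()].
#' @return minimum movie duration in minutes.
#' @export
min_movie_span <- function(config) {
  10L * config$frame_interval +
    config$shrink_duration_mean + config$lag_depol_to_shrink +
    config$lag_na_to_depol + config$lag_atp_to_na + 3 * config$frame_interval
}
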