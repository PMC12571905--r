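# Reproduction cohorts: generate synthetic fields until event quotas are
# met, run the measurement pipeline, and return per-cell rosters that the
# headline statistics are computed from.  Field seeds are derived as
# base_seed * 1000 + field index (well below 2^31 for any sensible base
# seed), so an entire benchmark is reproducible from one integer.

#' Join ground truth and lightning calls into a per-cell roster
#'
#' @param dataset an `hes_dataset`.
#' @param lightning a [run_lightning()] result for that dataset.
#' @return data frame with one row per ROI: truth class/times plus the
#'   pipeline's calls.
#' @export
make_roster <- function(dataset, lightning) {
  roster <- dataset$rois[, c("cell_id", "frame_first", "frame_last")]
  tr <- dataset$truth
  m <- match(roster$cell_id, tr$cell_id)
  roster$event_class <- ifelse(is.na(m), "none", tr$event_class[m])
  roster$has_shrink <- !is.na(m) & tr$has_shrink[m]
  roster$true_vol_loss <- tr$true_vol_loss[m]
  roster$t_extrusion <- tr$t_extrusion[m]
  i <- match(roster$cell_id, lightning$cell_id)
  roster$called_hes <- lightning$called_hes[i]
  roster$t_shrink_onset_min <- lightning$t_shrink_onset_min[i]
  roster$shrink_duration_min <- lightning$shrink_duration_min[i]
  roster$peak_percent_change <- lightning$peak_percent_change[i]
  roster
}

#' HES-calling benchmark cohort
#'
#' Simulates default-configuration crowded fields (phase channel; the
#' volume-reporter channel is rendered while the volume quota is unmet),
#' runs the lightning assay in partition mode with the ground-truth
#' extrusion times as annotations, and accumulates per-cell rosters until
#' the requested numbers of live-cell extrusions, apoptotic extrusions and
#' reporter-scored shrinking extruders are reached.
#'
#' @param base_seed integer; field `i` uses seed `base_seed * 1000 + i`.
#' @param min_lce,min_apoptotic,min_volume_extruders event quotas.
#' @param min_volume_stayers quota of reporter-scored non-extruding
#'   shrinkers (usually collected under the hypertonic condition instead;
#'   see [bench_volume_stay_cohort()]).
#' @param config field configuration.
#' @param params lightning parameters.
#' @param max_fields safety cap on the number of fields.
#' @return data frame: one row per cell over all fields, with a `field`
#'   column and, where the reporter was rendered, `percent_shrink`.
#' @export
bench_hes_cohort <- function(base_seed, min_lce = 200L, min_apoptotic = 0L,
                             min_volume_extruders = 0L, min_volume_stayers = 0L,
                             config = generator_config(),
                             params = lightning_params(), max_fields = 500L) {
  rosters <- list()
  n_lce <- n_apo <- n_vol <- n_stay <- 0L
  for (i in seq_len(max_fields)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed * 1000 + i)
    need_vol <- n_vol < min_volume_extruders || n_stay < min_volume_stayers
    chans <- c("phase", if (need_vol) "volume_reporter")
    ds <- simulate_dataset(cfg, channels = chans)
    res <- run_lightning(ds, params, mode = "partition")
    roster <- make_roster(ds, res)
    roster$field <- i
    roster$percent_shrink <- NA_real_
    if (need_vol) {
      vs <- reporter_volume_shrink(ds, "volume_reporter", lightning = res)
      roster$percent_shrink <- vs$percent_shrink[match(roster$cell_id, vs$cell_id)]
      n_vol <- n_vol + sum(roster$event_class == "LCE" & roster$has_shrink)
      n_stay <- n_stay + sum(roster$event_class == "none" & roster$has_shrink)
    }
    rosters[[i]] <- roster
    n_lce <- n_lce + sum(roster$event_class == "LCE")
    n_apo <- n_apo + sum(roster$event_class == "apoptotic_extrusion")
    if (n_lce >= min_lce && n_apo >= min_apoptotic &&
        n_vol >= min_volume_extruders && n_stay >= min_volume_stayers) break
  }
  do.call(rbind, rosters)
}

#' Non-extruding shrinker volume cohort
#'
#' Simulates hypertonic-condition fields (where many cells shrink without
#' extruding) and scores per-cell percent volume loss from the reporter
#' channel using detected shrink onsets, accumulating fields until the
#' requested number of non-extruding shrinkers is collected.
#'
#' @inheritParams bench_hes_cohort
#' @param min_stayers required number of non-extruding shrinkers.
#' @return roster data frame as in [bench_hes_cohort()].
#' @export
bench_volume_stay_cohort <- function(base_seed, min_stayers = 100L,
                                     config = apply_condition(
                                       generator_config(extrusion_rate = 20),
                                       "hypertonic"),
                                     params = lightning_params(),
                                     max_fields = 100L) {
  rosters <- list()
  n_stay <- 0L
  for (i in seq_len(max_fields)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed * 1000 + 600L + i)
    ds <- simulate_dataset(cfg, channels = c("phase", "volume_reporter"))
    res <- run_lightning(ds, params, mode = "partition")
    roster <- make_roster(ds, res)
    roster$field <- i
    vs <- reporter_volume_shrink(ds, "volume_reporter", lightning = res)
    roster$percent_shrink <- vs$percent_shrink[match(roster$cell_id, vs$cell_id)]
    rosters[[i]] <- roster
    n_stay <- n_stay + sum(roster$event_class == "none" & roster$has_shrink)
    if (n_stay >= min_stayers) break
  }
  do.call(rbind, rosters)
}

#' Cross-channel lag benchmark cohort
#'
#' Simulates default fields with phase, DiBAC and CoroNa channels, detects
#' per-cell depolarisation and sodium-entry up-onsets and the lightning
#' shrink onset, and returns one row per shrink-positive live-cell
#' extrusion carrying the three detected onset times.
#'
#' @inheritParams bench_hes_cohort
#' @param min_cells required number of shrink-positive LCE cells with all
#'   three onsets.
#' @return data frame: `cell_id`, `field`, `t_corona`, `t_dibac`,
#'   `t_shrink` (minutes).
#' @export
bench_lag_cohort <- function(base_seed, min_cells = 50L,
                             config = generator_config(),
                             params = lightning_params(), max_fields = 100L) {
  rows <- list()
  total <- 0L
  for (i in seq_len(max_fields)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed * 1000 + 300L + i)
    ds <- simulate_dataset(cfg, channels = c("phase", "dibac", "corona"))
    res <- run_lightning(ds, params, mode = "partition")
    dib <- channel_onsets(ds, "dibac", direction = "up")
    cor <- channel_onsets(ds, "corona", direction = "up")
    keep <- ds$truth$cell_id[ds$truth$event_class == "LCE" & ds$truth$has_shrink]
    df <- data.frame(
      cell_id = keep, field = i,
      t_corona = cor$t_onset_min[match(keep, cor$cell_id)],
      t_dibac = dib$t_onset_min[match(keep, dib$cell_id)],
      t_shrink = res$t_shrink_onset_min[match(keep, res$cell_id)]
    )
    df <- df[stats::complete.cases(df), , drop = FALSE]
    rows[[i]] <- df
    total <- total + nrow(df)
    if (total >= min_cells) break
  }
  do.call(rbind, rows)
}

#' Condition fold-change benchmark
#'
#' Simulates paired cohorts -- untreated control and contractility-inhibited
#' -- at homeostatic density, scores shrink incidence with the lightning
#' assay (no use of ground truth beyond the generative model), and returns
#' the two cohort summaries and the fold-change of detected shrink
#' incidence.  The control cohort is made several-fold larger than the
#' inhibited one because its rare events dominate the variance of the
#' ratio.  All fields of one benchmark share a single monolayer geometry
#' (events and noise are drawn independently per field), a common-random-
#' numbers economy that spends the simulation budget on the event
#' statistics the ratio actually depends on.
#'
#' @param base_seed integer seed.
#' @param n_cells_control,n_cells_inhibited minimum cells per cohort.
#' @param config base configuration; homeostatic-density filming.
#' @param params lightning parameters.
#' @return list with `control`, `inhibited` ([summarize_cohort()] objects)
#'   and `fold` ([fold_change()]).
#' @export
bench_condition_foldchange <- function(base_seed, n_cells_control = 50000L,
                                       n_cells_inhibited = 9000L,
                                       config = generator_config(
                                         extrusion_rate = 20, n_frames = 60L),
                                       params = lightning_params()) {
  cfg_geo <- config
  cfg_geo$seed <- as.integer(base_seed * 1000 + 99L)
  mono <- build_monolayer(cfg_geo)
  mono$geometry <- monolayer_geometry(mono, cfg_geo)

  run_condition <- function(condition, offset, n_target) {
    cfg0 <- apply_condition(config, condition)
    rosters <- list()
    n <- 0L
    i <- 0L
    while (n < n_target) {
      i <- i + 1L
      cfg <- cfg0
      cfg$seed <- as.integer(base_seed * 1000 + offset + i)
      truth <- sample_events(cfg, mono$rois)
      ds <- render_dataset(cfg, mono, truth, channels = "phase")
      res <- run_lightning(ds, params, mode = "partition")
      roster <- make_roster(ds, res)
      roster$field <- i
      rosters[[i]] <- roster
      n <- n + nrow(roster)
    }
    do.call(rbind, rosters)
  }
  ctl <- run_condition("control", 100000L, n_cells_control)
  inh <- run_condition("contractility_inhibited", 200000L, n_cells_inhibited)
  s_ctl <- summarize_cohort(ctl, "control", seed = base_seed)
  s_inh <- summarize_cohort(inh, "contractility_inhibited", seed = base_seed + 1L)
  list(control = s_ctl, inhibited = s_inh,
       fold = fold_change(s_ctl, s_inh, "shrink_incidence", seed = base_seed))
}
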