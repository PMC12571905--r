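# Shared fixtures: small configurations for unit tests and lazily-built,
# memoised benchmark cohorts reused across acceptance checks.

noiseless <- list(photon_gain = Inf, read_sd = 0)

tiny_config <- function(...) {
  args <- list(n_cells = 16L, image_size = c(128L, 128L), n_frames = 60L,
               extrusion_rate = 300, seed = 42L)
  user <- list(...)
  args[names(user)] <- user
  do.call(generator_config, args)
}

# a moderate noiseless field with plenty of events, for recovery checks
recovery_config <- function(seed = 7L) {
  generator_config(n_cells = 30L, image_size = c(208L, 208L), n_frames = 100L,
                   extrusion_rate = 400, seed = seed, noise = noiseless)
}

.bench_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .bench_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .bench_cache)
  }
  get(key, envir = .bench_cache, inherits = FALSE)
}

main_cohort <- function() {
  cached("main", bench_hes_cohort(1, min_lce = 200L, min_apoptotic = 300L,
                                  min_volume_extruders = 100L))
}
stay_cohort <- function() {
  cached("stay", bench_volume_stay_cohort(1, min_stayers = 100L))
}
lag_cohort <- function() {
  cached("lag", bench_lag_cohort(1, min_cells = 50L))
}
fold_bench <- function() {
  cached("fold", bench_condition_foldchange(1, n_cells_control = 4000L,
                                            n_cells_inhibited = 2000L))
}

# single-cell noiseless scene with a forced volume loss, for dose-response
# and oracle checks
forced_loss_scene <- function(loss, seed = 5L, extrude = TRUE) {
  cfg <- generator_config(n_cells = 12L, image_size = c(128L, 128L),
                          n_frames = 70L, extrusion_rate = 0,
                          p_shrink_no_extrude = 0, p_division = 0,
                          seed = seed, noise = noiseless)
  mono <- build_monolayer(cfg)
  id <- mono$rois$cell_id[which.min(abs(mono$rois$centroid_x - 64) +
                                      abs(mono$rois$centroid_y - 64))]
  truth <- data.frame(cell_id = id, event_class = if (extrude) "LCE" else "none",
                      has_shrink = TRUE,
                      t_atp_decline = 5.6, t_na_entry = 8.6, t_depol = 11,
                      t_shrink_onset = 16, t_relaxation = 22.5,
                      t_extrusion = if (extrude) 22.5 else NA_real_,
                      t_division = NA_real_, true_vol_loss = loss,
                      stringsAsFactors = FALSE)
  render_dataset(cfg, mono, truth, channels = c("phase", "volume_reporter"))
}
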