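# Synthetic monolayer generator: geometry, event sampling, rendering.

test_that("monolayer tessellation partitions the field", {
  cfg <- generator_config(n_cells = 4L, image_size = c(64L, 64L), seed = 1L)
  mono <- build_monolayer(cfg)
  expect_equal(sort(unique(as.vector(mono$partition))), 1:4)
  # every pixel is exactly one cell or junction skeleton
  expect_equal(sum(mono$label > 0) + sum(mono$junction), 64L * 64L)
  areas <- tabulate(mono$label[mono$label > 0], nbins = 4L)
  expect_equal(sum(areas), 64L * 64L - sum(mono$junction))
  expect_true(all(areas > 0))
})

test_that("monolayer generation is deterministic for a fixed seed", {
  cfg <- generator_config(n_cells = 4L, image_size = c(64L, 64L), seed = 1L)
  m1 <- build_monolayer(cfg)
  m2 <- build_monolayer(cfg)
  expect_identical(m1$label, m2$label)
  expect_identical(m1$rois, m2$rois)
})

test_that("cell areas are near-uniform, against exhaustive pixel counts", {
  cfg <- generator_config(n_cells = 200L, image_size = c(512L, 512L), seed = 7L)
  mono <- build_monolayer(cfg)
  # oracle: brute-force count of label occurrences
  areas <- vapply(1:200, function(i) sum(mono$label == i), numeric(1))
  expect_equal(as.vector(tabulate(mono$label[mono$label > 0], 200L)), areas)
  expect_lt(sd(areas) / mean(areas), 0.5)
  # junction skeleton is thin
  expect_lt(sum(mono$junction) / (512 * 512), 0.25)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(generator_config(p_hes_given_lce = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(frame_interval = 0), "> 0")
  expect_error(generator_config(vol_loss_extrude_mean = 10, vol_loss_stay_mean = 11),
               "exceed")
  expect_error(generator_config(n_cells = 100, image_size = c(32, 32)),
               "at least 50 px")
  expect_error(generator_config(condition = "nonsense"), "unknown condition")
})

test_that("no event sources means an empty event table", {
  cfg <- tiny_config(extrusion_rate = 0, p_shrink_no_extrude = 0, p_division = 0)
  mono <- build_monolayer(cfg)
  truth <- sample_events(cfg, mono$rois)
  expect_equal(nrow(truth), 0L)
})

test_that("a movie shorter than the event chain is rejected by name", {
  cfg <- tiny_config(n_frames = 20L)
  mono <- build_monolayer(cfg)
  expect_error(sample_events(cfg, mono$rois), "movie too short.*min required")
})

test_that("HES incidence among sampled LCE matches the binomial model", {
  # ~12,000 LCE sampled directly from the event model
  cfg <- generator_config(n_cells = 20000L, image_size = c(2048L, 2048L),
                          extrusion_rate = 800, seed = 3L)
  rois <- data.frame(cell_id = seq_len(cfg$n_cells))
  truth <- sample_events(cfg, rois)
  lce <- truth[truth$event_class == "LCE", ]
  expect_gt(nrow(lce), 10000L)
  p_hat <- mean(lce$has_shrink)
  se <- sqrt(0.7 * 0.3 / nrow(lce))       # oracle: binomial tail bound
  expect_lt(abs(p_hat - 0.7), 3 * se)
})

test_that("zero jitter chains event times at the exact configured lags", {
  cfg <- generator_config(n_cells = 2000L, image_size = c(1024L, 1024L),
                          extrusion_rate = 300, jitter_frac = 0,
                          shrink_duration_sd = 0, seed = 11L)
  truth <- sample_events(cfg, data.frame(cell_id = seq_len(cfg$n_cells)))
  ch <- truth[truth$has_shrink & !is.na(truth$t_atp_decline), ]
  expect_gt(nrow(ch), 100L)
  expect_equal(ch$t_depol - ch$t_na_entry, rep(2.4, nrow(ch)))
  expect_equal(ch$t_shrink_onset - ch$t_depol, rep(5, nrow(ch)))
  expect_equal(ch$t_na_entry - ch$t_atp_decline, rep(3, nrow(ch)))
  # non-extruding shrinkers carry the same depolarisation chain
  sne <- truth[truth$event_class == "none" & truth$has_shrink, ]
  expect_equal(sne$t_depol - sne$t_na_entry, rep(2.4, nrow(sne)))
})

test_that("event times respect the causal ordering in random configurations", {
  for (s in 1:8) {
    cfg <- generator_config(n_cells = 500L, image_size = c(512L, 512L),
                            extrusion_rate = runif(1, 50, 400),
                            n_frames = sample(80:200, 1),
                            jitter_frac = runif(1, 0, 0.3), seed = s)
    truth <- sample_events(cfg, data.frame(cell_id = seq_len(cfg$n_cells)))
    ch <- truth[truth$has_shrink & !is.na(truth$t_atp_decline), ]
    if (nrow(ch)) {
      expect_true(all(ch$t_atp_decline < ch$t_na_entry))
      expect_true(all(ch$t_na_entry < ch$t_depol))
      expect_true(all(ch$t_depol < ch$t_shrink_onset))
      expect_true(all(ch$t_shrink_onset < ch$t_extrusion))
      expect_true(all(ch$t_relaxation > ch$t_shrink_onset &
                        ch$t_relaxation <= ch$t_extrusion))
    }
    shr <- truth[truth$has_shrink, ]
    expect_true(all(shr$true_vol_loss >= 0))
    movie_min <- (cfg$n_frames - 1) * cfg$frame_interval
    tcols <- c("t_atp_decline", "t_na_entry", "t_depol", "t_shrink_onset",
               "t_relaxation", "t_extrusion", "t_division")
    for (cc in tcols) {
      v <- truth[[cc]]
      expect_true(all(is.na(v) | (v >= 0 & v <= movie_min)))
    }
  }
})

test_that("sampled volume losses match the configured distributions", {
  cfg <- generator_config(n_cells = 6000L, image_size = c(2048L, 2048L),
                          extrusion_rate = 400, seed = 9L)
  truth <- sample_events(cfg, data.frame(cell_id = seq_len(cfg$n_cells)))
  ext <- truth[truth$event_class == "LCE" & truth$has_shrink, ]
  expect_gt(nrow(ext), 1000L)
  se_mean <- 3 / sqrt(nrow(ext))
  expect_lt(abs(mean(ext$true_vol_loss) - 20), 3 * se_mean)
  expect_lt(abs(sd(ext$true_vol_loss) - 3), 3 * 3 / sqrt(2 * nrow(ext)))
})

test_that("conditions rescale shrink incidence relative to the untreated monolayer", {
  base <- generator_config(n_cells = 30000L, image_size = c(4096L, 4096L),
                           extrusion_rate = 20, n_frames = 60L, seed = 13L)
  rois <- data.frame(cell_id = seq_len(base$n_cells))
  t_ctl <- sample_events(apply_condition(base, "control"), rois)
  t_inh <- sample_events(apply_condition(base, "contractility_inhibited"), rois)
  p_ctl <- sum(t_ctl$has_shrink) / base$n_cells
  p_inh <- sum(t_inh$has_shrink) / base$n_cells
  ratio <- p_inh / p_ctl
  se <- ratio * sqrt(1 / sum(t_ctl$has_shrink) + 1 / sum(t_inh$has_shrink))
  expect_lt(abs(ratio - 23), 3 * se)
  # extrusion suppressed under contractility inhibition
  expect_lt(sum(t_inh$event_class %in% c("LCE", "apoptotic_extrusion")),
            0.2 * sum(t_ctl$event_class %in% c("LCE", "apoptotic_extrusion")))
})

test_that("noiseless rendering without events is static", {
  cfg <- tiny_config(extrusion_rate = 0, p_shrink_no_extrude = 0,
                     p_division = 0, noise = noiseless)
  ds <- simulate_dataset(cfg, channels = c("phase", "dibac"))
  for (ch in names(ds$channels)) {
    arr <- ds$channels[[ch]]
    for (t in seq_len(dim(arr)[3])) expect_identical(arr[, , t], arr[, , 1])
  }
})

test_that("rendering is bit-reproducible for a fixed seed", {
  cfg <- tiny_config()
  d1 <- simulate_dataset(cfg, channels = c("phase", "corona"))
  d2 <- simulate_dataset(cfg, channels = c("phase", "corona"))
  expect_identical(as.vector(d1$channels$phase), as.vector(d2$channels$phase))
  expect_identical(as.vector(d1$channels$corona), as.vector(d2$channels$corona))
  expect_identical(d1$truth, d2$truth)
})

test_that("suprathreshold junctional area rises monotonically during shrink", {
  ds <- forced_loss_scene(24, extrude = FALSE)
  ev <- ds$truth[1, ]
  stack <- ds$channels$phase
  params <- lightning_params()
  bl <- seq_len(params$baseline_window)
  id <- ev$cell_id
  reg <- ds$partition == id
  thr <- percentile <- NULL
  # oracle: exhaustive per-frame pixel count over the cell's region
  px <- matrix(as.numeric(stack), prod(dim(stack)[1:2]), dim(stack)[3])
  thr <- sort(as.numeric(px[as.vector(reg), bl]))[ceiling(0.98 * sum(reg) * length(bl))]
  counts <- colSums(px[as.vector(reg), ] > thr)
  on_f <- ceiling(ev$t_shrink_onset / 0.5) + 1
  peak_f <- which.max(counts)
  expect_true(all(diff(counts[(on_f - 1):peak_f]) > 0))
  # matches the packaged measurement exactly
  area <- measure_area_series(stack, thr, mask = reg)
  expect_equal(area, counts * attr(stack, "pixel_size")^2)
})

test_that("DiBAC trace of a depolarising cell steps exactly at t_depol", {
  cfg <- generator_config(n_cells = 12L, image_size = c(128L, 128L),
                          n_frames = 70L, extrusion_rate = 0,
                          p_shrink_no_extrude = 0, p_division = 0,
                          seed = 5L, noise = noiseless)
  mono <- build_monolayer(cfg)
  id <- mono$rois$cell_id[1]
  truth <- data.frame(cell_id = id, event_class = "LCE", has_shrink = TRUE,
                      t_atp_decline = 6, t_na_entry = 9, t_depol = 12,
                      t_shrink_onset = 17, t_relaxation = 24, t_extrusion = 24,
                      t_division = NA_real_, true_vol_loss = 20)
  ds <- render_dataset(cfg, mono, truth, channels = "dibac")
  reg <- as.vector(ds$partition == id)
  px <- matrix(as.numeric(ds$channels$dibac),
               prod(dim(ds$channels$dibac)[1:2]), cfg$n_frames)
  tr <- colMeans(px[reg, ])
  step_frame <- ceiling(12 / 0.5) + 1  # first frame at/after t_depol
  expect_true(all(tr[seq_len(step_frame - 1)] == tr[1]))
  expect_equal(tr[step_frame] / tr[1], 1.5, tolerance = 1e-12)
})

test_that("reporter integrated intensity tracks ground-truth volume to <1%", {
  ds <- forced_loss_scene(18, extrude = FALSE)
  ev <- ds$truth[1, ]
  stack <- ds$channels$volume_reporter
  reg <- as.vector(ds$partition == ev$cell_id)
  px <- matrix(as.numeric(stack), prod(dim(stack)[1:2]), dim(stack)[3])
  tot <- colSums(px[reg, ])
  rel <- tot / mean(tot[1:10])
  # proportionality: normalised intensity stays within the prescribed
  # volume range and reaches the trough exactly
  expect_equal(min(rel), 1 - 18 / 100, tolerance = 0.01)
  expect_true(all(rel >= 1 - 18 / 100 - 1e-9 & rel <= 1 + 1e-9))
})

test_that("channels requested without event annotations fail loudly", {
  cfg <- tiny_config()
  mono <- build_monolayer(cfg)
  truth <- sample_events(cfg, mono$rois)
  truth$t_depol <- NULL
  expect_error(render_dataset(cfg, mono, truth, channels = "dibac"),
               "lacks column")
})
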