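# Fluorescence kinetics: ROI traces, onset detection, lag estimation,
# pre-crowding normalisation.

test_that("ROI traces are per-frame box means", {
  arr <- array(7, dim = c(16, 16, 5))
  s <- hes_stack(arr, 0.2, 0.5)
  roi <- data.frame(x_min = 2L, y_min = 3L, x_max = 8L, y_max = 9L)
  expect_equal(extract_trace(s, roi), rep(7, 5))

  # 4-pixel ROI with values 1..4: mean 2.5 (hand-summed oracle)
  arr2 <- array(0, dim = c(4, 4, 1))
  arr2[1:2, 1:2, 1] <- c(1, 2, 3, 4)
  s2 <- hes_stack(arr2, 0.2, 0.5)
  roi2 <- data.frame(x_min = 0L, y_min = 0L, x_max = 2L, y_max = 2L)
  expect_equal(extract_trace(s2, roi2), (1 + 2 + 3 + 4) / 4)

  # disjoint ROIs give independent traces
  arr3 <- array(0, dim = c(8, 8, 2))
  arr3[1:4, 1:4, ] <- 5
  arr3[5:8, 5:8, ] <- 9
  s3 <- hes_stack(arr3, 0.2, 0.5)
  expect_equal(extract_trace(s3, data.frame(x_min = 0L, y_min = 0L, x_max = 4L, y_max = 4L)),
               rep(5, 2))
  expect_equal(extract_trace(s3, data.frame(x_min = 4L, y_min = 4L, x_max = 8L, y_max = 8L)),
               rep(9, 2))

  expect_error(extract_trace(s, data.frame(x_min = 5L, y_min = 5L, x_max = 5L, y_max = 5L)),
               "empty")
})

test_that("onset detection finds the first sustained run", {
  # step to 1.3 at frame 41 (0-based frame 40), 0.5 min/frame
  tr <- c(rep(1, 40), rep(1.3, 20))
  r <- detect_onset(tr, "up", frame_interval = 0.5, baseline_window = 10L)
  # oracle: exhaustive scan
  on <- NA
  for (f in 11:59) if (tr[f] >= 1.1 && tr[f + 1] >= 1.1) { on <- f; break }
  expect_equal(r$t_onset_min, (on - 1) * 0.5)
  expect_equal(r$t_onset_min, 20)
  expect_equal(r$effect_size, 0.3, tolerance = 1e-12)

  flat <- detect_onset(rep(1, 30), "up", frame_interval = 0.5, baseline_window = 10L)
  expect_true(is.na(flat$t_onset_min))

  dn <- detect_onset(c(rep(1, 20), rep(0.8, 10)), "down", frame_interval = 0.5,
                     baseline_window = 10L)
  expect_equal(dn$t_onset_min, 10)

  # onset detection is invariant to positive affine rescaling applied
  # before normalisation
  raw <- c(rep(50, 20), rep(68, 20))
  r1 <- detect_onset(normalize_series(raw, 1:10), "up", frame_interval = 0.5)
  r2 <- detect_onset(normalize_series(3 * raw + 0, 1:10), "up", frame_interval = 0.5)
  expect_equal(r1$t_onset_min, r2$t_onset_min)

  # marked medium-change frames cannot seed an onset run
  med <- c(rep(1, 20), 1.4, rep(1, 19))
  rx <- detect_onset(med, "up", frame_interval = 0.5, baseline_window = 10L,
                     exclude_frames = 21L)
  expect_true(is.na(rx$t_onset_min))
})

test_that("noiseless DiBAC onsets match ground truth to one frame", {
  cfg <- recovery_config(seed = 4L)
  ds <- simulate_dataset(cfg, channels = c("phase", "dibac"))
  calls <- channel_onsets(ds, "dibac", "up")
  ch <- ds$truth[!is.na(ds$truth$t_depol), ]
  got <- calls$t_onset_min[match(ch$cell_id, calls$cell_id)]
  expect_true(all(!is.na(got)))
  expect_true(all(got - ch$t_depol >= 0 & got - ch$t_depol <= 0.5 + 1e-9))
})

test_that("lag estimation averages per-cell onset differences", {
  a <- data.frame(cell_id = 1:5, channel = "corona",
                  t_onset_min = c(10, 12, NA, 14, 16))
  b <- data.frame(cell_id = 1:5, channel = "dibac",
                  t_onset_min = c(12.5, 14.5, 20, NA, 18.3))
  lag <- estimate_lag(a, b)
  expect_equal(lag$n_cells, 3L)
  expect_equal(lag$n_missing, 2L)
  expect_equal(lag$mean_lag, mean(c(2.5, 2.5, 2.3)))

  # identical call sets: zero lag
  z <- estimate_lag(a, a)
  expect_equal(z$mean_lag, 0)

  none <- data.frame(cell_id = 99, channel = "x", t_onset_min = NA_real_)
  expect_error(estimate_lag(a, none), "no cells")
})

test_that("zero-jitter cohorts recover configured lags to frame quantisation", {
  cfg <- generator_config(n_cells = 40L, image_size = c(248L, 248L),
                          n_frames = 90L, extrusion_rate = 700,
                          jitter_frac = 0, shrink_duration_sd = 0,
                          seed = 31L, noise = noiseless)
  ds <- simulate_dataset(cfg, channels = c("phase", "dibac", "corona"))
  dib <- channel_onsets(ds, "dibac", "up")
  cor <- channel_onsets(ds, "corona", "up")
  keep <- ds$truth$cell_id[ds$truth$has_shrink & !is.na(ds$truth$t_na_entry)]
  expect_gt(length(keep), 3)
  lag <- estimate_lag(cor[cor$cell_id %in% keep, ], dib[dib$cell_id %in% keep, ])
  # configured 2.4 min at 0.5 min frames: each onset quantised upward
  expect_lt(abs(lag$mean_lag - 2.4), 0.5)
  expect_true(all(abs(lag$lags - 2.4) <= 0.5 + 1e-9))
})

test_that("noisy multi-seed cohorts recover lags within two standard errors", {
  lags_ds <- c(); lags_cd <- c()
  for (s in 1:10) {
    cfg <- generator_config(n_cells = 50L, image_size = c(272L, 272L),
                            n_frames = 100L, extrusion_rate = 300, seed = 500 + s)
    ds <- simulate_dataset(cfg, channels = c("phase", "dibac", "corona"))
    res <- run_lightning(ds)
    dib <- channel_onsets(ds, "dibac", "up")
    cor <- channel_onsets(ds, "corona", "up")
    keep <- ds$truth$cell_id[ds$truth$event_class == "LCE" & ds$truth$has_shrink]
    td <- dib$t_onset_min[match(keep, dib$cell_id)]
    tc <- cor$t_onset_min[match(keep, cor$cell_id)]
    ts <- res$t_shrink_onset_min[match(keep, res$cell_id)]
    ok <- !is.na(td) & !is.na(tc) & !is.na(ts)
    lags_ds <- c(lags_ds, (ts - td)[ok])
    lags_cd <- c(lags_cd, (td - tc)[ok])
  }
  expect_gt(length(lags_ds), 50)
  expect_lt(abs(mean(lags_ds) - 5), 2 * sd(lags_ds) / sqrt(length(lags_ds)) + 0.25)
  expect_lt(abs(mean(lags_cd) - 2.4), 2 * sd(lags_cd) / sqrt(length(lags_cd)) + 0.25)
})

test_that("pre-crowding normalisation divides by the single reference value", {
  tr <- c(100, 110, 140)
  expect_equal(normalize_to_precrowding(tr, 1), c(1, 1.1, 1.4))
  expect_equal(normalize_to_precrowding(rep(55, 10), 1), rep(1, 10))
  expect_error(normalize_to_precrowding(c(0, 1, 2), 1), "positive")
})

test_that("crowding CoroNa stays high only in extruders", {
  cfg <- generator_config(n_cells = 25L, image_size = c(192L, 192L),
                          n_frames = 100L, extrusion_rate = 250,
                          seed = 12L, noise = noiseless)
  ds <- simulate_dataset(cfg, channels = "corona")
  stack <- ds$channels$corona
  px <- matrix(as.numeric(stack), prod(dim(stack)[1:2]), dim(stack)[3])
  ids_ext <- ds$truth$cell_id[ds$truth$event_class == "LCE" & ds$truth$has_shrink]
  ids_non <- setdiff(ds$rois$cell_id, ds$truth$cell_id)
  expect_gt(length(ids_ext), 0)
  mean_at_end <- function(id) {
    reg <- as.vector(ds$partition == id)
    ext_t <- ds$truth$t_extrusion[match(id, ds$truth$cell_id)]
    f <- if (!is.na(ext_t)) ceiling(ext_t / 0.5) else dim(stack)[3] - 1
    mean(normalize_to_precrowding(colMeans(px[reg, ]), 1)[f])
  }
  m_ext <- vapply(ids_ext, mean_at_end, numeric(1))
  m_non <- vapply(ids_non, mean_at_end, numeric(1))
  expect_gt(mean(m_ext), mean(m_non))
})
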