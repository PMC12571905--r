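# Lightning assay: thresholding, area measurement, normalisation, HES calls.

test_that("crop_window centres, clips and re-embeds exactly", {
  arr <- array(runif(1024 * 1024 * 2), dim = c(1024, 1024, 2))
  stack <- hes_stack(arr, 0.2125, 0.5)
  params <- lightning_params(window_px = 400L)

  mid <- data.frame(centroid_x = 512, centroid_y = 512)
  cr <- crop_window(stack, mid, params)
  expect_equal(dim(cr)[1:2], c(400L, 400L))

  corner <- data.frame(centroid_x = 10, centroid_y = 10)
  cc <- crop_window(stack, corner, params)
  expect_equal(attr(cc, "offset_x"), 0L)
  expect_equal(attr(cc, "offset_y"), 0L)

  # round trip: re-embed at the recorded offset recovers the pixels
  ox <- attr(cr, "offset_x"); oy <- attr(cr, "offset_y")
  expect_identical(arr[(oy + 1):(oy + 400), (ox + 1):(ox + 400), ],
                   unclass(cr)[, , ])

  outside <- data.frame(centroid_x = -5, centroid_y = 3)
  expect_error(crop_window(stack, outside, params), "outside")
})

test_that("threshold selection matches an exhaustive sort", {
  params <- lightning_params()
  # uniform baseline: degenerate, threshold equals the constant
  u <- hes_stack(array(10, dim = c(8, 8, 12)), 0.2125, 0.5)
  thr <- select_threshold(u, 1:10, params)
  expect_equal(as.numeric(thr), 10)
  expect_true(attr(thr, "degenerate"))
  expect_equal(measure_area_series(u, as.numeric(thr)), rep(0, 12))

  # two-valued baseline at the 98th percentile
  vals <- c(rep(0, 96), rep(100, 4))
  arr <- array(rep(vals, 10), dim = c(10, 10, 10))
  s <- hes_stack(arr, 0.2125, 0.5)
  thr2 <- select_threshold(s, 1:10, params)
  # oracle: exhaustive sort
  srt <- sort(as.numeric(arr))
  expect_equal(as.numeric(thr2), srt[ceiling(0.98 * length(srt))])
  expect_equal(as.numeric(thr2), 100)

  # determinism: identical windows give identical thresholds
  expect_identical(select_threshold(s, 1:10, params),
                   select_threshold(s, 1:10, params))
})

test_that("suprathreshold area matches exhaustive pixel counting", {
  set.seed(1)
  arr <- array(runif(64 * 64 * 5, 0, 200), dim = c(64, 64, 5))
  s <- hes_stack(arr, 0.2125, 0.5)
  a <- measure_area_series(s, 120)
  oracle <- vapply(1:5, function(t) sum(arr[, , t] > 120), numeric(1)) * 0.2125^2
  expect_equal(a, oracle)

  # 1,000 suprathreshold pixels at 0.2125 um/px
  arr2 <- array(0, dim = c(40, 40, 1))
  arr2[seq_len(1000)] <- 5
  expect_equal(measure_area_series(hes_stack(arr2, 0.2125, 0.5), 1),
               1000 * 0.2125^2)
  expect_equal(1000 * 0.2125^2, 45.15625)

  # all below threshold
  expect_equal(measure_area_series(s, 1e6), rep(0, 5))

  # per-frame independence: permuting frames permutes the series
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(measure_area_series(hes_stack(arr[, , perm], 0.2125, 0.5), 120),
               a[perm])
})

test_that("baseline normalisation uses the arithmetic baseline mean", {
  expect_equal(as.vector(normalize_series(rep(7, 20), 1:10)), rep(1, 20))
  s <- c(rep(50, 10), 75)
  expect_equal(as.vector(normalize_series(s, 1:10))[11], 1.5)
  # hand-summed oracle for a non-constant baseline
  b <- seq(48, by = 2, length.out = 10)
  tr <- normalize_series(c(b, 100), 1:10)
  expect_equal(attr(tr, "baseline_mean"), sum(b) / 10)
  expect_equal(mean(tr[1:10]), 1, tolerance = 1e-9)
  expect_error(normalize_series(rep(0, 15), 1:10), "positive")
})

test_that("detect_hes calls onset, relaxation and peak from a boxcar", {
  # boxcar rising to 1.4 for 13 frames at 0.5 min/frame
  tr <- c(rep(1, 10), rep(1.4, 13), rep(1, 17))
  params <- lightning_params()
  r <- detect_hes(tr, params, frame_interval = 0.5)
  # oracle: exhaustive scan over all frames
  on <- NA
  for (f in 11:length(tr)) {
    if (all(tr[f:(f + 1)] >= 1.1)) { on <- f; break }
  }
  rel <- on + which(tr[(on + 1):length(tr)] <= 1.05)[1]
  expect_equal(r$t_shrink_onset_min, (on - 1) * 0.5)
  expect_equal(r$t_relaxation_min, (rel - 1) * 0.5)
  expect_equal(r$shrink_duration_min, 6.5)
  expect_equal(r$peak_percent_change, 40)
  expect_true(r$called_hes)

  # flat trace: no call
  flat <- detect_hes(rep(1, 40), params, 0.5)
  expect_false(flat$called_hes)
  expect_true(is.na(flat$t_shrink_onset_min))

  # onset after extrusion is not a call
  late <- detect_hes(c(rep(1, 30), rep(1.4, 10)), params, 0.5, t_extrusion = 10)
  expect_false(late$called_hes)

  # never relaxing before a known extrusion truncates the duration
  never <- detect_hes(c(rep(1, 10), rep(1.5, 30)), params, 0.5, t_extrusion = 12)
  expect_true(never$called_hes)
  expect_true(never$relax_truncated)
  expect_equal(never$t_relaxation_min, 12)
})

test_that("affine intensity rescaling leaves the assay unchanged", {
  set.seed(2)
  arr <- array(runif(48 * 48 * 30, 50, 300), dim = c(48, 48, 30))
  arr[10:20, 10:20, 15:20] <- 400
  s1 <- hes_stack(arr, 0.2125, 0.5)
  s2 <- hes_stack(3.7 * arr + 11, 0.2125, 0.5)
  params <- lightning_params()
  t1 <- select_threshold(s1, 1:10, params)
  t2 <- select_threshold(s2, 1:10, params)
  expect_equal(as.numeric(t2), 3.7 * as.numeric(t1) + 11)
  a1 <- measure_area_series(s1, as.numeric(t1))
  a2 <- measure_area_series(s2, as.numeric(t2))
  expect_equal(a1, a2)
  expect_equal(as.vector(normalize_series(a1, 1:10)),
               as.vector(normalize_series(a2, 1:10)))
})

test_that("normalised traces have unit baseline mean to 1e-9", {
  ds <- forced_loss_scene(20)
  res <- run_lightning(ds, return_traces = TRUE)
  for (tr in attr(res, "traces")) {
    expect_equal(mean(tr[1:10]), 1, tolerance = 1e-9)
  }
})

test_that("peak percent change increases strictly with true volume loss", {
  losses <- seq(6, 28.5, by = 2.5)  # 10 magnitudes
  peaks <- vapply(losses, function(l) {
    ds <- forced_loss_scene(l)
    res <- run_lightning(ds)
    res$peak_percent_change[res$cell_id == ds$truth$cell_id[1]]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("noiseless HES calls and onsets match ground truth", {
  onset_off <- c()
  for (s in 1:4) {
    cfg <- recovery_config(seed = s)
    ds <- simulate_dataset(cfg, channels = "phase")
    res <- run_lightning(ds)
    roster <- make_roster(ds, res)
    expect_equal(roster$called_hes, roster$has_shrink)
    shr <- roster[roster$has_shrink, ]
    tr_on <- ds$truth$t_shrink_onset[match(shr$cell_id, ds$truth$cell_id)]
    onset_off <- c(onset_off, abs(shr$t_shrink_onset_min - tr_on))
  }
  expect_gt(length(onset_off), 20)
  # detected onsets within one frame of truth for >= 99% of shrink events
  expect_gte(mean(onset_off <= 0.5 + 1e-9), 0.99)
})

test_that("run_lightning with no ROIs returns an empty result", {
  ds <- forced_loss_scene(20)
  ds$rois <- ds$rois[0, ]
  res <- run_lightning(ds)
  expect_equal(nrow(res), 0L)
})

test_that("crop mode reproduces the single-cell protocol on an isolated event", {
  ds <- forced_loss_scene(22)
  params <- lightning_params(window_px = 96L)
  res <- run_lightning(ds, params, mode = "crop")
  id <- ds$truth$cell_id[1]
  r <- res[res$cell_id == id, ]
  expect_true(r$called_hes)
  expect_equal(r$t_shrink_onset_min, 16, tolerance = 0.51)
  # lightning results round-trip through the CSV writer
  f <- tempfile(fileext = ".csv")
  write_lightning_results(res, f)
  back <- read.csv(f)
  expect_equal(back$called_hes, res$called_hes)
  expect_equal(back$peak_percent_change, res$peak_percent_change, tolerance = 1e-12)
})
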