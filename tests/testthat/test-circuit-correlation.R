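# frame grid with exactly six baseline frames in the 2 s before t_i = 4 s
zscore_fixture <- function(baseline_vals, f_event) {
  ft <- seq(0, 5, by = 1 / 3)
  trace <- rep(0, length(ft))
  base_idx <- which(ft >= 2 & ft < 4)
  stopifnot(length(base_idx) == length(baseline_vals))
  trace[base_idx] <- baseline_vals
  trace[which.min(abs(ft - 4))] <- f_event
  list(trace = trace, ft = ft)
}

test_that("event z-scores follow the 2 s pre-event baseline definition", {
  fx <- zscore_fixture(c(10, 12, 14, 16, 18, 20), 22)
  zs <- event_zscores(fx$trace, fx$ft, 4)
  # hand computation: mean 15, sample SD sqrt(70/5), z = 7/sqrt(14)
  expect_equal(zs$baseline_mean, 15)
  expect_equal(zs$baseline_sd, sqrt(14))
  expect_equal(zs$z, 7 / sqrt(14))

  # F(t_i) equal to the baseline mean gives z = 0
  fx0 <- zscore_fixture(c(10, 12, 14, 16, 18, 20), 15)
  expect_equal(event_zscores(fx0$trace, fx0$ft, 4)$z, 0)

  # F(t_i) two SDs above the mean gives z = 2
  fx2 <- zscore_fixture(c(10, 12, 14, 16, 18, 20), 15 + 2 * sqrt(14))
  expect_equal(event_zscores(fx2$trace, fx2$ft, 4)$z, 2)

  # events without a full baseline, or with zero SD, are skipped
  expect_warning(z_early <- event_zscores(fx$trace, fx$ft, c(1, 4)),
                 "baseline")
  expect_equal(nrow(z_early), 1L)
  fxc <- zscore_fixture(rep(5, 6), 7)
  expect_warning(z_const <- event_zscores(fxc$trace, fxc$ft, 4), "zero")
  expect_equal(nrow(z_const), 0L)
})

test_that("stationarity filter keeps flat series and discards trends", {
  # constant z: slope 0, inside any shuffle band
  zs_flat <- tibble::tibble(event_time_s = 1:10, z = rep(1.3, 10))
  res <- stationarity_filter(zs_flat, seed = 1)
  expect_equal(res$slope, 0)
  expect_true(res$stationary)

  # strictly increasing z over 10 events: above the 90th percentile
  zs_up <- tibble::tibble(event_time_s = 1:10, z = seq(0, 3, length.out = 10))
  expect_false(stationarity_filter(zs_up, seed = 1)$stationary)

  # <= 6 events: exact enumeration, monotone series is the extreme slope
  zs6 <- tibble::tibble(event_time_s = 1:6, z = 1:6)
  res6 <- stationarity_filter(zs6)
  expect_true(res6$exact)
  expect_false(res6$stationary)
  expect_gt(res6$slope, res6$shuffle_p90)

  expect_error(stationarity_filter(
    tibble::tibble(event_time_s = 1:2, z = 1:2)), ">= 3")
})

test_that("stationarity filter is reproducible and calibrated near 20%", {
  zs <- tibble::tibble(event_time_s = 1:20, z = rnorm(20))
  r1 <- stationarity_filter(zs, seed = 99)
  r2 <- stationarity_filter(zs, seed = 99)
  expect_identical(r1, r2)

  # exchangeable series: the 10th-90th band discards ~20% of cells
  set.seed(202)
  n_cells <- 400
  times <- seq(10, 200, length.out = 15)
  discard <- vapply(seq_len(n_cells), function(i) {
    zs_i <- tibble::tibble(event_time_s = times, z = rnorm(15))
    !stationarity_filter(zs_i, n_shuffles = 400, seed = i)$stationary
  }, logical(1))
  expect_lt(abs(mean(discard) - 0.20), 0.06)
})

test_that("trace filtering removes baseline and smooths impulses", {
  # constant trace becomes all zeros
  expect_equal(filter_trace(rep(4.2, 200), 10), rep(0, 200))

  # impulse of height 3 spreads to (1, 1, 1) around its frame
  tr <- rep(0, 101); tr[51] <- 3
  f <- filter_trace(tr, 10)
  expect_equal(f[50:52], c(1, 1, 1))
  expect_equal(f[1:45], rep(0, 45))

  # pure linear drift is removed away from the edges
  ramp <- seq(0, 5, length.out = 400)
  fr <- filter_trace(ramp, 10)
  interior <- fr[160:240]
  expect_lt(max(abs(interior)), 1e-8)
})

test_that("pair correlations recover identity and independence", {
  set.seed(5)
  n_frames <- 400
  shared <- rnorm(n_frames)
  fl <- rbind(shared, shared, rnorm(n_frames))
  img <- imaging_recording(fl, 10, coords_um = rbind(c(0, 0), c(30, 40),
                                                     c(100, 0)),
                           area = "cortex")
  pc <- pair_correlations(list(img))
  r_ab <- pc$r[pc$cell_a == 1 & pc$cell_b == 2]
  expect_equal(r_ab, 1, tolerance = 1e-10)
  expect_equal(pc$distance_um[pc$cell_a == 1 & pc$cell_b == 2], 50)

  # independent white-noise cells: |r| < 0.05 for at least 95% of pairs
  set.seed(6)
  fl_n <- matrix(rnorm(20 * 10000), nrow = 20)
  img_n <- imaging_recording(fl_n, 10,
                             coords_um = matrix(runif(40, 0, 400), ncol = 2),
                             area = "cortex")
  pc_n <- pair_correlations(list(img_n))
  expect_gte(mean(abs(pc_n$r) < 0.05), 0.95)
})

test_that("spatial profile bins pairs with the unique-cell DOF rule", {
  pairs <- tibble::tibble(cell_a = c(1, 1), cell_b = c(2, 3),
                          distance_um = c(40, 60), r = c(0.2, 0.4))
  prof <- spatial_profile(pairs)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$mean_r, 0.3)
  expect_equal(prof$n_unique_cells, 3L)
  expect_equal(prof$sem_r, sd(c(0.2, 0.4)) / sqrt(3))

  # pairs at 50 and 150 um occupy bins [0,100) and [100,200)
  p2 <- tibble::tibble(cell_a = c(1, 2), cell_b = c(3, 4),
                       distance_um = c(50, 150), r = c(0.5, 0.1))
  prof2 <- spatial_profile(p2)
  expect_equal(prof2$bin_start_um, c(0, 100))
  expect_equal(prof2$n_pairs, c(1L, 1L))

  # identical correlations give SEM 0
  p3 <- tibble::tibble(cell_a = c(1, 2, 3), cell_b = c(4, 5, 6),
                       distance_um = c(10, 20, 30), r = rep(0.7, 3))
  expect_equal(spatial_profile(p3)$sem_r, 0)

  # invariance to pair ordering; count-weighted bin means pool to global mean
  set.seed(8)
  pr <- tibble::tibble(cell_a = 1:50, cell_b = 51:100,
                       distance_um = runif(50, 0, 350), r = runif(50, -1, 1))
  prof_a <- spatial_profile(pr)
  prof_b <- spatial_profile(pr[sample(50), ])
  expect_equal(prof_a, prof_b)
  filled <- prof_a[prof_a$n_pairs > 0, ]
  expect_equal(sum(filled$mean_r * filled$n_pairs) / sum(filled$n_pairs),
               mean(pr$r))
})

test_that("before/after comparison detects a constant correlation shift", {
  same <- tibble::tibble(r_before = runif(30), r_after = NA)
  same$r_after <- same$r_before
  res_same <- before_after_test(same)
  expect_equal(res_same$mean_diff, 0)
  expect_equal(res_same$p_value, 1)

  set.seed(9)
  shifted <- tibble::tibble(r_before = runif(100, 0, 0.5))
  shifted$r_after <- shifted$r_before + 0.1
  res <- before_after_test(shifted)
  expect_equal(res$mean_diff, -0.1)
  expect_lt(res$p_value, 1e-10)
  td <- tidy(res)
  expect_true(all(c("mean_diff", "p_value") %in% names(td)))
})

test_that("full before/after pipeline sees the correlation increase", {
  coords <- NULL
  base_cfg <- function(seed, base) {
    experiment_config(duration_s = 60, imaging_rate_hz = 10,
                      n_cells_cortex = 40, n_cells_thalamus = 2,
                      event_rate_hz = 0.25, participation_base = base,
                      noise_sd = 0.05, bleach_fraction = 0, seed = seed)
  }
  coords <- sample_fov_coords(base_cfg(1L, 0.1))
  mk <- function(seed, base) {
    cfg <- base_cfg(seed, base)
    truth <- generate_event_schedule(cfg, coords = coords)
    render_fluorescence(truth, cfg, "cortex")
  }
  before <- list(mk(11L, 0.10), mk(12L, 0.10))
  after <- list(mk(13L, 0.60), mk(14L, 0.60))
  pw <- suppressWarnings(pairwise_correlations(
    before, after, threshold_fraction = 0.1, n_shuffles = 100, seed = 2L))
  expect_gt(nrow(pw$pairs), 10)
  expect_gt(mean(pw$pairs$r_after), mean(pw$pairs$r_before))
  ba <- before_after_test(pw$pairs)
  expect_lt(ba$mean_diff, 0)
  expect_error(pairwise_correlations(before[1], after), "two recordings")
})

test_that("zero-lag dual-patch correlation and group comparison behave", {
  set.seed(10)
  x <- rnorm(5000)
  ea <- ephys_recording(x, 1000)
  eb <- ephys_recording(x, 1000)
  expect_equal(dual_patch_zero_lag(ea, eb), 1)
  en <- ephys_recording(-x, 1000)
  expect_equal(dual_patch_zero_lag(ea, en), -1)
  expect_warning(r <- dual_patch_zero_lag(
    ea, ephys_recording(x[1:4000], 1000)), "truncat")
  expect_equal(r, 1)
  expect_error(dual_patch_zero_lag(ea, ephys_recording(x, 500)), "rates")

  gc <- group_compare(c(0.5, 0.6, 0.7), c(0.55, 0.65))
  expect_true(gc$p_value > 0 && gc$p_value <= 1)
})

test_that("rank-sum p-values are uniform under the null (calibration)", {
  set.seed(11)
  pvals <- replicate(400, {
    g1 <- rnorm(11); g2 <- rnorm(7)
    group_compare(g1, g2)$p_value
  })
  # the exact rank-sum p-value is discrete, so calibration is checked as
  # agreement of tail probabilities with the uniform at several levels
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lt(abs(mean(pvals <= alpha) - alpha),
              0.03 + 3 * sqrt(alpha * (1 - alpha) / 400))
  }
})
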