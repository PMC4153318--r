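test_that("interval overlap drives matching, with signed lags", {
  m <- match_discharges(make_events(0, 1), make_events(0.5, 1.5))
  expect_true(m$matched)
  expect_equal(m$lag_s, 0.5)
  expect_equal(m$overlap_s, 0.5)

  m2 <- match_discharges(make_events(0, 1), make_events(2, 3))
  expect_false(m2$matched)
  expect_true(is.na(m2$lag_s))

  # a thalamic event overlapping two cortical events goes to the larger overlap
  m3 <- match_discharges(make_events(c(0, 1.2), c(1, 2.2)),
                         make_events(0.9, 1.4))
  expect_equal(m3$matched, c(FALSE, TRUE))
  expect_equal(m3$overlap_s[2], 0.2)

  expect_error(match_discharges(make_events(c(2, 0), c(3, 1)),
                                make_events(0, 1)), "sorted")
})

test_that("coupling reliability reproduces the worked examples", {
  # 8 cortical discharges, exactly 1 overlapped in thalamus: CR = 1/8
  ctx <- make_events(seq(0, 70, by = 10), seq(0, 70, by = 10) + 2)
  tha <- make_events(31, 33.5)
  m <- match_discharges(ctx, tha)
  expect_equal(coupling_reliability(m), 0.125)

  # 7 of 7 overlapped: CR = 1
  ctx7 <- make_events(seq(0, 60, by = 10), seq(0, 60, by = 10) + 2)
  tha7 <- make_events(seq(0, 60, by = 10) + 0.07, seq(0, 60, by = 10) + 2.1)
  expect_equal(coupling_reliability(match_discharges(ctx7, tha7)), 1.0)

  # nothing matched: CR = 0; no cortical events: undefined
  expect_equal(coupling_reliability(
    match_discharges(ctx7, make_events(200, 201))), 0)
  expect_error(coupling_reliability(
    match_discharges(make_events(numeric(0), numeric(0)), tha)), "undefined")
})

test_that("matching and CR agree with brute-force interval matching (<=6 events)", {
  set.seed(101)
  for (rep in 1:60) {
    inst <- random_instance(sample(0:6, 1), sample(0:6, 1))
    m <- match_discharges(inst$cortical, inst$thalamic)
    bf <- brute_force_match(inst$cortical, inst$thalamic)
    expect_identical(m$matched, bf$matched)
    expect_equal(m$lag_s, bf$lag_s)
    if (nrow(inst$cortical) > 0) {
      expect_equal(coupling_reliability(m), bf$cr)
      # when the overlap graph is one-to-one, CR equals a plain count of
      # cortical events overlapping any thalamic event
      ov <- outer(seq_len(nrow(inst$cortical)), seq_len(nrow(inst$thalamic)),
                  function(i, j) {
                    pmin(inst$cortical$offset_s[i], inst$thalamic$offset_s[j]) -
                      pmax(inst$cortical$onset_s[i], inst$thalamic$onset_s[j])
                  })
      if (length(ov) && all(rowSums(ov > 0) <= 1) && all(colSums(ov > 0) <= 1)) {
        expect_equal(coupling_reliability(m),
                     mean(rowSums(ov > 0) > 0))
      }
    }
  }
})

test_that("CR is invariant to a common time shift of both event lists", {
  set.seed(7)
  inst <- random_instance(6, 5)
  cr0 <- coupling_reliability(match_discharges(inst$cortical, inst$thalamic))
  shift <- function(ev, dt) make_events(ev$onset_s + dt, ev$offset_s + dt)
  cr1 <- coupling_reliability(match_discharges(shift(inst$cortical, 1234.5),
                                               shift(inst$thalamic, 1234.5)))
  expect_equal(cr0, cr1)
})

test_that("lag statistics summarise matched lags with the tie rule", {
  m <- tibble::tibble(matched = TRUE, lag_s = c(0.05, 0.07, 0.10))
  ls <- lag_statistics(m)
  expect_equal(ls$median_lag_s, 0.07)
  expect_equal(ls$fraction_cortex_leading, 1.0)

  m2 <- tibble::tibble(matched = TRUE, lag_s = c(-0.1, 0.1))
  ls2 <- lag_statistics(m2)
  expect_equal(ls2$median_lag_s, 0.0)
  expect_equal(ls2$fraction_cortex_leading, 0.5)

  # exact zero lag counts as not leading
  m3 <- tibble::tibble(matched = TRUE, lag_s = c(0, 0.1))
  expect_equal(lag_statistics(m3)$fraction_cortex_leading, 0.5)

  expect_error(lag_statistics(tibble::tibble(matched = FALSE,
                                             lag_s = NA_real_)), "undefined")
})

test_that("simulated log-normal lags are recovered through the matcher", {
  cfg <- experiment_config(duration_s = 10000, event_rate_hz = 0.5,
                           n_cells_cortex = 2, n_cells_thalamus = 2,
                           lag_median_s = 0.066, lag_spread = 0.5, seed = 17L)
  truth <- generate_event_schedule(cfg)
  coup <- truth$thalamic_coupled
  expect_gt(sum(coup), 2000)
  ctx <- make_events(truth$event_times_s, truth$event_times_s + 1)
  tha <- make_events(truth$event_times_s[coup] + truth$true_lags_s[coup],
                     truth$event_times_s[coup] + truth$true_lags_s[coup] + 1)
  ls <- lag_statistics(match_discharges(ctx, tha))
  expect_equal(ls$n_matched, sum(coup))
  expect_lt(abs(ls$median_lag_s - median(truth$true_lags_s[coup])), 1e-12)
  expect_lt(abs(ls$median_lag_s - 0.066), 0.005)
  expect_equal(ls$fraction_cortex_leading, 1.0)
})

test_that("timelines align at the first threshold crossing", {
  pts <- tibble::tibble(slice_id = "s1", time_min = c(0, 10, 20),
                        value = c(0, 0, 1))
  al <- align_timeline(pts, bin_min = 20)
  expect_equal(sort(al$points$aligned_min), c(-20, -10, 0))

  # two identical slices: bin means equal single-slice values, SEM 0
  pts2 <- dplyr::bind_rows(pts, dplyr::mutate(pts, slice_id = "s2"))
  al2 <- align_timeline(pts2, bin_min = 10)
  expect_equal(al2$bins$sem, rep(0, nrow(al2$bins)))
  expect_equal(al2$bins$mean, c(0, 0, 1))

  # output is invariant to slice relabeling
  pts3 <- dplyr::mutate(pts2, slice_id = rev(slice_id))
  al3 <- align_timeline(pts3, bin_min = 10)
  expect_equal(al3$bins, al2$bins)

  # a slice that never crosses is excluded with a warning
  pts4 <- dplyr::bind_rows(
    pts, tibble::tibble(slice_id = "flat", time_min = c(0, 10),
                        value = c(0.1, 0.2)))
  expect_warning(al4 <- align_timeline(pts4), "never crosses")
  expect_equal(unique(al4$points$slice_id), "s1")
  expect_error(suppressWarnings(
    align_timeline(tibble::tibble(slice_id = "f", time_min = 0:1,
                                  value = c(0, 0)))), "no slice")
})

test_that("frame averaging downsamples a voltage trace correctly", {
  fs <- 1000
  # constant trace stays constant
  rec_const <- ephys_recording(rep(1, 2 * fs), fs)
  expect_equal(downsample_by_frame_average(rec_const, seq(0, 1.9, by = 0.1)),
               rep(1, 20))

  # 0..999 mV ramp at 1 kHz, 10 Hz frames: frame 0 averages samples 0..99
  rec_ramp <- ephys_recording(0:999, fs)
  v <- downsample_by_frame_average(rec_ramp, seq(0, 0.9, by = 0.1))
  expect_equal(v, seq(49.5, 949.5, by = 100))

  # one sample per frame is the identity
  rec_id <- ephys_recording(c(5, 7, 9), 10)
  expect_equal(downsample_by_frame_average(rec_id, c(0, 0.1, 0.2)), c(5, 7, 9))
})

test_that("correlated-cell rule combines one-sided significance and |r| gate", {
  fs <- 1000; rate <- 10; dur <- 60
  set.seed(3)
  vm <- rep(-65, dur * fs)
  for (t0 in seq(5, 55, by = 5)) {
    idx <- (t0 * fs):((t0 + 1) * fs)
    vm[idx] <- vm[idx] + 15
  }
  eph <- ephys_recording(vm, fs, area = "cortex")
  ft <- (seq_len(dur * rate) - 1) / rate
  v_ds <- downsample_by_frame_average(eph, ft)

  n_cells <- 20
  fl <- matrix(rnorm(n_cells * dur * rate, 0, 0.05), n_cells)
  fl[1, ] <- v_ds + 65            # perfectly locked
  fl[2, ] <- -(v_ds + 65)         # anti-correlated
  locked <- 3:12                  # ten more event-locked cells, mild noise
  for (i in locked) fl[i, ] <- v_ds + 65 + rnorm(dur * rate, 0, 1)
  img <- imaging_recording(fl, rate, coords_um = matrix(0, n_cells, 2),
                           area = "thalamus")
  res <- fraction_correlated_cells(img, eph)
  expect_true(res$cells$correlated[1])
  expect_equal(res$cells$r[1], 1)
  expect_false(res$cells$correlated[2])  # |r| = 1 but r not > 0
  expect_equal(res$cells$r[2], -1)
  expect_true(all(res$cells$correlated[locked]))
  expect_lt(abs(res$fraction - 12 / 20), 0.05 + 1e-9)

  # a constant cell is undefined and counted as not correlated
  fl2 <- fl; fl2[15, ] <- 2
  img2 <- imaging_recording(fl2, rate, coords_um = matrix(0, n_cells, 2),
                            area = "thalamus")
  expect_warning(res2 <- fraction_correlated_cells(img2, eph), "constant")
  expect_false(res2$cells$correlated[15])

  # too little overlap is an error
  short <- ephys_recording(vm[1:(20 * fs)], fs)
  expect_error(fraction_correlated_cells(img, short), "30 s")
})

test_that("recovered CR tracks the scheduled coupling probability", {
  for (p in c(0.2, 0.7)) {
    cfg <- experiment_config(duration_s = 600, event_rate_hz = 0.2,
                             n_cells_cortex = 2, n_cells_thalamus = 2,
                             coupling_schedule = function(t) rep(p, length(t)),
                             seed = 23L)
    truth <- generate_event_schedule(cfg)
    expect_gte(length(truth$event_times_s), 30)
    coup <- truth$thalamic_coupled
    ctx <- make_events(truth$event_times_s, truth$event_times_s + 1)
    tha <- make_events(truth$event_times_s[coup] + truth$true_lags_s[coup],
                       truth$event_times_s[coup] + truth$true_lags_s[coup] + 1)
    cr <- coupling_reliability(match_discharges(ctx, tha))
    expect_lt(abs(cr - p), 0.1)
  }
})
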