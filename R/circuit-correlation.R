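#' Event-aligned z-scored fluorescence for one cell
#'
#' For each population event at time `t_i`, computes
#' `z(t_i) = (F(t_i) - <F_b>) / sigma_Fb`, where `F(t_i)` is the fluorescence
#' at the frame nearest `t_i` and `<F_b>`, `sigma_Fb` are the mean and sample
#' standard deviation (n - 1 denominator) of the fluorescence over the
#' `baseline_window_s` seconds preceding the event (frames in
#' `[t_i - w, t_i)`). Events without a full preceding baseline, or with zero
#' baseline SD, are skipped with a warning.
#'
#' @param trace Numeric vector, one cell's fluorescence.
#' @param frame_times_s Absolute frame times (s).
#' @param event_times_s Event (discharge) onset times (s).
#' @param baseline_window_s Baseline window before each event (default 2 s).
#' @return A tibble with one row per usable event: `event_time_s`, `z`,
#'   `baseline_mean`, `baseline_sd`.
#' @export
event_zscores <- function(trace, frame_times_s, event_times_s,
                          baseline_window_s = 2.0) {
  stopifnot(length(trace) == length(frame_times_s))
  rows <- purrr::map(event_times_s, function(t_i) {
    if (t_i - baseline_window_s < frame_times_s[1]) {
      warn_tc("event at ", signif(t_i, 4), " s lacks a full baseline; skipped")
      return(NULL)
    }
    base_idx <- which(frame_times_s >= t_i - baseline_window_s &
                        frame_times_s < t_i)
    if (length(base_idx) < 2L) {
      warn_tc("event at ", signif(t_i, 4), " s has <2 baseline frames; skipped")
      return(NULL)
    }
    mu <- mean(trace[base_idx])
    sdev <- sd(trace[base_idx])
    if (sdev == 0) {
      warn_tc("zero baseline SD at ", signif(t_i, 4), " s; event skipped")
      return(NULL)
    }
    f_i <- trace[which.min(abs(frame_times_s - t_i))]
    tibble(event_time_s = t_i, z = (f_i - mu) / sdev,
           baseline_mean = mu, baseline_sd = sdev)
  })
  bind_rows(purrr::compact(rows))
}

#' Permutation test for stationarity of event-aligned signal strength
#'
#' Guards the correlation analysis against bleaching-like artifacts: the
#' least-squares slope of `z(t_i)` against `t_i` is compared with the
#' distribution of slopes obtained by permuting the z values across the
#' fixed event times. A cell is stationary when the empirical slope lies
#' within the 10th-90th percentiles of the shuffled distribution; otherwise
#' it is discarded from the correlation analysis. For six or fewer events
#' every permutation is enumerated exactly; otherwise `n_shuffles` random
#' permutations are drawn.
#'
#' @param zs Tibble from [event_zscores()] (needs `event_time_s`, `z`).
#' @param n_shuffles Number of random permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @param lower,upper Percentile bounds of the acceptance band.
#' @return One-row tibble: `slope`, `shuffle_p10`, `shuffle_p90`,
#'   `stationary`, `n_events`, `exact` (whether permutations were
#'   enumerated).
#' @export
stationarity_filter <- function(zs, n_shuffles = 1000, seed = 1L,
                                lower = 0.10, upper = 0.90) {
  if (!is.data.frame(zs) || !all(c("event_time_s", "z") %in% names(zs))) {
    stop_tc("`zs` must come from event_zscores()")
  }
  n <- nrow(zs)
  if (n < 3L) stop_tc("stationarity test needs >= 3 events with defined z")
  tt <- zs$event_time_s
  z <- zs$z
  tc <- tt - mean(tt)
  ssd <- sum(tc^2)
  slope <- sum(tc * z) / ssd

  exact <- n <= 6L
  if (exact) {
    perms <- all_permutations(n)
    zp <- matrix(z[perms], nrow(perms), n)
  } else {
    set.seed(seed)
    zp <- t(replicate(n_shuffles, sample(z)))
  }
  shuffle_slopes <- as.numeric(zp %*% tc) / ssd
  qs <- stats::quantile(shuffle_slopes, c(lower, upper), names = FALSE)
  # accumulation-order rounding bound, so e.g. a constant series (all slopes
  # analytically zero) is never discarded on numerical noise
  tol <- 1e-10 * sum(abs(tc)) * max(abs(z)) / ssd
  tibble(slope = slope, shuffle_p10 = qs[1], shuffle_p90 = qs[2],
         stationary = slope >= qs[1] - tol & slope <= qs[2] + tol,
         n_events = n, exact = exact)
}

#' Filter a fluorescence trace for correlation analysis
#'
#' Removes a 30 s running-median baseline and applies a 3-frame centered
#' moving average (edge frames use shrunken windows). Output length equals
#' input length.
#'
#' @param trace Numeric fluorescence vector.
#' @param frame_rate_hz Frame rate (Hz).
#' @param baseline_window_s Running-median window (s).
#' @param smooth_frames Moving-average width in frames (odd).
#' @return Filtered numeric vector.
#' @export
filter_trace <- function(trace, frame_rate_hz, baseline_window_s = 30,
                         smooth_frames = 3L) {
  n <- length(trace)
  k <- round(baseline_window_s * frame_rate_hz)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  base <- if (k >= 3L) stats::runmed(trace, k, endrule = "median") else
    rep(stats::median(trace), n)
  moving_average(trace - base, smooth_frames)
}

#' Pairwise correlations of one set of recordings
#'
#' Filters every cell's trace per recording ([filter_trace()]), concatenates
#' the filtered traces across recordings, and computes the Pearson
#' correlation for every cell pair together with the intersomatic distance.
#'
#' @param recordings List of [imaging_recording()]s from the same FOV (same
#'   cells, same order).
#' @param cells Optional integer vector restricting which cells enter.
#' @param ... Passed to [filter_trace()].
#' @return A tibble: `cell_a`, `cell_b`, `distance_um`, `r`.
#' @export
pair_correlations <- function(recordings, cells = NULL, ...) {
  stopifnot(length(recordings) >= 1L)
  n_cells <- nrow(recordings[[1]]$fluorescence)
  cells <- cells %||% seq_len(n_cells)
  filt <- purrr::map(recordings, function(rec) {
    t(apply(rec$fluorescence[cells, , drop = FALSE], 1, filter_trace,
            frame_rate_hz = rec$frame_rate_hz, ...))
  })
  traces <- do.call(cbind, filt)
  cmat <- stats::cor(t(traces))
  coords <- recordings[[1]]$coords_um[cells, , drop = FALSE]
  pr <- which(upper.tri(cmat), arr.ind = TRUE)
  tibble(
    cell_a = cells[pr[, 1]], cell_b = cells[pr[, 2]],
    distance_um = sqrt((coords[pr[, 1], 1] - coords[pr[, 2], 1])^2 +
                         (coords[pr[, 1], 2] - coords[pr[, 2], 2])^2),
    r = cmat[pr]
  )
}

#' Before/after pairwise correlations around thalamic recruitment
#'
#' Implements the full intracortical correlation pipeline. Requires at least
#' two recordings per condition. Per recording, onsets are inferred and
#' population events detected; a cell is included when it is active in at
#' least one event before recruitment and at least one event after, and when
#' it passes the stationarity filter computed on its event-aligned z-scores
#' pooled over all recordings. For each condition the filtered traces of the
#' included cells are concatenated across that condition's recordings and a
#' single Pearson r per pair is computed.
#'
#' @param before,after Lists of [imaging_recording()]s (>= 2 each) from the
#'   same FOV.
#' @param decay_s,k_mad,noise_scale Onset-inference parameters.
#' @param threshold_fraction,window_frames,merge_gap_s Event-detection
#'   parameters (see [detect_circuit_events()]).
#' @param n_shuffles,seed Stationarity-filter parameters.
#' @return A list: `pairs` (tibble `cell_a`, `cell_b`, `distance_um`,
#'   `r_before`, `r_after`), `cells` (per-cell inclusion bookkeeping), and
#'   `n_excluded_nonstationary`.
#' @export
pairwise_correlations <- function(before, after, decay_s = 1.0, k_mad = 3,
                                  noise_scale = 3, threshold_fraction = NULL,
                                  window_frames = 1L, merge_gap_s = 0.5,
                                  n_shuffles = 1000, seed = 1L) {
  if (length(before) < 2L || length(after) < 2L) {
    stop_tc("need at least two recordings before and two after recruitment")
  }
  prep <- function(recs) {
    purrr::map(recs, function(rec) {
      ras <- infer_onsets(rec, decay_s = decay_s, k_mad = k_mad,
                          noise_scale = noise_scale)
      ev <- detect_circuit_events(ras, threshold_fraction = threshold_fraction,
                                  window_frames = window_frames,
                                  merge_gap_s = merge_gap_s)
      list(rec = rec, raster = ras, events = ev)
    })
  }
  pb <- prep(before); pa <- prep(after)

  active_in_events <- function(p) {
    act <- rep(FALSE, nrow(p$rec$fluorescence))
    for (k in seq_len(nrow(p$events))) {
      fr <- which(p$raster$frame_times_s >= p$events$onset_s[k] &
                    p$raster$frame_times_s < p$events$offset_s[k])
      act <- act | rowSums(p$raster$onsets[, fr, drop = FALSE]) > 0
    }
    act
  }
  act_before <- Reduce(`|`, purrr::map(pb, active_in_events))
  act_after <- Reduce(`|`, purrr::map(pa, active_in_events))
  included <- act_before & act_after

  # stationarity on z-scores pooled over every recording, experiment clock
  stationary <- rep(NA, length(included))
  for (i in which(included)) {
    zs <- bind_rows(purrr::map(c(pb, pa), function(p) {
      if (!nrow(p$events)) return(NULL)
      suppressWarnings(event_zscores(p$rec$fluorescence[i, ],
                                     frame_times(p$rec), p$events$onset_s))
    }))
    if (is.null(zs) || nrow(zs) < 3L) {
      included[i] <- FALSE
      next
    }
    stationary[i] <- stationarity_filter(zs, n_shuffles = n_shuffles,
                                         seed = seed + i)$stationary
  }
  n_nonstat <- sum(!stationary[included], na.rm = TRUE)
  eligible <- which(included & stationary %in% TRUE)
  if (length(eligible) < 2L) stop_tc("fewer than 2 eligible cells")

  prs_b <- pair_correlations(purrr::map(pb, "rec"), cells = eligible)
  prs_a <- pair_correlations(purrr::map(pa, "rec"), cells = eligible)
  pairs <- prs_b |>
    rename(r_before = "r") |>
    left_join(select(prs_a, "cell_a", "cell_b", r_after = "r"),
              by = c("cell_a", "cell_b"))
  cells <- tibble(cell = seq_along(included),
                  active_before = act_before, active_after = act_after,
                  stationary = stationary,
                  eligible = seq_along(included) %in% eligible)
  list(pairs = pairs, cells = cells, n_excluded_nonstationary = n_nonstat)
}

#' Distance-binned spatial profile of pairwise correlations
#'
#' Pairs are grouped into contiguous distance bins `[0, w)`, `[w, 2w)`, ...
#' (default 100 um). Per bin the mean correlation is reported with a SEM
#' whose degrees of freedom come from the number of unique cells in the bin
#' rather than the number of pairs (one cell can appear in many pairs):
#' `SEM = SD(r) / sqrt(n_unique_cells)`.
#'
#' @param pairs Tibble with `cell_a`, `cell_b`, `distance_um` and a
#'   correlation column.
#' @param value Name of the correlation column (default `"r"`; use
#'   `"r_before"`/`"r_after"` on [pairwise_correlations()] output).
#' @param bin_um Bin width in micrometers (default 100).
#' @return A tibble of class `spatial_profile`: `bin_start_um`,
#'   `bin_end_um`, `mean_r`, `sem_r`, `n_pairs`, `n_unique_cells`.
#' @export
spatial_profile <- function(pairs, value = "r", bin_um = 100) {
  if (!nrow(pairs)) stop_tc("need at least one pair")
  if (!value %in% names(pairs)) stop_tc("no column `", value, "` in pairs")
  r <- pairs[[value]]
  bin <- floor(pairs$distance_um / bin_um)
  n_bins <- max(bin) + 1L
  rows <- purrr::map(seq_len(n_bins) - 1L, function(b) {
    sel <- bin == b
    if (!any(sel)) {
      return(tibble(bin_start_um = b * bin_um, bin_end_um = (b + 1) * bin_um,
                    mean_r = NA_real_, sem_r = NA_real_, n_pairs = 0L,
                    n_unique_cells = 0L))
    }
    uc <- length(unique(c(pairs$cell_a[sel], pairs$cell_b[sel])))
    rs <- r[sel]
    tibble(bin_start_um = b * bin_um, bin_end_um = (b + 1) * bin_um,
           mean_r = mean(rs),
           sem_r = if (length(rs) >= 2L) sd(rs) / sqrt(uc) else NA_real_,
           n_pairs = sum(sel), n_unique_cells = uc)
  })
  out <- bind_rows(rows)
  class(out) <- c("spatial_profile", class(out))
  out
}

#' Paired before/after comparison of pairwise correlations
#'
#' Per-pair difference `d = r_before - r_after`, summarised by its mean and
#' a two-sided paired Wilcoxon signed-rank p-value (a distribution-free
#' choice consistent with the nonparametric tests used elsewhere in the
#' analysis). Negative mean difference means correlations increased after
#' recruitment.
#'
#' @param pairs Tibble with `r_before` and `r_after` columns.
#' @return Object of class `tc_test` with `mean_diff`, `p_value`,
#'   `statistic`, `n`, `method`. Supports [tidy()] and [glance()].
#' @export
before_after_test <- function(pairs) {
  if (nrow(pairs) < 2L) stop_tc("need >= 2 pairs")
  d <- pairs$r_before - pairs$r_after
  if (all(d == 0)) {
    return(new_tc_test(mean_diff = 0, p_value = 1, statistic = NA_real_,
                       n = length(d),
                       method = "Wilcoxon signed rank (degenerate: all ties)"))
  }
  wt <- suppressWarnings(stats::wilcox.test(pairs$r_before, pairs$r_after,
                                            paired = TRUE))
  new_tc_test(mean_diff = mean(d), p_value = wt$p.value,
              statistic = unname(wt$statistic), n = length(d),
              method = wt$method)
}

#' Zero-lag correlation between two simultaneous voltage traces
#'
#' Pearson correlation of the two mean-removed traces with no time shift.
#' Traces of unequal length are truncated to their overlap with a warning.
#'
#' @param ephys_a,ephys_b [ephys_recording()]s at the same sample rate.
#' @return A single correlation coefficient.
#' @export
dual_patch_zero_lag <- function(ephys_a, ephys_b) {
  stopifnot(inherits(ephys_a, "ephys_recording"),
            inherits(ephys_b, "ephys_recording"))
  if (ephys_a$sample_rate_hz != ephys_b$sample_rate_hz) {
    stop_tc("sample rates differ")
  }
  a <- ephys_a$vm_mv; b <- ephys_b$vm_mv
  if (length(a) != length(b)) {
    warn_tc("trace lengths differ; truncating to the overlap")
    n <- min(length(a), length(b))
    a <- a[seq_len(n)]; b <- b[seq_len(n)]
  }
  stats::cor(a - mean(a), b - mean(b))
}

#' Compare two groups of per-slice correlation coefficients
#'
#' Two-sided Wilcoxon rank-sum test, as used to compare zero-lag dual-patch
#' correlations between slices with and without thalamocortical
#' connectivity.
#'
#' @param group1,group2 Numeric vectors of per-slice correlations.
#' @return Object of class `tc_test` with `p_value`, `statistic`, group
#'   means and sizes. Supports [tidy()] and [glance()].
#' @export
group_compare <- function(group1, group2) {
  wt <- stats::wilcox.test(group1, group2)
  new_tc_test(p_value = wt$p.value, statistic = unname(wt$statistic),
              mean1 = mean(group1), mean2 = mean(group2),
              n1 = length(group1), n2 = length(group2), method = wt$method)
}

new_tc_test <- function(...) {
  structure(list(...), class = "tc_test")
}

#' @export
print.tc_test <- function(x, ...) {
  cat("<tc_test>", x$method, "\n")
  flds <- setdiff(names(x), "method")
  for (f in flds) cat(sprintf("  %s: %s\n", f, format(x[[f]], digits = 4)))
  invisible(x)
}

#' @export
tidy.tc_test <- function(x, ...) {
  as_tibble(x[setdiff(names(x), "method")]) |>
    mutate(method = x$method)
}

#' @export
glance.tc_test <- function(x, ...) tidy(x, ...)
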