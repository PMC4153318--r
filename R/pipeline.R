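#' Run the full thalamocortical recruitment pipeline on a synthetic session
#'
#' End-to-end, logged run of every stage on one simulated slice session:
#' simulate repeated two-minute recordings while the coupling schedule
#' evolves; infer onsets from cortical fluorescence; detect population
#' discharges (imaging) and membrane-potential discharges (ephys); match
#' discharges across areas; compute per-recording coupling reliability and
#' pooled lag statistics; build the crossing-aligned CR timeline and the
#' fraction-of-correlated-cells timeline; compare intracortical pairwise
#' correlations before vs after recruitment with spatial profiles; and
#' correlate per-discharge cortical and thalamic intensities. All
#' intermediate tables are written as TSV and the summary as JSON, with a
#' run log recording every parameter in force.
#'
#' @param config An [experiment_config()] whose `coupling_schedule` spans the
#'   session (absolute time); a step schedule reproduces recruitment.
#' @param out_dir Output directory.
#' @param n_recordings Number of recordings in the session.
#' @param interval_min Minutes between recording starts.
#' @param decay_s,k_mad,noise_scale Onset-inference parameters.
#' @param threshold_fraction Population event threshold (NULL = size rule).
#' @param amp_thresh_mv,min_dur_s,merge_gap_s Ephys detection parameters.
#' @param bin_min Timeline bin width (minutes).
#' @param n_shuffles Stationarity-filter permutations.
#' @return Invisibly, a list with all computed results (`cr_points`,
#'   `aligned_cr`, `lag_stats`, `fraction_points`, `aligned_fraction`,
#'   `pairs`, `before_after`, `profiles`, `intensity`, `matches`).
#' @export
run_pipeline <- function(config, out_dir, n_recordings = 8,
                         interval_min = 10, decay_s = NULL, k_mad = 3,
                         noise_scale = 3, threshold_fraction = NULL,
                         amp_thresh_mv = 5, min_dur_s = 0.2,
                         merge_gap_s = 0.5, bin_min = 20, n_shuffles = 200) {
  config <- validate_experiment_config(config)
  decay_s <- decay_s %||% config$calcium_decay_s
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("tcrecruit pipeline run")
  logf("seed=%d n_recordings=%d interval_min=%g", config$seed, n_recordings,
       interval_min)
  logf("onset: decay_s=%g k_mad=%g noise_scale=%s", decay_s, k_mad,
       format(noise_scale))
  logf("events: threshold_fraction=%s amp_thresh_mv=%g min_dur_s=%g merge_gap_s=%g",
       if (is.null(threshold_fraction)) "population-size rule" else
         format(threshold_fraction), amp_thresh_mv, min_dur_s, merge_gap_s)
  logf("timeline: bin_min=%g threshold=0.5; stationarity: n_shuffles=%d (10th-90th pct)",
       bin_min, n_shuffles)

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop_tc("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    logf("stage %s: ok", name)
    res
  }

  starts <- (seq_len(n_recordings) - 1L) * interval_min * 60
  sims <- stage("simulate", simulate_session(config, starts))

  per_rec <- stage("detect+match", purrr::imap(sims, function(sim, k) {
    ras <- infer_onsets(sim$imaging_cortex, decay_s = decay_s, k_mad = k_mad,
                        noise_scale = noise_scale)
    ev_c <- detect_circuit_events(ras, threshold_fraction = threshold_fraction,
                                  merge_gap_s = merge_gap_s)
    ev_c$area <- "cortex"
    ev_t <- detect_ephys_discharges(sim$ephys_thalamus,
                                    amp_thresh_mv = amp_thresh_mv,
                                    min_dur_s = min_dur_s,
                                    merge_gap_s = merge_gap_s)
    matches <- match_discharges(ev_c, ev_t)
    cr <- if (nrow(ev_c)) coupling_reliability(matches) else NA_real_
    fc <- suppressWarnings(
      fraction_correlated_cells(sim$imaging_cortex, sim$ephys_thalamus))
    list(k = k, sim = sim, raster = ras, events_cortex = ev_c,
         events_thalamus = ev_t, matches = matches, cr = cr,
         fraction_correlated = fc$fraction)
  }))

  mid <- starts / 60 + config$duration_s / 120
  cr_points <- tibble(slice_id = "slice1", time_min = mid,
                      value = purrr::map_dbl(per_rec, "cr"),
                      n_cortical_events = purrr::map_dbl(
                        per_rec, function(p) nrow(p$events_cortex)))
  fraction_points <- tibble(slice_id = "slice1", time_min = mid,
                            value = purrr::map_dbl(per_rec,
                                                   "fraction_correlated"))
  aligned_cr <- tryCatch(
    align_timeline(cr_points, bin_min = bin_min),
    error = function(e) { logf("aligned CR: %s", conditionMessage(e)); NULL })
  aligned_fraction <- tryCatch(
    align_timeline(fraction_points, bin_min = bin_min),
    error = function(e) { logf("aligned fraction: %s",
                               conditionMessage(e)); NULL })

  all_matches <- bind_rows(purrr::map(per_rec, "matches"))
  lag_stats <- if (any(all_matches$matched)) lag_statistics(all_matches) else
    tibble(median_lag_s = NA_real_, fraction_cortex_leading = NA_real_,
           n_matched = 0L)

  # before/after split at the CR crossing
  pairs <- NULL; ba <- NULL; profiles <- NULL
  cross <- which(cr_points$value >= 0.5)
  if (length(cross) && cross[1] > 2 && n_recordings - cross[1] >= 1) {
    before <- purrr::map(per_rec[seq_len(cross[1] - 1L)],
                         function(p) p$sim$imaging_cortex)
    after <- purrr::map(per_rec[cross[1]:n_recordings],
                        function(p) p$sim$imaging_cortex)
    if (length(before) >= 2L && length(after) >= 2L) {
      pw <- stage("pairwise", pairwise_correlations(
        before, after, decay_s = decay_s, k_mad = k_mad,
        noise_scale = noise_scale, threshold_fraction = threshold_fraction,
        n_shuffles = n_shuffles, seed = config$seed))
      pairs <- pw$pairs
      logf("pairwise: %d eligible cells, %d excluded non-stationary",
           sum(pw$cells$eligible), pw$n_excluded_nonstationary)
      ba <- before_after_test(pairs)
      profiles <- list(before = spatial_profile(pairs, "r_before"),
                       after = spatial_profile(pairs, "r_after"))
    }
  }
  if (is.null(pairs)) logf("pairwise: skipped (no usable before/after split)")

  # intensity coupling over the whole session (one FOV)
  ever <- ever_active_cells(purrr::map(per_rec, "raster"))
  ipairs <- bind_rows(purrr::map(per_rec, function(p) {
    if (!nrow(p$matches)) return(NULL)
    intensity_pairs(p$matches, p$raster, p$sim$ephys_thalamus, ever)
  }))
  intensity <- if (!is.null(ipairs) && nrow(ipairs) >= 3L) {
    intensity_correlation(ipairs)
  } else NULL

  # artifacts
  write_events(bind_rows(purrr::map(per_rec, "events_cortex")),
               file.path(out_dir, "events_cortex.tsv"))
  write_events(bind_rows(purrr::map(per_rec, "events_thalamus")),
               file.path(out_dir, "events_thalamus.tsv"))
  write_matches(all_matches, file.path(out_dir, "matches.tsv"))
  readr::write_tsv(cr_points, file.path(out_dir, "cr_points.tsv"))
  readr::write_tsv(fraction_points, file.path(out_dir, "fraction_points.tsv"))
  if (!is.null(pairs)) readr::write_tsv(pairs, file.path(out_dir, "pairs.tsv"))
  if (!is.null(ipairs)) readr::write_tsv(ipairs,
                                         file.path(out_dir, "intensity.tsv"))

  summary <- list(
    cr_per_recording = cr_points$value,
    aligned_cr_bins = if (!is.null(aligned_cr)) aligned_cr$bins else NULL,
    median_lag_s = lag_stats$median_lag_s,
    fraction_cortex_leading = lag_stats$fraction_cortex_leading,
    n_matched = lag_stats$n_matched,
    fraction_correlated_per_recording = fraction_points$value,
    aligned_fraction_bins = if (!is.null(aligned_fraction))
      aligned_fraction$bins else NULL,
    before_after = if (!is.null(ba))
      list(mean_diff = ba$mean_diff, p_value = ba$p_value) else NULL,
    intensity = if (!is.null(intensity))
      list(r = intensity$r, p_value = intensity$p_value,
           significant = intensity$significant) else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logf("done")

  invisible(list(cr_points = cr_points, aligned_cr = aligned_cr,
                 lag_stats = lag_stats, fraction_points = fraction_points,
                 aligned_fraction = aligned_fraction, pairs = pairs,
                 before_after = ba, profiles = profiles,
                 intensity = intensity, intensity_table = ipairs,
                 matches = all_matches, per_recording = per_rec))
}
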