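#' Cells ever active in any recording from one field of view
#'
#' The denominator of the cortical discharge-intensity measure: every cell
#' with at least one detected onset in any recording obtained from the same
#' FOV.
#'
#' @param rasters List of `onset_raster`s sharing the same cell index space.
#' @return Sorted integer vector of cell ids.
#' @export
ever_active_cells <- function(rasters) {
  if (!length(rasters)) stop_tc("need at least one raster")
  act <- Reduce(`|`, purrr::map(rasters, function(r) rowSums(r$onsets) > 0))
  sort(which(act))
}

#' Cortical discharge intensity: fraction of ever-active cells recruited
#'
#' Number of distinct cells with at least one onset inside the discharge
#' interval `[onset_s, offset_s]`, divided by the number of cells ever
#' active in the FOV.
#'
#' @param event One-row event (list or tibble row) with `onset_s`,
#'   `offset_s` in absolute seconds.
#' @param raster The `onset_raster` covering the event.
#' @param ever_active Integer ids from [ever_active_cells()].
#' @return A fraction in `[0, 1]`.
#' @export
cortical_intensity <- function(event, raster, ever_active) {
  if (!length(ever_active)) stop_tc("`ever_active` must be nonempty")
  ft <- raster$frame_times_s
  if (event$onset_s > max(ft) || event$offset_s < min(ft)) {
    stop_tc("event lies outside the raster's span")
  }
  fr <- which(ft >= event$onset_s & ft <= event$offset_s)
  active <- which(rowSums(raster$onsets[, fr, drop = FALSE]) > 0)
  length(intersect(active, ever_active)) / length(ever_active)
}

#' Thalamic discharge intensity: depolarization area under the curve
#'
#' Trapezoid integral of `max(Vm - baseline, 0)` over the discharge window
#' (mV·s). The baseline is the same 30 s running median used by
#' [detect_ephys_discharges()]; only the depolarizing part of the trace
#' contributes (hyperpolarizing excursions are clipped at zero so they
#' cannot cancel signal).
#'
#' @param event One-row event with `onset_s`, `offset_s` (absolute s).
#' @param ephys An [ephys_recording()] covering the event.
#' @param baseline_window_s Running-median window (s).
#' @param baseline Optional precomputed baseline vector (one value per
#'   sample); callers measuring many events on one trace compute it once.
#' @return AUC in mV·s.
#' @export
thalamic_intensity <- function(event, ephys, baseline_window_s = 30,
                               baseline = NULL) {
  st <- frame_times(ephys)
  if (event$onset_s < min(st) || event$offset_s > max(st)) {
    stop_tc("event lies outside the trace's span")
  }
  base <- baseline %||% running_median_baseline(ephys$vm_mv,
                                                ephys$sample_rate_hz,
                                                baseline_window_s)
  dep <- pmax(ephys$vm_mv - base, 0)
  sel <- which(st >= event$onset_s & st <= event$offset_s)
  if (length(sel) < 2L) return(0)
  sum(diff(st[sel]) * (dep[sel][-1] + dep[sel][-length(sel)]) / 2)
}

#' Per-discharge cortico-thalamic intensity pairs
#'
#' For every matched discharge, measures the cortical fraction of activated
#' cells and the thalamic depolarization AUC over the discharge window. The
#' window is the cortical `[onset, offset]` extended to the matched thalamic
#' offset when that is later (the thalamic discharge lags cortex, and
#' truncating at the cortical offset would bias the AUC low).
#'
#' @param matches Tibble from [match_discharges()].
#' @param raster Cortical `onset_raster` covering the events.
#' @param ephys Thalamic [ephys_recording()].
#' @param ever_active Ids from [ever_active_cells()] for the cortical FOV.
#' @return A tibble: `event`, `cortical_fraction`, `thalamic_auc_mv_s`,
#'   `matched`.
#' @export
intensity_pairs <- function(matches, raster, ephys, ever_active) {
  base <- running_median_baseline(ephys$vm_mv, ephys$sample_rate_hz)
  rows <- purrr::map(seq_len(nrow(matches)), function(k) {
    m <- matches[k, ]
    end_s <- max(m$cortical_offset_s,
                 if (isTRUE(m$matched)) m$thalamic_offset_s else -Inf)
    win <- list(onset_s = m$cortical_onset_s, offset_s = end_s)
    tibble(event = k,
           cortical_fraction = cortical_intensity(win, raster, ever_active),
           thalamic_auc_mv_s = thalamic_intensity(win, ephys, baseline = base),
           matched = m$matched)
  })
  bind_rows(rows)
}

#' Correlation between cortical and thalamic discharge intensities
#'
#' Pearson correlation across discharges, two-sided p-value; the FOV/ephys
#' pairing counts as correlated when p < `p_max`. Zero variance on either
#' axis leaves r undefined (not significant) with a warning.
#'
#' @param pairs Tibble from [intensity_pairs()] (columns
#'   `cortical_fraction`, `thalamic_auc_mv_s`), or any tibble with those
#'   columns; needs >= 3 rows.
#' @param p_max Significance level (default 0.05).
#' @return Object of class `tc_test` with `r`, `p_value`, `significant`,
#'   `n`. Supports [tidy()] and [glance()].
#' @export
intensity_correlation <- function(pairs, p_max = 0.05) {
  if (nrow(pairs) < 3L) stop_tc("need >= 3 discharge intensity pairs")
  x <- pairs$cortical_fraction
  y <- pairs$thalamic_auc_mv_s
  if (sd(x) == 0 || sd(y) == 0) {
    warn_tc("zero variance in an intensity axis; r undefined")
    return(new_tc_test(r = NA_real_, p_value = NA_real_, significant = FALSE,
                       n = nrow(pairs), method = "Pearson (degenerate)"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  new_tc_test(r = unname(ct$estimate), p_value = ct$p.value,
              significant = ct$p.value < p_max, n = nrow(pairs),
              method = ct$method)
}
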