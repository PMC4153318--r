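#' Detect population discharges in an onset raster
#'
#' Per frame, counts the distinct cells with an onset within a trailing
#' window of `window_frames` frames. An epileptiform circuit event starts at
#' the first frame where the count reaches `ceiling(threshold_fraction *
#' n_cells)` and ends when the count falls back below it; events separated by
#' less than `merge_gap_s` are merged.
#'
#' The default threshold fraction follows the published rule: 0.25% of cells
#' for populations under 400 cells, 0.33% at 1100 cells, linearly
#' interpolated in between (clamped outside). These printed percentages imply
#' a required count of only a few cells; pass `threshold_fraction` explicitly
#' to use another rule (e.g. 0.25 for 25%).
#'
#' @param raster An `onset_raster` from [binarize_onsets()].
#' @param threshold_fraction Fraction of cells that must fire to open an
#'   event; `NULL` (default) applies the population-size-dependent rule.
#' @param window_frames Trailing window defining "simultaneous" onsets
#'   (default 1, the strictest reading).
#' @param merge_gap_s Events closer than this are merged (s).
#' @return A tibble of discharge events: `recording_id`, `onset_s`,
#'   `offset_s`, `area` (NA here; set by callers that know it), `source`
#'   (`"imaging"`), `n_cells_active`.
#' @examples
#' on <- matrix(0L, 10, 50); on[1:5, 25] <- 1L
#' ras <- structure(list(onsets = on, frame_times_s = (0:49) / 10,
#'                       frame_rate_hz = 10, recording_id = "demo"),
#'                  class = "onset_raster")
#' detect_circuit_events(ras, threshold_fraction = 0.3)
#' @export
detect_circuit_events <- function(raster, threshold_fraction = NULL,
                                  window_frames = 1L, merge_gap_s = 0.5) {
  stopifnot(inherits(raster, "onset_raster"))
  if (window_frames < 1L) stop_tc("`window_frames` must be >= 1")
  on <- raster$onsets
  n_cells <- nrow(on)
  n_frames <- ncol(on)
  if (n_frames == 0L || n_cells == 0L) return(empty_events())
  if (is.null(threshold_fraction)) {
    threshold_fraction <- default_threshold_fraction(n_cells)
  }
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    stop_tc("`threshold_fraction` must be in (0, 1]")
  }
  required <- ceiling(threshold_fraction * n_cells)
  if (required < 1L) stop_tc("threshold yields a required count of 0 cells")

  # distinct cells with >= 1 onset in the trailing window
  if (window_frames == 1L) {
    count <- colSums(on > 0)
  } else {
    cs <- cbind(0, t(apply(on, 1, cumsum)))
    lo <- pmax(seq_len(n_frames) - window_frames + 1L, 1L)
    hit <- cs[, seq_len(n_frames) + 1L, drop = FALSE] -
      cs[, lo, drop = FALSE] > 0
    count <- colSums(hit)
  }

  above <- count >= required
  if (!any(above)) return(empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- tibble(start = starts[r$values], end = ends[r$values])

  dt <- 1 / raster$frame_rate_hz
  ft <- raster$frame_times_s
  ev <- tibble(onset_s = ft[seg$start], offset_s = ft[seg$end] + dt)
  ev <- merge_events(ev, merge_gap_s)
  ev$n_cells_active <- vapply(seq_len(nrow(ev)), function(k) {
    fr <- which(ft >= ev$onset_s[k] & ft < ev$offset_s[k])
    sum(rowSums(on[, fr, drop = FALSE]) > 0)
  }, integer(1))
  tibble(recording_id = raster$recording_id, onset_s = ev$onset_s,
         offset_s = ev$offset_s, area = NA_character_, source = "imaging",
         n_cells_active = ev$n_cells_active)
}

# Published population-size rule: 0.25% below 400 cells, 0.33% at 1100,
# linear in between.
default_threshold_fraction <- function(n_cells) {
  if (n_cells < 400) return(0.0025)
  if (n_cells >= 1100) return(0.0033)
  0.0025 + (0.0033 - 0.0025) * (n_cells - 400) / (1100 - 400)
}

empty_events <- function() {
  tibble(recording_id = character(), onset_s = numeric(),
         offset_s = numeric(), area = character(), source = character(),
         n_cells_active = integer())
}

merge_events <- function(ev, merge_gap_s) {
  if (nrow(ev) <= 1L) return(ev)
  ev <- arrange(ev, .data$onset_s)
  on <- ev$onset_s[1]; off <- ev$offset_s[1]
  res_on <- numeric(0); res_off <- numeric(0)
  for (k in seq_len(nrow(ev))[-1]) {
    if (ev$onset_s[k] - off < merge_gap_s - 1e-9) {
      off <- max(off, ev$offset_s[k])
    } else {
      res_on <- c(res_on, on); res_off <- c(res_off, off)
      on <- ev$onset_s[k]; off <- ev$offset_s[k]
    }
  }
  tibble(onset_s = c(res_on, on), offset_s = c(res_off, off))
}

#' Detect epileptiform discharges in a membrane-potential trace
#'
#' The baseline is a running median over a 30 s window (global median, with a
#' warning, for shorter traces). An event is a maximal interval where the
#' voltage exceeds baseline + `amp_thresh_mv` for at least `min_dur_s`;
#' events closer than `merge_gap_s` are merged. Onset is the first threshold
#' crossing.
#'
#' @param rec An [ephys_recording()].
#' @param amp_thresh_mv Depolarization threshold above baseline (mV).
#' @param min_dur_s Minimum event duration (s).
#' @param merge_gap_s Events closer than this are merged (s).
#' @param baseline_window_s Running-median window (s).
#' @return A tibble of discharge events with `source = "ephys"` and the
#'   recording's area filled in.
#' @export
detect_ephys_discharges <- function(rec, amp_thresh_mv = 5, min_dur_s = 0.2,
                                    merge_gap_s = 0.5,
                                    baseline_window_s = 30) {
  stopifnot(inherits(rec, "ephys_recording"))
  if (amp_thresh_mv <= 0) stop_tc("`amp_thresh_mv` must be > 0")
  fs <- rec$sample_rate_hz
  vm <- rec$vm_mv
  base <- running_median_baseline(vm, fs, baseline_window_s)
  above <- vm > base + amp_thresh_mv
  if (!any(above)) return(empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- tibble(start = starts[r$values], end = ends[r$values])
  t0 <- rec$start_time_s
  ev <- tibble(onset_s = t0 + (seg$start - 1L) / fs,
               offset_s = t0 + seg$end / fs)
  ev <- ev[ev$offset_s - ev$onset_s >= min_dur_s, , drop = FALSE]
  if (!nrow(ev)) return(empty_events())
  ev <- merge_events(ev, merge_gap_s)
  tibble(recording_id = rec$recording_id, onset_s = ev$onset_s,
         offset_s = ev$offset_s, area = rec$area, source = "ephys",
         n_cells_active = NA_integer_)
}

#' Write detected events as a tab-separated table
#'
#' Columns: recording_id, onset_s, offset_s, area, source, n_cells_active;
#' times printed with six decimals.
#'
#' @param events Event tibble from the detectors.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events |>
    mutate(onset_s = sprintf("%.6f", .data$onset_s),
           offset_s = sprintf("%.6f", .data$offset_s))
  readr::write_tsv(out, path)
  invisible(path)
}
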