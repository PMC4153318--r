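#' Infer a non-negative spiking signal from calcium fluorescence
#'
#' First-order sparse non-negative deconvolution. The calcium trace is
#' modelled as an AR(1) process: each spike adds an impulse that decays as
#' `exp(-dt / decay_s)` per frame. A slow per-cell baseline (running 20th
#' percentile over a 30 s window) is removed, the AR(1) kernel is inverted
#' (`s_t = f_t - gamma * f_{t-1}`), negative residuals are clipped to zero,
#' and values the noise model explains without activity (below
#' `noise_scale` robust noise SDs, estimated per cell from the first
#' differences of the baseline-subtracted trace) are set to zero.
#'
#' @param rec An [imaging_recording()].
#' @param decay_s Calcium decay time constant in seconds (default 1.0,
#'   appropriate for a synthetic-dye indicator at room temperature).
#' @param noise_scale Zeroing threshold in robust noise SDs; `NULL` disables
#'   the noise floor (useful on noiseless data). Default 3.
#' @param baseline_window_s Width of the running-percentile baseline window.
#' @param baseline_percentile Percentile used for the baseline (default 0.2,
#'   robust to discharge-dense epochs).
#' @return A non-negative numeric matrix (cells x frames), one deconvolved
#'   activity signal per cell.
#' @examples
#' cfg <- experiment_config(duration_s = 30, n_cells_cortex = 5,
#'                          n_cells_thalamus = 5, noise_sd = 0, seed = 2)
#' truth <- generate_event_schedule(cfg)
#' rec <- render_fluorescence(truth, cfg, "cortex")
#' sig <- infer_spike_signal(rec, decay_s = cfg$calcium_decay_s)
#' range(sig)
#' @export
infer_spike_signal <- function(rec, decay_s = 1.0, noise_scale = 3,
                               baseline_window_s = 30,
                               baseline_percentile = 0.2) {
  if (!inherits(rec, "imaging_recording")) {
    stop_tc("`rec` must be an imaging_recording")
  }
  if (is.null(rec$frame_rate_hz) || !is.finite(rec$frame_rate_hz)) {
    stop_tc("frame rate is missing")
  }
  if (!is.numeric(decay_s) || decay_s <= 0) stop_tc("`decay_s` must be > 0")
  rate <- rec$frame_rate_hz
  if (decay_s < 1 / rate) {
    warn_tc("`decay_s` shorter than one frame; clamping to one frame")
    decay_s <- 1 / rate
  }
  gamma <- exp(-1 / (rate * decay_s))
  fl <- rec$fluorescence
  n_frames <- ncol(fl)
  out <- matrix(0, nrow(fl), n_frames)
  for (i in seq_len(nrow(fl))) {
    x <- fl[i, ]
    b <- running_percentile(x, rate, baseline_window_s, baseline_percentile)
    xb <- x - b
    s <- xb - gamma * c(0, xb[-n_frames])
    s[1] <- 0
    s[s < 0] <- 0
    if (!is.null(noise_scale)) {
      sigma <- stats::mad(diff(xb)) / sqrt(2)
      # the relative term suppresses ripple from the interpolated baseline
      # (a few percent of the transient amplitude on noiseless traces)
      s[s < max(noise_scale * sigma, 0.05 * max(s))] <- 0
    }
    out[i, ] <- s
  }
  out
}

#' Binarize a deconvolved signal into firing onsets
#'
#' Per cell, the threshold is `median + k_mad * MAD` of that cell's signal;
#' an onset is marked at every frame where the signal crosses the threshold
#' from below (rising edges only, one onset per crossing). An all-constant
#' signal yields no onsets.
#'
#' @param signal Non-negative matrix (cells x frames) from
#'   [infer_spike_signal()].
#' @param k_mad Threshold multiplier (default 3).
#' @param frame_rate_hz Frame rate of the source recording (Hz).
#' @param start_time_s Absolute time of the first frame (s).
#' @param recording_id Identifier carried into the raster.
#' @return An object of class `onset_raster`: list with binary `onsets`
#'   matrix (cells x frames), `frame_times_s`, and `recording_id`.
#' @export
binarize_onsets <- function(signal, k_mad = 3, frame_rate_hz,
                            start_time_s = 0, recording_id = "rec") {
  if (!is.numeric(k_mad) || k_mad <= 0) stop_tc("`k_mad` must be > 0")
  signal <- as.matrix(signal)
  n_frames <- ncol(signal)
  onsets <- matrix(0L, nrow(signal), n_frames)
  for (i in seq_len(nrow(signal))) {
    s <- signal[i, ]
    thr <- stats::median(s) + k_mad * stats::mad(s)
    above <- s > thr
    rising <- above & !c(FALSE, above[-n_frames])
    onsets[i, rising] <- 1L
  }
  structure(
    list(onsets = onsets,
         frame_times_s = start_time_s + (seq_len(n_frames) - 1L) / frame_rate_hz,
         frame_rate_hz = frame_rate_hz,
         recording_id = recording_id),
    class = "onset_raster"
  )
}

#' Infer onsets for a whole recording
#'
#' Convenience chain of [infer_spike_signal()] and [binarize_onsets()].
#'
#' @inheritParams infer_spike_signal
#' @inheritParams binarize_onsets
#' @return An `onset_raster`.
#' @export
infer_onsets <- function(rec, decay_s = 1.0, k_mad = 3, noise_scale = 3,
                         baseline_window_s = 30) {
  sig <- infer_spike_signal(rec, decay_s = decay_s, noise_scale = noise_scale,
                            baseline_window_s = baseline_window_s)
  binarize_onsets(sig, k_mad = k_mad, frame_rate_hz = rec$frame_rate_hz,
                  start_time_s = rec$start_time_s,
                  recording_id = rec$recording_id)
}

#' @export
print.onset_raster <- function(x, ...) {
  cat(sprintf("<onset_raster '%s'> %d cells x %d frames, %d onsets\n",
              x$recording_id, nrow(x$onsets), ncol(x$onsets), sum(x$onsets)))
  invisible(x)
}

#' Tidy an onset raster into a (cell, frame, time) tibble
#'
#' @param x An `onset_raster`.
#' @param ... Unused.
#' @return A tibble with one row per onset: `cell`, `frame`, `time_s`.
#' @export
tidy.onset_raster <- function(x, ...) {
  idx <- which(x$onsets == 1L, arr.ind = TRUE)
  tibble(cell = as.integer(idx[, 1]), frame = as.integer(idx[, 2]),
         time_s = x$frame_times_s[idx[, 2]]) |>
    arrange(.data$time_s, .data$cell)
}
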