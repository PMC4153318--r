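#' Configuration for a synthetic two-area slice experiment
#'
#' Bundles every parameter of the synthetic-data generator: recording
#' geometry, the discharge renewal process, the time-varying
#' cortex-to-thalamus coupling probability, the cortico-thalamic lag
#' distribution, distance-correlated per-event participation, the calcium
#' forward model, bleaching drift, and the voltage-trace envelope model.
#'
#' Defaults emulate the recordings the analyses were designed for: two-minute
#' recordings, imaging at 10 Hz over a few hundred cells in a 400-um field of
#' view, kHz-rate membrane potential, recurring epileptiform discharges a few
#' per minute, and a positive right-skewed cortico-thalamic onset lag with a
#' median of 66 ms.
#'
#' @param duration_s Recording duration in seconds.
#' @param imaging_rate_hz Imaging frame rate (Hz).
#' @param ephys_rate_hz Voltage sampling rate (Hz).
#' @param n_cells_cortex,n_cells_thalamus Number of imaged cells per area.
#' @param fov_size_um Side length of the square field of view (um).
#' @param event_rate_hz Rate parameter of the discharge renewal process
#'   (exponential waiting times on top of a refractory floor).
#' @param refractory_s Minimum gap between consecutive discharges (s).
#' @param coupling_schedule Function mapping absolute experiment time (s) to
#'   the probability, in `[0, 1]`, that a cortical discharge recruits
#'   thalamus. Must be vectorised over time.
#' @param lag_median_s Median of the log-normal cortico-thalamic onset lag (s).
#' @param lag_spread Log-scale standard deviation of the lag distribution.
#' @param participation_base Baseline probability that a cell joins a
#'   discharge, before spatial hotspot modulation.
#' @param event_intensity_range Range of the per-event intensity factor
#'   shared by both areas: each discharge draws one factor uniformly from
#'   this interval and scales every cell's participation probability with
#'   it, so strong discharges recruit more cells in cortex *and* drive a
#'   larger thalamic depolarization. Set to `c(1, 1)` for equal-intensity
#'   events.
#' @param spatial_corr_length_um Length scale (um) of the Gaussian hotspots
#'   that induce distance-correlated participation.
#' @param calcium_decay_s Decay time constant of the AR(1) calcium kernel (s).
#' @param transient_amplitude Fluorescence jump per spike (dF units).
#' @param noise_sd Additive Gaussian noise on fluorescence (dF units).
#' @param bleach_fraction Fraction of cells given a linear baseline drift.
#' @param bleach_slope Drift slope for those cells (dF units per second;
#'   negative values emulate bleaching).
#' @param discharge_amp_mv Peak depolarization of a full-participation
#'   discharge envelope (mV).
#' @param discharge_dur_s Duration of the discharge envelope (s).
#' @param vm_noise_sd_mv Additive Gaussian noise on the voltage trace (mV).
#' @param seed Master seed; every stage derives its own stream from it.
#'
#' @return An object of class `experiment_config` (a validated named list).
#' @examples
#' cfg <- experiment_config(duration_s = 60, n_cells_cortex = 50,
#'                          n_cells_thalamus = 40, seed = 7)
#' cfg$event_rate_hz
#' @export
experiment_config <- function(duration_s = 120,
                              imaging_rate_hz = 10,
                              ephys_rate_hz = 1000,
                              n_cells_cortex = 300,
                              n_cells_thalamus = 300,
                              fov_size_um = 400,
                              event_rate_hz = 0.1,
                              refractory_s = 2,
                              coupling_schedule = function(t) rep(1, length(t)),
                              lag_median_s = 0.066,
                              lag_spread = 0.5,
                              participation_base = 0.3,
                              event_intensity_range = c(0.4, 1),
                              spatial_corr_length_um = 100,
                              calcium_decay_s = 1.0,
                              transient_amplitude = 1.0,
                              noise_sd = 0.05,
                              bleach_fraction = 0.2,
                              bleach_slope = -0.002,
                              discharge_amp_mv = 20,
                              discharge_dur_s = 1.0,
                              vm_noise_sd_mv = 0.3,
                              seed = 1L) {
  cfg <- list(
    duration_s = duration_s, imaging_rate_hz = imaging_rate_hz,
    ephys_rate_hz = ephys_rate_hz, n_cells_cortex = n_cells_cortex,
    n_cells_thalamus = n_cells_thalamus, fov_size_um = fov_size_um,
    event_rate_hz = event_rate_hz, refractory_s = refractory_s,
    coupling_schedule = coupling_schedule, lag_median_s = lag_median_s,
    lag_spread = lag_spread, participation_base = participation_base,
    event_intensity_range = event_intensity_range,
    spatial_corr_length_um = spatial_corr_length_um,
    calcium_decay_s = calcium_decay_s,
    transient_amplitude = transient_amplitude, noise_sd = noise_sd,
    bleach_fraction = bleach_fraction, bleach_slope = bleach_slope,
    discharge_amp_mv = discharge_amp_mv, discharge_dur_s = discharge_dur_s,
    vm_noise_sd_mv = vm_noise_sd_mv, seed = as.integer(seed)
  )
  class(cfg) <- "experiment_config"
  validate_experiment_config(cfg)
}

validate_experiment_config <- function(cfg) {
  num_pos <- c("duration_s", "imaging_rate_hz", "ephys_rate_hz",
               "event_rate_hz", "lag_median_s", "calcium_decay_s",
               "discharge_dur_s", "fov_size_um")
  for (f in num_pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop_tc("`", f, "` must be a single positive number")
    }
  }
  if (cfg$n_cells_cortex < 1 || cfg$n_cells_thalamus < 1) {
    stop_tc("cell counts must be >= 1")
  }
  if (!is.function(cfg$coupling_schedule)) {
    stop_tc("`coupling_schedule` must be a function of time")
  }
  probe <- cfg$coupling_schedule(seq(0, cfg$duration_s, length.out = 16))
  if (any(probe < 0 | probe > 1)) {
    stop_tc("`coupling_schedule` must take values in [0, 1]")
  }
  if (cfg$participation_base < 0 || cfg$participation_base > 1 ||
      cfg$bleach_fraction < 0 || cfg$bleach_fraction > 1) {
    stop_tc("probabilities/fractions must lie in [0, 1]")
  }
  if (cfg$lag_spread < 0 || cfg$noise_sd < 0 || cfg$vm_noise_sd_mv < 0) {
    stop_tc("spreads and noise SDs must be non-negative")
  }
  ir <- cfg$event_intensity_range
  if (length(ir) != 2L || any(ir <= 0) || any(ir > 1) || ir[1] > ir[2]) {
    stop_tc("`event_intensity_range` must be an increasing pair in (0, 1]")
  }
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(sprintf("  %g s at %g Hz imaging / %g Hz ephys\n",
              x$duration_s, x$imaging_rate_hz, x$ephys_rate_hz))
  cat(sprintf("  cells: %d cortex, %d thalamus in a %g um FOV\n",
              x$n_cells_cortex, x$n_cells_thalamus, x$fov_size_um))
  cat(sprintf("  discharges: rate %g Hz, refractory %g s; lag median %g s\n",
              x$event_rate_hz, x$refractory_s, x$lag_median_s))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read an experiment configuration from a YAML or JSON file
#'
#' Scalar fields mirror the arguments of [experiment_config()]. The coupling
#' schedule is described declaratively: either `coupling_constant: p`, or
#' `coupling_step: {time_s: t, before: p0, after: p1}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sched <- NULL
  if (!is.null(raw$coupling_constant)) {
    p <- raw$coupling_constant
    sched <- function(t) rep(p, length(t))
  } else if (!is.null(raw$coupling_step)) {
    st <- raw$coupling_step
    sched <- step_schedule(st$time_s, before = st$before %||% 0,
                           after = st$after %||% 1)
  }
  raw$coupling_constant <- NULL
  raw$coupling_step <- NULL
  args <- raw[names(raw) %in% names(formals(experiment_config))]
  if (!is.null(sched)) args$coupling_schedule <- sched
  do.call(experiment_config, args)
}

#' Step coupling schedule
#'
#' Convenience constructor for the step-like recruitment profile: coupling
#' probability `before` until `time_s`, then `after`.
#'
#' @param time_s Step time in seconds of absolute experiment time.
#' @param before,after Coupling probabilities on either side of the step.
#' @return A vectorised function of time, usable as a `coupling_schedule`.
#' @export
step_schedule <- function(time_s, before = 0, after = 1) {
  force(time_s); force(before); force(after)
  function(t) ifelse(t < time_s, before, after)
}
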