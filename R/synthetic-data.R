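#' Generate the ground-truth discharge schedule for a synthetic slice
#'
#' Draws cortical epileptiform discharge times from a renewal process
#' (exponential waiting times with a refractory floor), decides per discharge
#' whether thalamus is recruited using the time-varying coupling schedule,
#' samples a positive right-skewed (log-normal) cortico-thalamic onset lag
#' for each coupled discharge, and samples per-cell participation with
#' distance-correlated structure: each event activates a few Gaussian spatial
#' hotspots, so nearby cells participate in similar subsets of events.
#'
#' Cell coordinates for both areas are drawn uniformly in the field of view
#' here so that participation can depend on them; the renderers reuse them.
#'
#' @param config An [experiment_config()].
#' @param coords Optional list with `cortex` and `thalamus` coordinate
#'   matrices (cells x 2, um) to reuse across recordings from one field of
#'   view; sampled uniformly when `NULL`.
#' @param drifting_cells Optional list with `cortex` and `thalamus` integer
#'   vectors fixing which cells drift (bleaching is a property of a cell,
#'   stable across a session); sampled when `NULL`.
#' @return An object of class `slice_truth`: a list with `event_times_s`,
#'   `thalamic_coupled`, `true_lags_s` (NA where uncoupled), per-area
#'   participation matrices (`active_cortex`, `active_thalamus`; cells x
#'   events), `per_event_participation` (tibble), `cell_spike_times`
#'   (per-area lists of per-cell spike-time vectors), cell coordinates, and
#'   `drifting_cells` per area.
#' @examples
#' cfg <- experiment_config(duration_s = 60, n_cells_cortex = 40,
#'                          n_cells_thalamus = 30, seed = 1)
#' truth <- generate_event_schedule(cfg)
#' truth$event_times_s
#' @export
generate_event_schedule <- function(config, coords = NULL,
                                    drifting_cells = NULL) {
  config <- validate_experiment_config(config)
  if (is.null(coords)) coords <- sample_fov_coords(config)
  if (is.null(drifting_cells)) drifting_cells <- sample_drifting_cells(config)
  set.seed(stage_seed(config$seed, "schedule"))

  # renewal process: refractory floor + exponential gaps; first event is
  # placed far enough in to leave room for pre-event baselines
  t_max <- config$duration_s
  times <- numeric(0)
  t_cur <- 3 + rexp(1, config$event_rate_hz)
  while (t_cur < t_max - config$discharge_dur_s) {
    times <- c(times, t_cur)
    t_cur <- t_cur + config$refractory_s + rexp(1, config$event_rate_hz)
  }
  n_ev <- length(times)

  p_couple <- if (n_ev) config$coupling_schedule(times) else numeric(0)
  coupled <- if (n_ev) rbinom(n_ev, 1L, p_couple) == 1L else logical(0)
  lags <- rep(NA_real_, n_ev)
  if (any(coupled)) {
    lags[coupled] <- rlnorm(sum(coupled), meanlog = log(config$lag_median_s),
                            sdlog = config$lag_spread)
  }

  coords_cortex <- coords$cortex
  coords_thalamus <- coords$thalamus
  stopifnot(nrow(coords_cortex) == config$n_cells_cortex,
            nrow(coords_thalamus) == config$n_cells_thalamus)

  # one intensity factor per discharge, shared by both areas, so strong
  # events recruit more cells everywhere (the basis of intensity coupling)
  intensity <- runif(n_ev, config$event_intensity_range[1],
                     config$event_intensity_range[2])
  active_cortex <- draw_participation(times, coords_cortex, config, intensity)
  # thalamic cells only participate in coupled events
  active_thalamus <- draw_participation(times, coords_thalamus, config,
                                        intensity)
  if (n_ev) active_thalamus[, !coupled] <- FALSE

  spikes_cortex <- participation_to_spikes(active_cortex, times)
  thal_onsets <- times + ifelse(is.na(lags), 0, lags)
  spikes_thalamus <- participation_to_spikes(active_thalamus, thal_onsets)

  drifting_cortex <- drifting_cells$cortex
  drifting_thalamus <- drifting_cells$thalamus

  part <- tibble(
    event = seq_len(n_ev),
    time_s = times,
    coupled = coupled,
    lag_s = lags,
    participation_cortex = if (n_ev) colMeans(active_cortex) else numeric(0),
    participation_thalamus = if (n_ev) colMeans(active_thalamus) else numeric(0)
  )

  structure(
    list(event_times_s = times, thalamic_coupled = coupled, true_lags_s = lags,
         active_cortex = active_cortex, active_thalamus = active_thalamus,
         per_event_participation = part,
         cell_spike_times = list(cortex = spikes_cortex,
                                 thalamus = spikes_thalamus),
         coords_um = list(cortex = coords_cortex, thalamus = coords_thalamus),
         drifting_cells = list(cortex = drifting_cortex,
                               thalamus = drifting_thalamus),
         config = config),
    class = "slice_truth"
  )
}

#' Sample uniform cell coordinates for both areas of a field of view
#'
#' Used internally by [generate_event_schedule()]; exposed so sessions can
#' fix one set of coordinates across recordings.
#'
#' @param config An [experiment_config()].
#' @return A list with `cortex` and `thalamus` (cells x 2) matrices in um.
#' @export
sample_fov_coords <- function(config) {
  set.seed(stage_seed(config$seed, "session") + 1L)
  list(cortex = matrix(runif(2L * config$n_cells_cortex, 0,
                             config$fov_size_um), ncol = 2L),
       thalamus = matrix(runif(2L * config$n_cells_thalamus, 0,
                               config$fov_size_um), ncol = 2L))
}

sample_drifting_cells <- function(config) {
  set.seed(stage_seed(config$seed, "session") + 2L)
  list(cortex = sort(sample.int(config$n_cells_cortex,
                                round(config$bleach_fraction *
                                        config$n_cells_cortex))),
       thalamus = sort(sample.int(config$n_cells_thalamus,
                                  round(config$bleach_fraction *
                                          config$n_cells_thalamus))))
}

# Per-event participation with spatial hotspots: probability is the base rate
# plus Gaussian bumps around a few random centers, scaled by the event's
# shared intensity factor and clipped to [0, 0.98].
draw_participation <- function(times, coords, config, intensity = NULL,
                               n_hotspots = 3L, hotspot_amp = 0.6) {
  n_cells <- nrow(coords)
  n_ev <- length(times)
  active <- matrix(FALSE, n_cells, n_ev)
  if (n_ev == 0L) return(active)
  if (is.null(intensity)) intensity <- rep(1, n_ev)
  L2 <- 2 * config$spatial_corr_length_um^2
  for (e in seq_len(n_ev)) {
    centers <- matrix(runif(2L * n_hotspots, 0, config$fov_size_um), ncol = 2L)
    d2 <- outer(coords[, 1], centers[, 1], "-")^2 +
      outer(coords[, 2], centers[, 2], "-")^2
    p <- config$participation_base + hotspot_amp * rowSums(exp(-d2 / L2))
    p <- intensity[e] * pmin(pmax(p, 0), 0.98)
    active[, e] <- runif(n_cells) < p
  }
  active
}

# One spike per participating cell per event, jittered within a tenth of a
# second after the population onset.
participation_to_spikes <- function(active, onset_times, jitter_s = 0.1) {
  lapply(seq_len(nrow(active)), function(i) {
    ev <- which(active[i, ])
    if (!length(ev)) return(numeric(0))
    sort(onset_times[ev] + runif(length(ev), 0, jitter_s))
  })
}

#' @export
print.slice_truth <- function(x, ...) {
  cat(sprintf("<slice_truth> %d discharges (%d coupled) over %g s; %d + %d cells\n",
              length(x$event_times_s), sum(x$thalamic_coupled),
              x$config$duration_s, x$config$n_cells_cortex,
              x$config$n_cells_thalamus))
  invisible(x)
}

#' Render calcium fluorescence traces from a ground-truth schedule
#'
#' Forward model: each spike adds a `transient_amplitude` impulse at the first
#' frame acquired after the spike, convolved with an exponential AR(1) kernel
#' of time constant `calcium_decay_s`; additive Gaussian noise; cells flagged
#' as drifting get a linear baseline ramp (`bleach_slope` per second).
#'
#' @param truth A `slice_truth` from [generate_event_schedule()].
#' @param config The same [experiment_config()] used for the schedule.
#' @param area `"cortex"` or `"thalamus"`.
#' @param start_time_s Absolute start time of the recording (s).
#' @param recording_id Identifier for the output recording.
#' @return An [imaging_recording()].
#' @export
render_fluorescence <- function(truth, config, area = c("cortex", "thalamus"),
                                start_time_s = 0, recording_id = NULL) {
  area <- match.arg(area)
  config <- validate_experiment_config(config)
  set.seed(stage_seed(config$seed, paste0("fluor_", area)))
  rate <- config$imaging_rate_hz
  n_frames <- floor(config$duration_s * rate)
  spikes <- truth$cell_spike_times[[area]]
  n_cells <- length(spikes)
  gamma <- exp(-1 / (rate * config$calcium_decay_s))

  fl <- matrix(0, n_cells, n_frames)
  for (i in seq_len(n_cells)) {
    imp <- numeric(n_frames)
    if (length(spikes[[i]])) {
      # impulse lands one frame after the frame containing the spike
      k <- floor(spikes[[i]] * rate) + 2L
      k <- k[k >= 1L & k <= n_frames]
      if (length(k)) {
        tab <- tabulate(k, nbins = n_frames)
        imp <- config$transient_amplitude * tab
      }
    }
    fl[i, ] <- stats::filter(imp, gamma, method = "recursive")
  }
  if (config$noise_sd > 0) {
    fl <- fl + matrix(rnorm(n_cells * n_frames, sd = config$noise_sd),
                      n_cells, n_frames)
  }
  drift <- truth$drifting_cells[[area]]
  if (length(drift) && config$bleach_slope != 0) {
    ramp <- config$bleach_slope * (seq_len(n_frames) - 1L) / rate
    fl[drift, ] <- fl[drift, , drop = FALSE] +
      matrix(ramp, length(drift), n_frames, byrow = TRUE)
  }
  imaging_recording(fl, frame_rate_hz = rate, start_time_s = start_time_s,
                    coords_um = truth$coords_um[[area]], area = area,
                    recording_id = recording_id %||% paste0("img_", area))
}

#' Render a membrane-potential trace from a ground-truth schedule
#'
#' Each discharge in the given area contributes a depolarizing
#' rise-plateau-decay envelope whose peak is that event's participation
#' fraction times `discharge_amp_mv` and whose duration is
#' `discharge_dur_s`; thalamic envelopes are shifted by the event's lag.
#' Additive Gaussian noise on a -65 mV resting baseline.
#'
#' @inheritParams render_fluorescence
#' @param baseline_mv Resting potential (mV).
#' @return An [ephys_recording()].
#' @export
render_ephys <- function(truth, config, area = c("cortex", "thalamus"),
                         start_time_s = 0, baseline_mv = -65,
                         recording_id = NULL) {
  area <- match.arg(area)
  config <- validate_experiment_config(config)
  set.seed(stage_seed(config$seed, paste0("ephys_", area)))
  fs <- config$ephys_rate_hz
  n <- floor(config$duration_s * fs)
  vm <- rep(baseline_mv, n)

  onsets <- truth$event_times_s
  part <- if (area == "cortex") {
    truth$per_event_participation$participation_cortex
  } else {
    onsets <- onsets + ifelse(is.na(truth$true_lags_s), 0, truth$true_lags_s)
    truth$per_event_participation$participation_thalamus
  }
  keep <- if (area == "thalamus") truth$thalamic_coupled else
    rep(TRUE, length(onsets))

  env <- discharge_envelope(config$discharge_dur_s, fs)
  for (e in which(keep)) {
    i0 <- floor(onsets[e] * fs) + 1L
    idx <- i0:(i0 + length(env) - 1L)
    ok <- idx >= 1L & idx <= n
    vm[idx[ok]] <- vm[idx[ok]] + part[e] * config$discharge_amp_mv * env[ok]
  }
  if (config$vm_noise_sd_mv > 0) vm <- vm + rnorm(n, sd = config$vm_noise_sd_mv)
  ephys_recording(vm, sample_rate_hz = fs, start_time_s = start_time_s,
                  area = area,
                  recording_id = recording_id %||% paste0("vm_", area))
}

# Unit-peak rise-plateau-decay envelope: 10% linear rise, 60% plateau,
# 30% linear decay of the total duration.
discharge_envelope <- function(dur_s, fs) {
  n <- max(3L, round(dur_s * fs))
  n_rise <- max(1L, round(0.1 * n))
  n_decay <- max(1L, round(0.3 * n))
  n_plat <- max(1L, n - n_rise - n_decay)
  c(seq(0, 1, length.out = n_rise + 1L)[-1L],
    rep(1, n_plat),
    seq(1, 0, length.out = n_decay + 1L)[-1L])
}

#' Simulate a complete two-area recording
#'
#' Convenience wrapper: draws a schedule and renders cortical imaging plus
#' cortical and thalamic voltage traces (thalamic imaging on request).
#'
#' @param config An [experiment_config()].
#' @param start_time_s Absolute start time of this recording within the
#'   experiment (s); the coupling schedule is evaluated at absolute time.
#' @param imaging Character vector of areas to render fluorescence for.
#' @param ephys Character vector of areas to render voltage for.
#' @param recording_id Identifier prefix.
#' @param coords,drifting_cells Optional fixed FOV structure (see
#'   [generate_event_schedule()]); used by [simulate_session()] so repeated
#'   recordings image the same cells.
#' @return A list with `truth` and any of `imaging_cortex`,
#'   `imaging_thalamus`, `ephys_cortex`, `ephys_thalamus`.
#' @export
simulate_recording <- function(config, start_time_s = 0,
                               imaging = "cortex",
                               ephys = c("cortex", "thalamus"),
                               recording_id = "rec", coords = NULL,
                               drifting_cells = NULL) {
  base_sched <- config$coupling_schedule
  cfg <- config
  # evaluate the experiment-level schedule at absolute time
  cfg$coupling_schedule <- function(t) base_sched(t + start_time_s)
  truth <- generate_event_schedule(cfg, coords = coords,
                                   drifting_cells = drifting_cells)
  out <- list(truth = truth)
  for (a in imaging) {
    out[[paste0("imaging_", a)]] <-
      render_fluorescence(truth, cfg, area = a, start_time_s = start_time_s,
                          recording_id = paste0(recording_id, "_img_", a))
  }
  for (a in ephys) {
    out[[paste0("ephys_", a)]] <-
      render_ephys(truth, cfg, area = a, start_time_s = start_time_s,
                   recording_id = paste0(recording_id, "_vm_", a))
  }
  out
}

#' Simulate a session of repeated recordings from one slice
#'
#' Emulates the experimental design: short recordings repeated every few
#' minutes across an hours-long session while the coupling probability
#' evolves (typically step-like recruitment). Each recording gets its own
#' derived seed.
#'
#' @param config An [experiment_config()]; its `coupling_schedule` is treated
#'   as a function of absolute session time.
#' @param start_times_s Numeric vector of recording start times (s).
#' @param ... Passed to [simulate_recording()].
#' @return A list of [simulate_recording()] results, one per start time.
#' @export
simulate_session <- function(config, start_times_s, ...) {
  # one FOV per session: coordinates and drifting cells are fixed across
  # recordings, only the discharge schedule and noise are redrawn
  coords <- sample_fov_coords(config)
  drifting <- sample_drifting_cells(config)
  purrr::imap(start_times_s, function(t0, k) {
    cfg <- config
    cfg$seed <- stage_seed(config$seed, "session") + 97L * k
    simulate_recording(cfg, start_time_s = t0,
                       recording_id = sprintf("rec%02d", k),
                       coords = coords, drifting_cells = drifting, ...)
  })
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth A `slice_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    event_times_s = truth$event_times_s,
    thalamic_coupled = truth$thalamic_coupled,
    true_lags_s = truth$true_lags_s,
    drifting_cells = truth$drifting_cells,
    cell_spike_times = truth$cell_spike_times
  )
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
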