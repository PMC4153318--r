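# Builders used across test files. Everything is generated in code; no data
# files are read.

# Minimal onset raster: `onsets[cell, frame]` from a list of (cell, frame)
# pairs.
make_raster <- function(n_cells, n_frames, hits = list(), rate_hz = 10,
                        start_s = 0, id = "test") {
  on <- matrix(0L, n_cells, n_frames)
  for (h in hits) on[h[1], h[2]] <- 1L
  structure(list(onsets = on,
                 frame_times_s = start_s + (seq_len(n_frames) - 1L) / rate_hz,
                 frame_rate_hz = rate_hz, recording_id = id),
            class = "onset_raster")
}

# Event tibble from onset/offset vectors.
make_events <- function(onsets, offsets) {
  tibble::tibble(onset_s = onsets, offset_s = offsets)
}

# Small config for fast generator tests; any argument can be overridden.
quick_config <- function(...) {
  args <- utils::modifyList(
    list(duration_s = 60, n_cells_cortex = 30, n_cells_thalamus = 20,
         seed = 42L),
    list(...))
  do.call(experiment_config, args)
}

# Independent brute-force interval matcher: iterative argmax over the full
# pairwise overlap table (recomputed each round), earlier cortical then
# thalamic onset breaking ties. Shares no code with match_discharges().
brute_force_match <- function(cortical, thalamic) {
  nc <- nrow(cortical); nt <- nrow(thalamic)
  matched <- rep(FALSE, nc)
  lag <- rep(NA_real_, nc)
  free_c <- rep(TRUE, nc); free_t <- rep(TRUE, nt)
  repeat {
    best <- NULL; best_ov <- 0
    for (i in seq_len(nc)) {
      if (!free_c[i]) next
      for (j in seq_len(nt)) {
        if (!free_t[j]) next
        ov <- min(cortical$offset_s[i], thalamic$offset_s[j]) -
          max(cortical$onset_s[i], thalamic$onset_s[j])
        if (ov <= 0) next
        better <- ov > best_ov ||
          (ov == best_ov && !is.null(best) &&
             (cortical$onset_s[i] < cortical$onset_s[best[1]] ||
                (cortical$onset_s[i] == cortical$onset_s[best[1]] &&
                   thalamic$onset_s[j] < thalamic$onset_s[best[2]])))
        if (better) { best <- c(i, j); best_ov <- ov }
      }
    }
    if (is.null(best)) break
    matched[best[1]] <- TRUE
    lag[best[1]] <- thalamic$onset_s[best[2]] - cortical$onset_s[best[1]]
    free_c[best[1]] <- FALSE; free_t[best[2]] <- FALSE
  }
  list(matched = matched, lag_s = lag, cr = mean(matched))
}

# Random discharge-like instance: disjoint, ordered events in each area.
random_instance <- function(n_c, n_t, t_max = 60) {
  gen <- function(n) {
    on <- sort(runif(n, 0, t_max))
    dur <- runif(n, 0.3, 2)
    off <- on + dur
    # enforce disjointness by pushing onsets past the previous offset
    for (k in seq_len(n)[-1]) {
      if (on[k] <= off[k - 1]) {
        on[k] <- off[k - 1] + runif(1, 0.05, 0.5)
        off[k] <- on[k] + dur[k]
      }
    }
    make_events(on, off)
  }
  list(cortical = gen(n_c), thalamic = gen(n_t))
}
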