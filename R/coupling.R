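#' Match cortical and thalamic discharges by interval overlap
#'
#' One row per cortical discharge. A thalamic discharge is assigned to a
#' cortical discharge when their `[onset, offset]` intervals overlap
#' (strictly positive overlap); each thalamic discharge is used at most
#' once. Assignment is greedy by descending pairwise overlap, ties broken by
#' earlier cortical onset, which makes the matching deterministic and
#' auditable. The signed lag is thalamic onset minus cortical onset
#' (positive = cortex leads).
#'
#' @param cortical,thalamic Event tibbles with `onset_s` and `offset_s`
#'   columns, sorted by onset and on the same experiment clock.
#' @return A tibble with one row per cortical event: `cortical_onset_s`,
#'   `cortical_offset_s`, `thalamic_onset_s`, `thalamic_offset_s`, `lag_s`,
#'   `overlap_s`, `matched`.
#' @examples
#' ctx <- tibble::tibble(onset_s = 0, offset_s = 1)
#' tha <- tibble::tibble(onset_s = 0.5, offset_s = 1.5)
#' match_discharges(ctx, tha)
#' @export
match_discharges <- function(cortical, thalamic) {
  check_event_tbl(cortical, "cortical")
  check_event_tbl(thalamic, "thalamic")
  nc <- nrow(cortical); nt <- nrow(thalamic)
  out <- tibble(
    cortical_onset_s = cortical$onset_s,
    cortical_offset_s = cortical$offset_s,
    thalamic_onset_s = NA_real_, thalamic_offset_s = NA_real_,
    lag_s = NA_real_, overlap_s = NA_real_, matched = FALSE
  )
  if (nc == 0L || nt == 0L) return(out)

  ov <- outer(seq_len(nc), seq_len(nt), function(i, j) {
    pmin(cortical$offset_s[i], thalamic$offset_s[j]) -
      pmax(cortical$onset_s[i], thalamic$onset_s[j])
  })
  cand <- which(ov > 0, arr.ind = TRUE)
  if (nrow(cand)) {
    ord <- order(-ov[cand], cortical$onset_s[cand[, 1]],
                 thalamic$onset_s[cand[, 2]])
    cand <- cand[ord, , drop = FALSE]
    used_c <- logical(nc); used_t <- logical(nt)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_c[i] || used_t[j]) next
      used_c[i] <- TRUE; used_t[j] <- TRUE
      out$thalamic_onset_s[i] <- thalamic$onset_s[j]
      out$thalamic_offset_s[i] <- thalamic$offset_s[j]
      out$overlap_s[i] <- ov[i, j]
      out$lag_s[i] <- thalamic$onset_s[j] - cortical$onset_s[i]
      out$matched[i] <- TRUE
    }
  }
  out
}

check_event_tbl <- function(ev, what) {
  if (!is.data.frame(ev) || !all(c("onset_s", "offset_s") %in% names(ev))) {
    stop_tc("`", what, "` must have `onset_s` and `offset_s` columns")
  }
  if (is.unsorted(ev$onset_s)) stop_tc("`", what, "` events must be sorted by onset")
  if (any(ev$offset_s < ev$onset_s)) stop_tc("`", what, "` has offset < onset")
  invisible(ev)
}

#' Coupling reliability (CR)
#'
#' The fraction of all cortical epileptiform discharges that were also
#' detected (as an overlapping discharge) in thalamus: matched count divided
#' by cortical count. CR = 0 is thalamic silence; CR = 1 is perfect
#' corticothalamic coupling.
#'
#' @param matches Tibble from [match_discharges()].
#' @return A single number in `[0, 1]`.
#' @export
coupling_reliability <- function(matches) {
  if (!is.data.frame(matches) || !"matched" %in% names(matches)) {
    stop_tc("`matches` must come from match_discharges()")
  }
  if (nrow(matches) == 0L) {
    stop_tc("CR is undefined without cortical discharges")
  }
  mean(matches$matched)
}

#' Lag statistics for matched discharges
#'
#' @param matches Tibble from [match_discharges()].
#' @return One-row tibble: `median_lag_s`, `fraction_cortex_leading`
#'   (lag strictly > 0; exact ties count as not leading), `n_matched`.
#' @export
lag_statistics <- function(matches) {
  lags <- matches$lag_s[matches$matched]
  if (!length(lags)) stop_tc("lag statistics are undefined with no matched discharges")
  tibble(median_lag_s = stats::median(lags),
         fraction_cortex_leading = mean(lags > 0),
         n_matched = length(lags))
}

#' Align per-recording metric timelines at their threshold crossing
#'
#' Implements the population-timeline construction: per slice, the crossing
#' is the first sampled time point at which the metric reaches `threshold`
#' (recordings are minutes apart, so no interpolation); all of that slice's
#' time points are shifted so the crossing sits at 0; points from all slices
#' are pooled into contiguous bins of `bin_min` minutes; per bin the mean and
#' SEM (sample SD / sqrt(n)) over the pooled values are reported. Slices
#' that never cross are excluded with a warning.
#'
#' @param points Tibble with columns `slice_id`, `time_min` (recording mid
#'   time in minutes), and `value` (CR or fraction of correlated cells).
#' @param threshold Crossing threshold (default 0.5).
#' @param bin_min Bin width in minutes (default 20).
#' @return An object of class `aligned_timeline`: list with `points`
#'   (aligned per-slice values) and `bins` (tibble of `bin_start_min`,
#'   `bin_end_min`, `mean`, `sem`, `n`, `n_slices`).
#' @export
align_timeline <- function(points, threshold = 0.5, bin_min = 20) {
  need <- c("slice_id", "time_min", "value")
  if (!is.data.frame(points) || !all(need %in% names(points))) {
    stop_tc("`points` must have columns ", paste(need, collapse = ", "))
  }
  aligned <- points |>
    group_by(.data$slice_id) |>
    arrange(.data$time_min, .by_group = TRUE) |>
    group_split_keep()
  shifted <- purrr::map(aligned, function(df) {
    hit <- which(df$value >= threshold)
    if (!length(hit)) {
      warn_tc("slice '", df$slice_id[1], "' never crosses ", threshold,
              "; excluded from the aligned timeline")
      return(NULL)
    }
    df$aligned_min <- df$time_min - df$time_min[hit[1]]
    df
  })
  shifted <- purrr::compact(shifted)
  if (!length(shifted)) stop_tc("no slice crosses the threshold")
  pts <- bind_rows(shifted)

  lo <- floor(min(pts$aligned_min) / bin_min) * bin_min
  hi <- ceiling((max(pts$aligned_min) + 1e-9) / bin_min) * bin_min
  edges <- seq(lo, max(hi, lo + bin_min), by = bin_min)
  pts$bin <- findInterval(pts$aligned_min, edges, rightmost.closed = FALSE)
  bins <- pts |>
    group_by(.data$bin) |>
    summarise(mean = mean(.data$value),
              sem = if (n() >= 2L) sd(.data$value) / sqrt(n()) else NA_real_,
              n = n(),
              n_slices = length(unique(.data$slice_id)),
              .groups = "drop") |>
    mutate(bin_start_min = edges[.data$bin],
           bin_end_min = edges[.data$bin] + bin_min) |>
    select("bin_start_min", "bin_end_min", "mean", "sem", "n", "n_slices")
  structure(list(points = select(pts, -"bin"), bins = bins,
                 threshold = threshold, bin_min = bin_min),
            class = "aligned_timeline")
}

# group_split that keeps the grouping column (dplyr::group_split drops keys
# only with .keep = FALSE; this wrapper just documents intent)
group_split_keep <- function(gdf) {
  dplyr::group_split(gdf, .keep = TRUE)
}

#' @export
print.aligned_timeline <- function(x, ...) {
  cat(sprintf("<aligned_timeline> %d slices, %d points, %g-min bins, threshold %g\n",
              length(unique(x$points$slice_id)), nrow(x$points), x$bin_min,
              x$threshold))
  print(x$bins)
  invisible(x)
}

#' @describeIn align_timeline Binned means as a tibble.
#' @param x An `aligned_timeline`.
#' @param ... Unused.
#' @export
tidy.aligned_timeline <- function(x, ...) x$bins

#' Downsample a voltage trace by per-frame averaging
#'
#' The value for frame `i` is the mean of all voltage samples in
#' `[frame_time_i, frame_time_{i+1})`; the last frame uses the nominal frame
#' period. Frames containing no sample carry the previous frame's value,
#' with a warning.
#'
#' @param ephys An [ephys_recording()].
#' @param frame_times_s Absolute frame times (s), within the recording span.
#' @return Numeric vector, one averaged voltage per frame.
#' @export
downsample_by_frame_average <- function(ephys, frame_times_s) {
  stopifnot(inherits(ephys, "ephys_recording"))
  n_fr <- length(frame_times_s)
  if (n_fr == 0L) return(numeric(0))
  period <- if (n_fr > 1L) stats::median(diff(frame_times_s)) else
    1 / ephys$sample_rate_hz
  st <- frame_times(ephys)
  edges <- c(frame_times_s, frame_times_s[n_fr] + period)
  # tiny epsilon keeps samples nominally at a frame edge in the next
  # (half-open) frame despite floating-point representation error
  idx <- findInterval(st + 1e-9, edges, rightmost.closed = FALSE)
  keep <- idx >= 1L & idx <= n_fr
  sums <- rowsum(ephys$vm_mv[keep], idx[keep])
  counts <- tabulate(idx[keep], nbins = n_fr)
  out <- rep(NA_real_, n_fr)
  out[as.integer(rownames(sums))] <- sums[, 1] / counts[counts > 0]
  if (anyNA(out)) {
    warn_tc("empty frame bins; carrying previous values")
    for (i in which(is.na(out))) out[i] <- if (i > 1L) out[i - 1L] else 0
  }
  out
}

#' Fraction of imaged cells correlated with a remote voltage trace
#'
#' The remote membrane potential is downsampled to the imaging frame times
#' by per-frame averaging; per cell, the Pearson correlation between the
#' full-length fluorescence trace and the downsampled voltage is computed
#' with a one-sided test for r > 0. A cell counts as correlated when the
#' correlation is significantly larger than zero (p < `p_max`) and its
#' absolute value exceeds `r_min`. Constant traces yield an undefined r and
#' count as not correlated.
#'
#' @param imaging An [imaging_recording()] (e.g. the thalamic FOV).
#' @param remote_ephys An [ephys_recording()] from the other area.
#' @param p_max Significance level (default 0.05).
#' @param r_min Magnitude gate on \|r\| (default 0.1).
#' @return A list with `fraction` (correlated cells / all cells in the FOV)
#'   and `cells`, a tibble of per-cell `r`, `p_value`, `correlated`.
#' @export
fraction_correlated_cells <- function(imaging, remote_ephys, p_max = 0.05,
                                      r_min = 0.1) {
  stopifnot(inherits(imaging, "imaging_recording"),
            inherits(remote_ephys, "ephys_recording"))
  ft <- frame_times(imaging)
  et <- frame_times(remote_ephys)
  span <- min(max(ft), max(et)) - max(min(ft), min(et))
  if (span < 30) stop_tc("overlapping time span must be >= 30 s")
  in_span <- ft >= min(et) & ft <= max(et)
  v <- downsample_by_frame_average(remote_ephys, ft[in_span])

  n_cells <- nrow(imaging$fluorescence)
  res <- purrr::map(seq_len(n_cells), function(i) {
    x <- imaging$fluorescence[i, in_span]
    if (sd(x) == 0 || sd(v) == 0) {
      warn_tc("constant trace for cell ", i, "; r undefined, not correlated")
      return(tibble(cell = i, r = NA_real_, p_value = NA_real_,
                    correlated = FALSE))
    }
    ct <- stats::cor.test(x, v, alternative = "greater", method = "pearson")
    tibble(cell = i, r = unname(ct$estimate), p_value = ct$p.value,
           correlated = ct$p.value < p_max && abs(ct$estimate) > r_min)
  })
  cells <- bind_rows(res)
  list(fraction = mean(cells$correlated), cells = cells)
}

#' Write a discharge-match table as TSV
#'
#' @param matches Tibble from [match_discharges()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  readr::write_tsv(matches, path)
  invisible(path)
}
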