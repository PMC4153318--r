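# Internal numerical helpers shared across modules.

# Running percentile of a trace, evaluated on a coarse grid and linearly
# interpolated back to every sample. window_s is the (centered) window width;
# stride_s controls the grid spacing. Much faster than a dense rolling
# quantile and accurate for the slow baselines it is used on.
running_percentile <- function(x, rate_hz, window_s, p, stride_s = 1) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- max(1L, round(window_s * rate_hz / 2))
  if (2L * half + 1L >= n) {
    # trace shorter than the window: fall back to a global statistic
    return(rep(stats::quantile(x, p, names = FALSE), n))
  }
  stride <- max(1L, round(stride_s * rate_hz))
  grid <- unique(c(seq(1L, n, by = stride), n))
  vals <- vapply(grid, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    stats::quantile(x[lo:hi], p, names = FALSE)
  }, numeric(1))
  stats::approx(grid, vals, xout = seq_len(n), rule = 2)$y
}

running_median_baseline <- function(x, rate_hz, window_s = 30) {
  if (length(x) * (1 / rate_hz) < window_s) {
    warn_tc("trace shorter than the baseline window; using the global median")
    return(rep(stats::median(x), length(x)))
  }
  running_percentile(x, rate_hz, window_s, p = 0.5)
}

# Centered moving average with shrunken windows at the edges; width must be odd.
moving_average <- function(x, width = 3L) {
  stopifnot(width %% 2L == 1L)
  n <- length(x)
  if (n == 0L || width == 1L) return(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# All permutations of seq_len(n) as an n! x n matrix; used for exact
# enumeration in the stationarity filter (n <= 6 there, so at most 720 rows).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# Deterministic per-stage seeds derived from one master seed, kept within
# 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(schedule = 101L, fluor_cortex = 211L, fluor_thalamus = 223L,
               ephys_cortex = 307L, ephys_thalamus = 311L, shuffle = 401L,
               session = 503L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

warn_tc <- function(...) warning(..., call. = FALSE)

stop_tc <- function(...) stop(..., call. = FALSE)
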