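#' Imaging recording container
#'
#' A per-cell fluorescence matrix with the metadata every downstream stage
#' needs: frame rate, absolute start time within the experiment, per-cell
#' coordinates in micrometers, and the brain-area label.
#'
#' @param fluorescence Numeric matrix, cells x frames (dF units).
#' @param frame_rate_hz Frame rate in Hz.
#' @param start_time_s Absolute time of the first frame (s).
#' @param coords_um Numeric matrix, cells x 2, positions in um.
#' @param area `"cortex"` or `"thalamus"`.
#' @param recording_id Identifier string.
#' @return An object of class `imaging_recording`.
#' @export
imaging_recording <- function(fluorescence, frame_rate_hz, start_time_s = 0,
                              coords_um, area = c("cortex", "thalamus"),
                              recording_id = "rec") {
  area <- match.arg(area)
  fluorescence <- as.matrix(fluorescence)
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) {
    stop_tc("`frame_rate_hz` must be positive")
  }
  if (anyNA(fluorescence)) stop_tc("fluorescence contains NA after ingest")
  coords_um <- as.matrix(coords_um)
  if (nrow(coords_um) != nrow(fluorescence) || ncol(coords_um) != 2L) {
    stop_tc("`coords_um` must be an (n_cells x 2) matrix")
  }
  structure(
    list(fluorescence = fluorescence, frame_rate_hz = frame_rate_hz,
         start_time_s = start_time_s, coords_um = coords_um, area = area,
         recording_id = recording_id),
    class = "imaging_recording"
  )
}

#' Electrophysiology recording container
#'
#' @param vm_mv Numeric vector of membrane potential samples (mV).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param start_time_s Absolute time of the first sample (s).
#' @param area `"cortex"` or `"thalamus"`.
#' @param cell_id,recording_id Identifier strings.
#' @return An object of class `ephys_recording`.
#' @export
ephys_recording <- function(vm_mv, sample_rate_hz, start_time_s = 0,
                            area = c("cortex", "thalamus"),
                            cell_id = "cell", recording_id = "rec") {
  area <- match.arg(area)
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop_tc("`sample_rate_hz` must be positive")
  }
  if (!all(is.finite(vm_mv))) stop_tc("vm_mv must be finite")
  structure(
    list(vm_mv = as.numeric(vm_mv), sample_rate_hz = sample_rate_hz,
         start_time_s = start_time_s, area = area, cell_id = cell_id,
         recording_id = recording_id),
    class = "ephys_recording"
  )
}

#' Frame (or sample) times of a recording
#'
#' Absolute times, in seconds, of each frame of an imaging recording or each
#' sample of an ephys recording.
#'
#' @param rec An `imaging_recording` or `ephys_recording`.
#' @return Numeric vector of absolute times (s).
#' @export
frame_times <- function(rec) {
  if (inherits(rec, "imaging_recording")) {
    n <- ncol(rec$fluorescence)
    rec$start_time_s + (seq_len(n) - 1L) / rec$frame_rate_hz
  } else if (inherits(rec, "ephys_recording")) {
    n <- length(rec$vm_mv)
    rec$start_time_s + (seq_len(n) - 1L) / rec$sample_rate_hz
  } else {
    stop_tc("`rec` must be an imaging_recording or ephys_recording")
  }
}

#' @export
print.imaging_recording <- function(x, ...) {
  cat(sprintf("<imaging_recording '%s'> %s, %d cells x %d frames at %g Hz, start %g s\n",
              x$recording_id, x$area, nrow(x$fluorescence),
              ncol(x$fluorescence), x$frame_rate_hz, x$start_time_s))
  invisible(x)
}

#' @export
print.ephys_recording <- function(x, ...) {
  cat(sprintf("<ephys_recording '%s'> %s, %d samples at %g Hz, start %g s\n",
              x$recording_id, x$area, length(x$vm_mv), x$sample_rate_hz,
              x$start_time_s))
  invisible(x)
}

#' Write a recording to a plain-text container
#'
#' One CSV with the data matrix (imaging: cells x frames with a header row;
#' ephys: a single `vm_mv` column) and one JSON sidecar holding the rate,
#' start time, area, identifiers and (for imaging) the cell coordinates.
#' Values round-trip losslessly.
#'
#' @param rec An `imaging_recording` or `ephys_recording`.
#' @param dir Output directory (created if needed).
#' @return The path of the metadata JSON, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- rec$recording_id
  if (inherits(rec, "imaging_recording")) {
    data_path <- file.path(dir, paste0(id, "_fluorescence.csv"))
    # format with 17 significant digits: guaranteed lossless round-trip
    df <- as.data.frame(apply(rec$fluorescence, 2, sprintf, fmt = "%.17g"))
    names(df) <- paste0("f", seq_len(ncol(df)))
    readr::write_csv(df, data_path)
    meta <- list(kind = "imaging", recording_id = id, area = rec$area,
                 rate_hz = rec$frame_rate_hz, start_time_s = rec$start_time_s,
                 coords_um = unname(apply(rec$coords_um, 1, as.numeric,
                                          simplify = FALSE)),
                 data_file = basename(data_path))
  } else if (inherits(rec, "ephys_recording")) {
    data_path <- file.path(dir, paste0(id, "_vm.csv"))
    readr::write_csv(tibble(vm_mv = sprintf("%.17g", rec$vm_mv)), data_path)
    meta <- list(kind = "ephys", recording_id = id, area = rec$area,
                 cell_id = rec$cell_id, rate_hz = rec$sample_rate_hz,
                 start_time_s = rec$start_time_s,
                 data_file = basename(data_path))
  } else {
    stop_tc("`rec` must be an imaging_recording or ephys_recording")
  }
  meta_path <- file.path(dir, paste0(id, "_meta.json"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(meta_path)
}

#' Read a recording written by [write_recording()]
#'
#' @param meta_path Path to the `*_meta.json` sidecar.
#' @return An `imaging_recording` or `ephys_recording`.
#' @export
read_recording <- function(meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("kind", "rate_hz", "start_time_s", "area", "data_file")) {
    if (is.null(meta[[f]])) stop_tc("metadata is missing field `", f, "`")
  }
  data_path <- file.path(dirname(meta_path), meta$data_file)
  if (identical(meta$kind, "imaging")) {
    if (is.null(meta$coords_um)) stop_tc("metadata is missing field `coords_um`")
    # base read.csv parses doubles with correctly rounded strtod, so the
    # 17-digit representation round-trips bit-exactly
    mat <- as.matrix(utils::read.csv(data_path, colClasses = "numeric"))
    dimnames(mat) <- NULL
    coords <- meta$coords_um
    if (is.list(coords)) coords <- do.call(rbind, coords)
    imaging_recording(mat, frame_rate_hz = meta$rate_hz,
                      start_time_s = meta$start_time_s, coords_um = coords,
                      area = meta$area, recording_id = meta$recording_id)
  } else if (identical(meta$kind, "ephys")) {
    vm <- utils::read.csv(data_path, colClasses = "numeric")$vm_mv
    ephys_recording(vm, sample_rate_hz = meta$rate_hz,
                    start_time_s = meta$start_time_s, area = meta$area,
                    cell_id = meta$cell_id %||% "cell",
                    recording_id = meta$recording_id)
  } else {
    stop_tc("unknown recording kind: ", meta$kind)
  }
}
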