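#' Raw recordings on disk
#'
#' A recording is a frames-by-channels voltage matrix stored as little-endian
#' int16 in frame-major order (all channels of frame 1, then frame 2, ...),
#' with a JSON sidecar holding the metadata needed to interpret it: sampling
#' rate, grid shape, electrode pitch and the ADC-to-microvolt scale factor.
#' Detectors stream recordings chunk-wise and never hold a full recording in
#' memory; all arithmetic downstream is in microvolts (doubles).
#'
#' `open_recording()` returns a lightweight file-backed handle of class
#' `mea_recording`. `read_frames()` reads a contiguous block of frames and
#' returns it scaled to microvolts. An HDF5 container is not supported by this
#' build; requesting `format = "hdf5"` raises an error.
#'
#' @param path Path to the `.bin` data file (the sidecar is `<path>.json`).
#' @param format Storage format. Only `"flat_binary"` is available.
#' @return `open_recording()`: an `mea_recording`; `read_frames()`: a numeric
#'   matrix (frames x channels) in microvolts.
#' @name recording_io
NULL

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname recording_io
#' @export
open_recording <- function(path, format = c("flat_binary", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    abort("HDF5 containers are not supported by this build; use flat_binary (int16 + JSON sidecar).")
  if (!file.exists(path)) abort(sprintf("recording data file not found: %s", path))
  sp <- sidecar_path(path)
  if (!file.exists(sp)) abort(sprintf("missing JSON sidecar: %s", sp))
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  required <- c("sampling_rate_hz", "n_rows", "n_cols", "pitch_um", "adc_scale_uv")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0)
    abort(sprintf("sidecar is missing required metadata: %s",
                  paste(missing, collapse = ", ")))
  if (meta$sampling_rate_hz < 1000 || meta$sampling_rate_hz > 50000)
    abort("sampling_rate_hz must lie in [1000, 50000]")
  geom <- mea_geometry(meta$n_rows, meta$n_cols, meta$pitch_um,
                       meta$electrode_size_um %||% 21)
  nch <- n_channels(geom)
  bytes <- file.size(path)
  if (bytes %% (2L * nch) != 0)
    abort(sprintf(
      "file size (%d bytes) is not a whole number of %d-channel int16 frames; stated grid %dx%d does not match the data",
      bytes, nch, meta$n_rows, meta$n_cols))
  n_frames <- as.numeric(bytes) / (2 * nch)
  if (!is.null(meta$n_frames) && meta$n_frames != n_frames)
    abort(sprintf("sidecar states %d frames but file holds %d", meta$n_frames, n_frames))
  structure(
    list(path = path, geometry = geom,
         sampling_rate_hz = meta$sampling_rate_hz,
         n_frames = n_frames, adc_scale_uv = meta$adc_scale_uv),
    class = "mea_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %s\n  %d x %d grid, %g Hz, %d frames (%.2f s)\n",
              x$path, x$geometry$n_rows, x$geometry$n_cols, x$sampling_rate_hz,
              x$n_frames, x$n_frames / x$sampling_rate_hz))
  invisible(x)
}

#' @rdname recording_io
#' @param rec An `mea_recording`.
#' @param start First frame to read (1-based).
#' @param n Number of frames to read.
#' @export
read_frames <- function(rec, start = 1, n = rec$n_frames) {
  nch <- n_channels(rec$geometry)
  start <- as.numeric(start); n <- as.numeric(n)
  stopifnot(start >= 1, start + n - 1 <= rec$n_frames)
  if (n == 0) return(matrix(numeric(0), nrow = 0, ncol = nch))
  con <- file(rec$path, "rb")
  on.exit(close(con))
  seek(con, where = (start - 1) * nch * 2, origin = "start")
  raw <- readBin(con, "integer", n = n * nch, size = 2, signed = TRUE,
                 endian = "little")
  x <- matrix(as.numeric(raw) * rec$adc_scale_uv, nrow = n, ncol = nch,
              byrow = TRUE)
  if (any(!is.finite(x))) abort("non-finite voltages after scaling")
  x
}

#' @rdname recording_io
#' @param chunk_frames Frames per chunk; defaults to one second of data.
#' @return `chunk_plan()`: a tibble with columns `start` and `n` covering all
#'   frames exactly once, in order.
#' @export
chunk_plan <- function(rec, chunk_frames = NULL) {
  chunk_frames <- chunk_frames %||% max(1, round(rec$sampling_rate_hz))
  if (rec$n_frames == 0)
    return(tibble(start = numeric(0), n = numeric(0)))
  starts <- seq(1, rec$n_frames, by = chunk_frames)
  tibble(start = starts, n = pmin(chunk_frames, rec$n_frames - starts + 1))
}

#' Write a voltage matrix as a flat-binary recording
#'
#' Quantizes microvolt values to int16 using `adc_scale_uv` and writes the
#' frame-major data file plus JSON sidecar. For long synthetic recordings use
#' [recording_writer()] to append chunk-wise.
#'
#' @param x Numeric matrix, frames x channels, in microvolts.
#' @inheritParams recording_io
#' @param geometry An [mea_geometry()] whose channel count matches `ncol(x)`.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param adc_scale_uv Microvolts per ADC count (quantization step).
#' @return The path, invisibly.
#' @export
write_recording <- function(x, path, geometry, sampling_rate_hz,
                            adc_scale_uv = 0.1) {
  w <- recording_writer(path, geometry, sampling_rate_hz, adc_scale_uv)
  if (nrow(x) > 0) writer_append(w, x)
  writer_close(w)
  invisible(path)
}

#' Chunked recording writer
#'
#' @inheritParams write_recording
#' @return An environment with an open connection; pass it to
#'   [writer_append()] and finish with [writer_close()] (which writes the
#'   sidecar).
#' @export
recording_writer <- function(path, geometry, sampling_rate_hz,
                             adc_scale_uv = 0.1) {
  stopifnot(inherits(geometry, "mea_geometry"))
  w <- new.env(parent = emptyenv())
  w$con <- file(path, "wb")
  w$path <- path
  w$geometry <- geometry
  w$sampling_rate_hz <- sampling_rate_hz
  w$adc_scale_uv <- adc_scale_uv
  w$n_frames <- 0
  w
}

#' @rdname recording_writer
#' @param w A writer from [recording_writer()].
#' @param chunk Numeric matrix, frames x channels, microvolts.
#' @export
writer_append <- function(w, chunk) {
  nch <- n_channels(w$geometry)
  if (ncol(chunk) != nch)
    abort(sprintf("chunk has %d channels, geometry states %d", ncol(chunk), nch))
  q <- as.integer(pmin(pmax(round(t(chunk) / w$adc_scale_uv), -32768), 32767))
  writeBin(q, w$con, size = 2, endian = "little")
  w$n_frames <- w$n_frames + nrow(chunk)
  invisible(w)
}

#' @rdname recording_writer
#' @export
writer_close <- function(w) {
  close(w$con)
  meta <- list(format = "hdmea-raw-v1", dtype = "int16", byte_order = "little",
               sampling_rate_hz = w$sampling_rate_hz,
               n_frames = w$n_frames,
               n_rows = w$geometry$n_rows, n_cols = w$geometry$n_cols,
               pitch_um = w$geometry$pitch_um,
               electrode_size_um = w$geometry$electrode_size_um,
               adc_scale_uv = w$adc_scale_uv, index_base = 1)
  jsonlite::write_json(meta, sidecar_path(w$path), auto_unbox = TRUE, digits = NA)
  invisible(w$path)
}

#' Per-frame median voltage across channels
#'
#' The median over all channels of each frame, used to remove common-mode
#' fluctuations before detection. Computed chunk-wise; chunked and whole-array
#' evaluation are bit-identical.
#'
#' @inheritParams recording_io
#' @inheritParams chunk_plan
#' @return A tibble with columns `frame` and `median_uv`.
#' @export
global_median_trace <- function(rec, chunk_frames = NULL) {
  plan <- chunk_plan(rec, chunk_frames)
  med <- purrr::map(seq_len(nrow(plan)), function(i) {
    x <- read_frames(rec, plan$start[i], plan$n[i])
    row_medians_cpp(x)
  })
  tibble(frame = seq_len(rec$n_frames), median_uv = unlist(med) %||% numeric(0))
}
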