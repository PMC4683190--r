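#' Event tables
#'
#' Detected spikes are plain tibbles with one row per event and columns
#' `frame` (1-based sampling frame of the negative peak), `time_s`, `channel`
#' (electrode index for single-channel detections, `NA` for events on the
#' virtual grid), `x_um`, `y_um` (event location), `amplitude` (peak depth in
#' units of the running variability estimate `v`) and `repolarizing`
#' (whether the trace returned above baseline shortly after the peak).
#' Additional columns (e.g. localized amplitude) pass through untouched.
#'
#' @param events A tibble of events.
#' @param n_frames,geometry Optional bounds used for validation: frames must
#'   lie in `[1, n_frames]` and locations within the grid bounding box
#'   expanded by one pitch.
#' @return `validate_events()` returns its input invisibly or aborts.
#' @export
validate_events <- function(events, n_frames = NULL, geometry = NULL) {
  required <- c("frame", "time_s", "channel", "x_um", "y_um", "amplitude",
                "repolarizing")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0)
    abort(sprintf("event table is missing columns: %s",
                  paste(missing, collapse = ", ")))
  if (any(events$amplitude < 0, na.rm = TRUE))
    abort("event amplitudes must be >= 0")
  if (!is.null(n_frames) && nrow(events) > 0 &&
      (min(events$frame) < 1 || max(events$frame) > n_frames))
    abort("event frames outside [1, n_frames]")
  if (!is.null(geometry) && nrow(events) > 0) {
    p <- geometry$pitch_um
    xmax <- (geometry$n_cols - 1) * p; ymax <- (geometry$n_rows - 1) * p
    if (any(events$x_um < -p | events$x_um > xmax + p |
            events$y_um < -p | events$y_um > ymax + p, na.rm = TRUE))
      abort("event locations outside grid bounding box (+/- one pitch)")
  }
  invisible(events)
}

empty_events <- function() {
  tibble(frame = integer(0), time_s = numeric(0), channel = integer(0),
         x_um = numeric(0), y_um = numeric(0), amplitude = numeric(0),
         repolarizing = logical(0))
}

#' Read and write event tables as CSV
#'
#' The on-disk format stores `repolarizing` as a 0/1 column; a write/read
#' round trip reproduces frames, channels, locations, flags exactly and
#' amplitudes to better than six significant digits.
#'
#' @param events An event tibble (see [validate_events()]).
#' @param path CSV file path.
#' @param detector,recording_id Optional provenance strings stored as comment
#'   header lines.
#' @return `read_events()` returns a tibble; `write_events()` its path,
#'   invisibly.
#' @export
write_events <- function(events, path, detector = NULL, recording_id = NULL) {
  validate_events(events)
  out <- as.data.frame(events)
  out$repolarizing <- as.integer(out$repolarizing)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(col) {
    ifelse(is.na(col), NA, format(col, digits = 15, scientific = FALSE, trim = TRUE))
  })
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(detector)) writeLines(sprintf("# detector: %s", detector), con)
  if (!is.null(recording_id)) writeLines(sprintf("# recording: %s", recording_id), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("event file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$repolarizing <- as.logical(df$repolarizing)
  df$frame <- as.integer(df$frame)
  df$channel <- as.integer(df$channel)
  as_tibble(df)
}
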