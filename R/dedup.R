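#' Remove spatio-temporal duplicate events
#'
#' The same physical spike can be detected on several nearby electrodes or
#' grid locations. Within a spatio-temporal lockout (time window `window_ms`
#' before and after, Euclidean radius `radius_um`), only the event with the
#' highest amplitude is retained. Suppression is greedy in descending
#' amplitude, with exact ties broken by earlier frame and then lower channel
#' index, so every removed event has a retained neighbour of greater (or
#' tie-winning equal) amplitude; the result is idempotent and independent of
#' input row order.
#'
#' Typical radii: 60 um for single-electrode (online) detections, 42 um (one
#' pitch) for interpolating detections, which carry sub-electrode locations.
#'
#' @param events An event tibble with `frame`, `x_um`, `y_um`, `amplitude`.
#' @param radius_um Lockout radius in micrometres.
#' @param window_ms Lockout half-window in milliseconds (before and after).
#' @param sampling_rate_hz Sampling rate used to convert the window to frames.
#' @return The retained events, original order preserved.
#' @export
remove_duplicates <- function(events, radius_um, window_ms = 0.5,
                              sampling_rate_hz) {
  if (nrow(events) <= 1) return(events)
  id <- if ("channel" %in% names(events) && !anyNA(events$channel))
    as.numeric(events$channel) else seq_len(nrow(events))
  keep <- dedup_cpp(as.numeric(events$frame), events$x_um, events$y_um,
                    events$amplitude, id, radius_um,
                    window_ms * 1e-3 * sampling_rate_hz)
  events[keep, ]
}

#' @rdname remove_duplicates
#' @param refractory_ms Same-electrode refractory window in milliseconds:
#'   among events on one electrode closer in time than this, only the largest
#'   amplitude survives.
#' @export
refractory_filter <- function(events, refractory_ms = 1, sampling_rate_hz) {
  if (nrow(events) <= 1) return(events)
  # radius 0 with per-channel coordinates: lockout applies within a channel
  keep <- dedup_cpp(as.numeric(events$frame),
                    as.numeric(events$channel),
                    numeric(nrow(events)),
                    events$amplitude, as.numeric(events$channel), 0,
                    refractory_ms * 1e-3 * sampling_rate_hz)
  events[keep, ]
}

#' Reference (brute-force) duplicate suppression
#'
#' Direct quadratic implementation of greedy suppression used as a test
#' oracle; equivalent to [remove_duplicates()] on any input.
#'
#' @inheritParams remove_duplicates
#' @keywords internal
#' @export
remove_duplicates_bruteforce <- function(events, radius_um, window_ms = 0.5,
                                         sampling_rate_hz) {
  n <- nrow(events)
  if (n <= 1) return(events)
  id <- if ("channel" %in% names(events) && !anyNA(events$channel))
    as.numeric(events$channel) else seq_len(n)
  ord <- order(-events$amplitude, events$frame, id)
  win <- window_ms * 1e-3 * sampling_rate_hz
  keep <- logical(n)
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (abs(events$frame[i] - events$frame[j]) <= win &&
          sqrt((events$x_um[i] - events$x_um[j])^2 +
               (events$y_um[i] - events$y_um[j])^2) <= radius_um) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  events[keep, ]
}
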