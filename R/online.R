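#' Parameters of the streaming single-channel detector
#'
#' The detector keeps, per channel, a running baseline `b` (tracking a
#' lower-tercile quantile of the signal) and a variability estimate `v` of the
#' negative-side noise spread; both are updated incrementally at every frame,
#' and the detection threshold is `b - threshold * v`. Durations given in
#' milliseconds are converted to integer frames by rounding half up.
#'
#' @param sampling_rate_hz Sampling rate `f_s` in Hz.
#' @param threshold Detection threshold in units of `v` (default 6).
#' @param theta_ev Minimum depolarization area: the summed baseline-subtracted
#'   voltage (in units of `v`) from threshold crossing to `tau_ev_ms` past the
#'   peak must exceed this (default 10.5).
#' @param tau_ev_ms Interval for the depolarization area after the peak
#'   (default 0.27 ms, 2 frames at ~7.5 kHz).
#' @param tau_event_ms Maximum depolarization width: no deeper minimum may
#'   occur for this long after the peak, and the repolarization check runs
#'   over the same window (default 1 ms).
#' @param theta_b Repolarization threshold in units of `v`: the event is
#'   flagged repolarizing if some frame within `tau_event_ms` after the peak
#'   exceeds `b + theta_b * v` (default 0).
#' @param variability_rate `f_v / f_s`: per-frame step of `v` in microvolts
#'   (default 0.03125).
#' @param baseline_rate `f_b / (f_s v)`: the per-frame baseline step in units
#'   of the current `v`. `b` moves down by `baseline_rate * v` when the signal
#'   is below `b - v` and up by half that when above `b + v` (default 0.5;
#'   deliberately asymmetric so positive deflections are ignored).
#' @param v_floor Lower clip for `v` in microvolts, guarding the amplitude
#'   normalization (default 0.1).
#' @param v_init Initial `v` in microvolts (default 10); `b` starts at the
#'   first corrected sample of each channel.
#' @param burn_in_s Initial period during which the state converges and no
#'   events are emitted (default 0.5 s).
#' @param init_frames Frames buffered to initialize `b` (median) and `v`
#'   (scaled median absolute deviation) per channel before tracking starts
#'   (default 128). The variability update is bistable: started far below
#'   the noise spread, `v` would collapse to the floor through the
#'   spike-compensation branch, so it must start at or above the noise
#'   scale. Set to 0 to start from `v_init` and the first sample instead.
#' @param refractory_ms Same-electrode window in which only the largest
#'   amplitude event is retained (default 1 ms).
#' @return A list of class `online_params`.
#' @export
online_params <- function(sampling_rate_hz, threshold = 6, theta_ev = 10.5,
                          tau_ev_ms = 0.27, tau_event_ms = 1, theta_b = 0,
                          variability_rate = 0.03125, baseline_rate = 0.5,
                          v_floor = 0.1, v_init = 10, burn_in_s = 0.5,
                          refractory_ms = 1, init_frames = 128) {
  frames <- function(ms) as.integer(floor(ms * 1e-3 * sampling_rate_hz + 0.5))
  p <- list(sampling_rate_hz = sampling_rate_hz, threshold = threshold,
            theta_ev = theta_ev, tau_ev = frames(tau_ev_ms),
            tau_event = frames(tau_event_ms), theta_b = theta_b,
            variability_rate = variability_rate, baseline_rate = baseline_rate,
            v_floor = v_floor, v_init = v_init,
            burn_in = as.integer(round(burn_in_s * sampling_rate_hz)),
            refractory_ms = refractory_ms,
            init_frames = as.integer(init_frames))
  if (p$threshold <= 0) abort("threshold must be > 0")
  if (p$tau_ev > p$tau_event) abort("tau_ev_ms must not exceed tau_event_ms")
  structure(p, class = "online_params")
}

#' Single step of the incremental baseline/variability estimator
#'
#' Pure reference implementation of the per-frame update: given the corrected
#' sample `x` (raw minus the per-frame global median), the baseline moves up
#' by `0.5 * baseline_rate * v` if `x > b + v` and down by `baseline_rate * v`
#' if `x < b - v`; the variability shrinks by `variability_rate` if
#' `x` falls in `(b - v, b]` or at or below `b - 6v` (spike compensation), and
#' grows by the same amount for `x` in `(b - 5v, b - v]`. All conditions use
#' the pre-update state; `v` is floored at `v_floor`.
#'
#' @param state List with elements `b` and `v` (microvolts).
#' @param x Corrected sample in microvolts.
#' @param params An [online_params()].
#' @return The updated state list.
#' @examples
#' p <- online_params(8000)
#' update_state(list(b = 0, v = 4), 5, p)   # b rises by 0.25 * v = 1
#' @export
update_state <- function(state, x, params) {
  b0 <- state$b; v0 <- state$v
  b <- b0; v <- v0
  if (x > b0 + v0) b <- b + 0.5 * params$baseline_rate * v0
  else if (x < b0 - v0) b <- b - params$baseline_rate * v0
  if ((x > b0 - v0 && x <= b0) || x <= b0 - 6 * v0) v <- v - params$variability_rate
  else if (x > b0 - 5 * v0 && x <= b0 - v0) v <- v + params$variability_rate
  list(b = b, v = max(v, params$v_floor))
}

#' Track baseline and variability over a single-channel stream
#'
#' @param x Numeric vector of corrected samples (microvolts).
#' @param params An [online_params()].
#' @return A tibble with per-frame `b` and `v`.
#' @export
track_baseline <- function(x, params) {
  r <- track_baseline_cpp(as.numeric(x), params$variability_rate,
                          params$baseline_rate, params$v_floor, params$v_init)
  tibble(frame = seq_along(x), b = r$b, v = r$v)
}

#' Detect spikes on a single corrected channel
#'
#' Streaming detection on one channel: after the corrected signal crosses
#' `b - threshold * v`, the deepest sample of the excursion is a candidate
#' peak. It is emitted as an event if (i) the summed baseline-subtracted
#' voltage (in units of `v`) from the crossing to `tau_ev` past the peak
#' exceeds `theta_ev`, and (ii) no deeper minimum follows within `tau_event`.
#' The repolarizing flag marks events where the trace exceeded
#' `b + theta_b * v` within `tau_event` after the peak. Positive deflections
#' never trigger. Amplitudes are `(b - x_peak)/v`, i.e. in units of `v`.
#'
#' @param x Numeric vector: corrected samples of one channel (microvolts).
#' @param params An [online_params()].
#' @param apply_refractory Keep only the largest-amplitude event within the
#'   same-electrode refractory window (default TRUE).
#' @return A tibble with `frame`, `amplitude`, `repolarizing`.
#' @export
detect_channel <- function(x, params, apply_refractory = TRUE) {
  p <- params
  det <- online_new(1L, p$sampling_rate_hz, p$threshold, p$theta_b, p$theta_ev,
                    p$tau_ev, p$tau_event, p$variability_rate, p$baseline_rate,
                    p$v_floor, p$v_init, p$burn_in, FALSE, p$init_frames)
  online_feed(det, matrix(as.numeric(x), ncol = 1))
  online_flush(det)
  ev <- as_tibble(online_take(det))
  ev <- tibble(frame = as.integer(ev$frame), amplitude = ev$amplitude,
               repolarizing = ev$repolarizing > 0)
  if (apply_refractory && nrow(ev) > 1) {
    keep <- dedup_cpp(ev$frame, numeric(nrow(ev)), numeric(nrow(ev)),
                      ev$amplitude, seq_len(nrow(ev)), 0,
                      p$refractory_ms * 1e-3 * p$sampling_rate_hz)
    ev <- ev[keep, ]
  }
  ev
}

#' Run the online detector over a recording
#'
#' Applies per-frame global median subtraction, per-channel streaming
#' detection, the same-electrode refractory rule (largest amplitude within
#' 1 ms wins) and spatio-temporal duplicate removal (see
#' [remove_duplicates()]; default lockout radius 60 um, +/-0.5 ms). Events
#' carry electrode-centre coordinates.
#'
#' @param rec An [open_recording()] handle.
#' @param params An [online_params()]; defaults to the recording's rate.
#' @param chunk_frames Streaming chunk length (default 1 s of frames).
#' @param dedup_radius_um Spatial lockout radius in micrometres; set to
#'   `NULL` to skip spatial dedup.
#' @return An event tibble (see [validate_events()]).
#' @export
detect_events_online <- function(rec, params = NULL, chunk_frames = NULL,
                                 dedup_radius_um = 60) {
  p <- params %||% online_params(rec$sampling_rate_hz)
  geom <- rec$geometry
  det <- online_new(n_channels(geom), p$sampling_rate_hz, p$threshold,
                    p$theta_b, p$theta_ev, p$tau_ev, p$tau_event,
                    p$variability_rate, p$baseline_rate, p$v_floor, p$v_init,
                    p$burn_in, TRUE, p$init_frames)
  plan <- chunk_plan(rec, chunk_frames)
  for (i in seq_len(nrow(plan)))
    online_feed(det, read_frames(rec, plan$start[i], plan$n[i]))
  online_flush(det)
  ev <- as_tibble(online_take(det))
  if (nrow(ev) == 0) return(empty_events())
  pos <- channel_position(geom, as.integer(ev$channel))
  ev <- tibble(frame = as.integer(ev$frame),
               time_s = (as.integer(ev$frame) - 1) / p$sampling_rate_hz,
               channel = as.integer(ev$channel),
               x_um = pos$x_um, y_um = pos$y_um,
               amplitude = ev$amplitude,
               repolarizing = ev$repolarizing > 0)
  ev <- refractory_filter(ev, p$refractory_ms, p$sampling_rate_hz)
  if (!is.null(dedup_radius_um))
    ev <- remove_duplicates(ev, radius_um = dedup_radius_um, window_ms = 0.5,
                            sampling_rate_hz = p$sampling_rate_hz)
  arrange(ev, .data$frame, .data$channel)
}
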