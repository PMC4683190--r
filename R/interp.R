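#' Parameters of the interpolating multi-electrode detector
#'
#' Signals are interpolated onto the real electrode grid (five-channel
#' weighting: centre plus its three strongest four-neighbours) and onto a
#' virtual grid centred between electrodes (four-channel weighting: mean of
#' the three strongest of the 2x2 block). The interpolated, boxcar-smoothed,
#' baseline-subtracted signal is normalized by the identically weighted
#' variability, and the minimum over two consecutive frames forms the
#' detection trace. A local minimum below `-threshold` is accepted only if no
#' deeper minimum follows within `tau_event_ms` at the same location and none
#' of the eight neighbouring locations (four real, four virtual) holds a
#' deeper minimum within `+/- tau_coinc_ms`.
#'
#' @inheritParams online_params
#' @param threshold Detection threshold in normalized units (default 5).
#' @param tau_coinc_ms Coincidence window for neighbour suppression
#'   (default 0.27 ms, i.e. +/-2 frames).
#' @param w_cs Centre/surround weight: the centre channel contributes
#'   `w_cs / (3 + w_cs)` of the five-channel signal (default 4).
#' @param smooth_ms Boxcar averaging window applied to the interpolated
#'   signal (default 0.4 ms, 3 frames at ~7.5 kHz).
#' @param tau_pre_ms,tau_post_ms Cut-out window before/after the peak used
#'   for localization (defaults 1 ms and 2.2 ms).
#' @return A list of class `interp_params`.
#' @export
interp_params <- function(sampling_rate_hz, threshold = 5, theta_b = 0,
                          tau_event_ms = 1, tau_coinc_ms = 0.27, w_cs = 4,
                          smooth_ms = 0.4, tau_pre_ms = 1, tau_post_ms = 2.2,
                          variability_rate = 0.03125, baseline_rate = 0.5,
                          v_floor = 0.1, v_init = 10, burn_in_s = 0.5,
                          refractory_ms = 1, init_frames = 128) {
  frames <- function(ms) as.integer(floor(ms * 1e-3 * sampling_rate_hz + 0.5))
  p <- list(sampling_rate_hz = sampling_rate_hz, threshold = threshold,
            theta_b = theta_b, tau_event = frames(tau_event_ms),
            tau_coinc = frames(tau_coinc_ms), w_cs = w_cs,
            smooth = max(1L, frames(smooth_ms)),
            tau_pre = frames(tau_pre_ms), tau_post = frames(tau_post_ms),
            variability_rate = variability_rate, baseline_rate = baseline_rate,
            v_floor = v_floor, v_init = v_init,
            burn_in = as.integer(round(burn_in_s * sampling_rate_hz)),
            refractory_ms = refractory_ms,
            init_frames = as.integer(init_frames))
  if (p$w_cs <= 0) abort("w_cs must be > 0")
  if (p$tau_coinc > p$tau_event) abort("tau_coinc_ms must not exceed tau_event_ms")
  structure(p, class = "interp_params")
}

#' Five-channel interpolated signal
#'
#' Weighted signal for a source assumed close to an electrode: the centre
#' contributes `w_cs / (3 + w_cs)`, and the three neighbours of largest
#' absolute amplitude contribute `1 / (3 + w_cs)` each. At array borders with
#' fewer than four neighbours, all present neighbours are used and the
#' weights are renormalized to sum to one. The variability estimate is
#' combined with identical weights.
#'
#' @param center Centre-channel value (baseline-subtracted signal).
#' @param neighbors Values of the up-to-four adjacent channels.
#' @param v_center,v_neighbors Matching variability estimates; defaults give
#'   the signal weighting only.
#' @param w_cs Centre/surround weight (default 4).
#' @return A list with `signal` and `v` (NA if variabilities not supplied).
#' @examples
#' five_channel_signal(-10, c(0, -10, -10, -10))$signal  # outlier 0 dropped
#' @export
five_channel_signal <- function(center, neighbors, v_center = NA,
                                v_neighbors = NA, w_cs = 4) {
  stopifnot(length(neighbors) >= 0, length(neighbors) <= 4)
  sel <- seq_along(neighbors)
  if (length(neighbors) == 4) sel <- order(abs(neighbors), decreasing = TRUE)[1:3]
  wsum <- w_cs + length(sel)
  sig <- (w_cs * center + sum(neighbors[sel])) / wsum
  v <- if (all(is.na(v_center))) NA_real_
       else (w_cs * v_center + sum(v_neighbors[sel])) / wsum
  list(signal = sig, v = v)
}

#' Four-channel interpolated (virtual) signal
#'
#' Value assigned to a virtual channel centred in a 2x2 block of electrodes:
#' the mean of the three values of largest absolute amplitude; the
#' variability is averaged over the same selection.
#'
#' @param values The four block values (baseline-subtracted signal).
#' @param v Matching variability estimates (optional).
#' @return A list with `signal` and `v`.
#' @examples
#' four_channel_signal(c(-10, -8, -6, -4))$signal  # (-10 - 8 - 6)/3 = -8
#' @export
four_channel_signal <- function(values, v = NA) {
  stopifnot(length(values) == 4)
  sel <- order(abs(values), decreasing = TRUE)[1:3]
  list(signal = mean(values[sel]),
       v = if (all(is.na(v))) NA_real_ else mean(v[sel]))
}

#' Global-fluctuation correction of a single sample
#'
#' Subtracts the per-frame global median and the fraction of its increment
#' explained by the channel's coupling coefficient `h`:
#' `corrected = x - g - h * (g - g_prev)`. `h` drifts at a speed of `1/f_s`
#' per frame towards values that remove the coupling: it is incremented when
#' the corrected voltage moved in the same direction as the global increment
#' and decremented when it moved oppositely; zero increments leave it
#' unchanged.
#'
#' @param x Raw sample (microvolts).
#' @param g,g_prev Global median at this and the previous frame.
#' @param h Current coupling coefficient.
#' @param corrected_prev Corrected value at the previous frame (for the
#'   direction test); `NA` skips the `h` update.
#' @param sampling_rate_hz Sampling rate.
#' @return List with `corrected` and updated `h`.
#' @export
correct_global <- function(x, g, g_prev, h, corrected_prev = NA,
                           sampling_rate_hz) {
  dg <- g - g_prev
  corrected <- x - g - h * dg
  if (!is.na(corrected_prev) && dg != 0) {
    dc <- corrected - corrected_prev
    if (dc != 0)
      h <- h + if ((dc > 0) == (dg > 0)) 1 / sampling_rate_hz else -1 / sampling_rate_hz
  }
  list(corrected = corrected, h = h)
}

interp_locations <- function(geom, loc) {
  nch <- n_channels(geom); nvc <- geom$n_cols - 1L
  virt <- loc > nch
  row <- col <- numeric(length(loc))
  vi <- loc[virt] - nch - 1L
  row[virt] <- vi %/% nvc + 1.5
  col[virt] <- vi %% nvc + 1.5
  row[!virt] <- (loc[!virt] - 1L) %/% geom$n_cols + 1
  col[!virt] <- (loc[!virt] - 1L) %% geom$n_cols + 1
  tibble(loc = loc, on_virtual = virt, row = row, col = col,
         x_um = (col - 1) * geom$pitch_um, y_um = (row - 1) * geom$pitch_um,
         channel = ifelse(virt, NA_integer_, as.integer(loc)))
}

#' Run the interpolating detector over a recording
#'
#' Streams the recording through the interpolating detector (see
#' [interp_params()]), optionally estimates a continuous current-source
#' location and amplitude for every event from a 9-12 channel raw cut-out
#' (see [localize_cutout()]), applies the same-location refractory rule and
#' removes spatio-temporal duplicates within one electrode pitch.
#'
#' @inheritParams detect_events_online
#' @param params An [interp_params()].
#' @param localize Estimate sub-electrode locations and localized amplitudes
#'   (default TRUE). When FALSE events carry grid-node coordinates.
#' @param dedup_radius_um Duplicate-removal radius (default one pitch).
#' @return An event tibble with additional columns `on_virtual`,
#'   `x_grid_um`, `y_grid_um` and (if localized) `amplitude_loc`.
#' @export
detect_events_interp <- function(rec, params = NULL, chunk_frames = NULL,
                                 localize = TRUE,
                                 dedup_radius_um = rec$geometry$pitch_um) {
  p <- params %||% interp_params(rec$sampling_rate_hz)
  geom <- rec$geometry
  det <- interp_new(geom$n_rows, geom$n_cols, p$sampling_rate_hz, p$threshold,
                    p$theta_b, p$w_cs, p$tau_event, p$tau_coinc,
                    p$variability_rate, p$baseline_rate, p$v_floor, p$v_init,
                    p$burn_in, p$tau_pre, p$tau_post, localize, p$init_frames)
  plan <- chunk_plan(rec, chunk_frames)
  parts <- vector("list", nrow(plan) + 1)
  for (i in seq_len(nrow(plan))) {
    interp_feed(det, read_frames(rec, plan$start[i], plan$n[i]))
    parts[[i]] <- interp_collect(det, geom, p, localize)
  }
  interp_flush(det)
  parts[[nrow(plan) + 1]] <- interp_collect(det, geom, p, localize)
  ev <- bind_rows(parts)
  if (nrow(ev) == 0) return(ev)
  ev <- ev[dedup_cpp(as.numeric(ev$frame), as.numeric(ev$loc), numeric(nrow(ev)),
                     ev$amplitude, as.numeric(ev$loc), 0,
                     p$refractory_ms * 1e-3 * p$sampling_rate_hz), ]
  if (!is.null(dedup_radius_um))
    ev <- remove_duplicates(ev, radius_um = dedup_radius_um, window_ms = 0.5,
                            sampling_rate_hz = p$sampling_rate_hz)
  arrange(select(ev, -"loc", -"row", -"col"), .data$frame)
}

interp_collect <- function(det, geom, p, localize) {
  out <- interp_take(det)
  ev <- as_tibble(out$events)
  if (nrow(ev) == 0) return(NULL)
  li <- interp_locations(geom, as.integer(ev$loc))
  ev <- tibble(frame = as.integer(ev$frame),
               time_s = (as.integer(ev$frame) - 1) / p$sampling_rate_hz,
               loc = as.integer(ev$loc), channel = li$channel,
               on_virtual = li$on_virtual, row = li$row, col = li$col,
               x_grid_um = li$x_um, y_grid_um = li$y_um,
               x_um = li$x_um, y_um = li$y_um,
               amplitude = ev$amplitude, repolarizing = ev$repolarizing > 0)
  if (localize) {
    locd <- localize_batch(out, ev, geom, p)
    ev$x_um <- locd$x_um
    ev$y_um <- locd$y_um
    ev$amplitude_loc <- locd$amplitude
  }
  ev
}
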