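#' Distance attenuation of a point current source
#'
#' Electrodes are given an effective square area (half-width
#' `half_width_um`) inside which a source is measured at full amplitude; the
#' minimum resistance between source and electrode is modelled as an offset
#' distance `r_offset_um`, and outside the effective area the potential falls
#' off as ~1/r:
#' `a = a0 * r_offset / (rho + r_offset)` with
#' `rho = sqrt(max(rx - w, 0)^2 + max(ry - w, 0)^2)`.
#' The literal form with squared length terms in the denominator is available
#' via `squared_form = TRUE`.
#'
#' @param r_offset_um Offset distance (default one fifth of a 42 um pitch).
#' @param half_width_um Effective electrode half-width (default 8.4, i.e. a
#'   16.8 x 16.8 um^2 effective area).
#' @param squared_form Use squared distances in the denominator.
#' @return An `attenuation_model` list.
#' @export
attenuation_model <- function(r_offset_um = 8.4, half_width_um = 8.4,
                              squared_form = FALSE) {
  stopifnot(r_offset_um > 0)
  structure(list(r_offset_um = r_offset_um, half_width_um = half_width_um,
                 squared_form = squared_form), class = "attenuation_model")
}

#' @rdname attenuation_model
#' @param a0 Source peak amplitude (microvolts).
#' @param rx,ry Horizontal distances from the electrode centre along the grid
#'   axes (micrometres, >= 0).
#' @param model An [attenuation_model()].
#' @return `attenuate()`: measured amplitude(s) in microvolts.
#' @examples
#' attenuate(100, 42, 0)  # 1/r regime: 0.2 * a0
#' @export
attenuate <- function(a0, rx, ry, model = attenuation_model()) {
  dx <- pmax(rx - model$half_width_um, 0)
  dy <- pmax(ry - model$half_width_um, 0)
  rho <- if (model$squared_form) dx^2 + dy^2 else sqrt(dx^2 + dy^2)
  a0 * model$r_offset_um / (rho + model$r_offset_um)
}

#' Spike-like voltage template
#'
#' A biphasic, zero-mean "distorted sine": a dominant negative trough
#' (squared sine lobe of width `trough_fraction` of the duration) followed by
#' a shallower positive overshoot balancing the area. The continuous form is
#' evaluated at 16 sub-frame time lags (`lag` in 0..15, each shifting the
#' waveform by `1/(16 f_s)`), so that lag `l + 16` reproduces lag `l` shifted
#' by exactly one frame. Samples have exactly zero mean and minimum -1.
#'
#' @param sampling_rate_hz Sampling rate.
#' @param lag Sub-frame lag index (0..15).
#' @param duration_ms Total template duration (default 1.15 ms, giving a
#'   trough of ~0.4 ms full width).
#' @param trough_fraction Fraction of the duration occupied by the negative
#'   lobe (default 0.35).
#' @return Numeric vector of samples (length covers the duration plus one
#'   frame of margin); attribute `trough` holds the index of the minimum.
#' @export
spike_waveform <- function(sampling_rate_hz, lag = 0, duration_ms = 1.15,
                           trough_fraction = 0.35) {
  dur <- duration_ms * 1e-3
  n <- ceiling(dur * sampling_rate_hz) + 2L
  if (n < 4) abort("template must span at least 4 frames")
  a <- trough_fraction
  tt <- (seq_len(n) - 1 - lag / 16) / sampling_rate_hz
  u <- tt / dur
  w <- numeric(n)
  neg <- u >= 0 & u <= a
  pos <- u > a & u <= 1
  w[neg] <- -sin(pi * u[neg] / a)^2
  w[pos] <- (a / (1 - a)) * sin(pi * (u[pos] - a) / (1 - a))^2
  w <- w - mean(w)
  w <- w / abs(min(w))
  structure(w, trough = which.min(w))
}

#' Synthetic noise recording
#'
#' Emulates an empty-chip recording: independent per-channel Gaussian noise
#' whose standard deviation varies between channels (log-normal spread, plus
#' a small fraction of "noisy" channels at `noisy_gain` times the typical
#' level, giving the pooled amplitude distribution its heavy tails), a slow
#' per-channel baseline drift (AR(1)), and optional per-sample Student-t
#' tails. Channel standard deviations are calibrated so the pooled rms
#' matches `rms_uv`.
#'
#' @param geometry An [mea_geometry()].
#' @param n_frames Number of frames.
#' @param sampling_rate_hz Sampling rate.
#' @param rms_uv Target pooled rms in microvolts (default 26).
#' @param seed RNG seed; identical seeds give bit-identical noise.
#' @param channel_sd_spread Log-normal sd of the channel-to-channel rms
#'   spread (default 0.15).
#' @param noisy_fraction Fraction of channels with `noisy_gain` times the
#'   rms (default 0.02).
#' @param noisy_gain Amplification of noisy channels (default 3).
#' @param drift_uv Stationary sd of the AR(1) drift (default 2).
#' @param drift_phi AR(1) coefficient of the drift (default 0.999).
#' @param colored_fraction Fraction of the fast-noise power carried by a
#'   temporally correlated (AR(1), `colored_phi`) component (default 0.5).
#'   Amplifier and electrode-interface noise is not white: a large share of
#'   its power sits below ~1-2 kHz, inside a typical spike band.
#' @param colored_phi AR(1) coefficient of the colored component (default
#'   0.45, a ~1 kHz corner at 7.5 kHz sampling).
#' @param common_mode_uv RMS of a chip-wide common-mode fluctuation (default
#'   10), shared across channels with per-channel coupling gains spread by
#'   `common_mode_gain_sd` around 1. External fields couple into every
#'   electrode; detectors may remove it via the per-frame channel median.
#' @param common_mode_phi AR(1) coefficient of the common mode (default 0.8,
#'   placing most of its power inside a typical spike band).
#' @param common_mode_gain_sd Spread of the per-channel coupling gains
#'   (default 0.1).
#' @param heavy_tail_df Degrees of freedom of per-sample Student-t noise;
#'   `Inf` (default) gives Gaussian samples.
#' @return A frames x channels matrix in microvolts. Attribute `sigma` holds
#'   the per-channel sd.
#' @export
generate_noise <- function(geometry, n_frames, sampling_rate_hz, rms_uv = 26,
                           seed = 1, channel_sd_spread = 0.15,
                           noisy_fraction = 0.02, noisy_gain = 3,
                           drift_uv = 2, drift_phi = 0.999,
                           colored_fraction = 0.5, colored_phi = 0.45,
                           common_mode_uv = 10, common_mode_phi = 0.8,
                           common_mode_gain_sd = 0.1, heavy_tail_df = Inf) {
  set.seed(seed)
  st <- noise_state(geometry, rms_uv, channel_sd_spread, noisy_fraction,
                    noisy_gain, drift_uv, drift_phi, heavy_tail_df,
                    colored_fraction, colored_phi, common_mode_uv,
                    common_mode_phi, common_mode_gain_sd)
  x <- noise_chunk(st, n_frames)
  attr(x, "sigma") <- st$sigma
  x
}

noise_state <- function(geometry, rms_uv, channel_sd_spread, noisy_fraction,
                        noisy_gain, drift_uv, drift_phi, heavy_tail_df,
                        colored_fraction = 0.5, colored_phi = 0.45,
                        common_mode_uv = 10, common_mode_phi = 0.8,
                        common_mode_gain_sd = 0.1) {
  nch <- n_channels(geometry)
  sigma <- rms_uv * exp(rnorm(nch, 0, channel_sd_spread))
  n_noisy <- round(noisy_fraction * nch)
  noisy <- if (n_noisy > 0) sample.int(nch, n_noisy) else integer(0)
  sigma[noisy] <- sigma[noisy] * noisy_gain
  # calibrate the pooled rms (fast + drift + common mode) to the target
  target_fast <- max(rms_uv^2 - drift_uv^2 - common_mode_uv^2,
                     (0.1 * rms_uv)^2)
  sigma <- sigma * sqrt(target_fast / mean(sigma^2))
  st <- new.env(parent = emptyenv())
  st$sigma <- sigma; st$noisy <- noisy; st$nch <- nch
  st$drift_uv <- drift_uv; st$drift_phi <- drift_phi
  st$drift_innov <- drift_uv * sqrt(1 - drift_phi^2)
  st$drift_state <- rnorm(nch, 0, drift_uv)
  st$df <- heavy_tail_df
  st$cf <- colored_fraction
  st$cphi <- colored_phi
  st$cstate <- rnorm(nch, 0, 1)   # unit-variance AR(1) state
  st$cm_uv <- common_mode_uv
  st$cm_phi <- common_mode_phi
  st$cm_gain <- 1 + rnorm(nch, 0, common_mode_gain_sd)
  st$cm_state <- rnorm(1, 0, 1)
  st
}

noise_chunk <- function(st, n_frames) {
  if (n_frames == 0) return(matrix(numeric(0), 0, st$nch))
  eps <- if (is.finite(st$df)) {
    matrix(stats::rt(n_frames * st$nch, st$df) / sqrt(st$df / (st$df - 2)),
           n_frames, st$nch)
  } else {
    matrix(rnorm(n_frames * st$nch), n_frames, st$nch)
  }
  if (st$cf > 0) {
    col <- ar1_cpp(matrix(rnorm(n_frames * st$nch, 0,
                                sqrt(1 - st$cphi^2)),
                          n_frames, st$nch),
                   st$cstate, st$cphi)
    st$cstate <- col[n_frames, ]
    eps <- sqrt(1 - st$cf) * eps + sqrt(st$cf) * col
  }
  eps <- t(t(eps) * st$sigma)
  if (st$cm_uv > 0) {
    cm <- as.numeric(ar1_cpp(matrix(rnorm(n_frames, 0,
                                          sqrt(1 - st$cm_phi^2))),
                             st$cm_state, st$cm_phi))
    st$cm_state <- cm[n_frames]
    eps <- eps + (st$cm_uv * cm) %o% st$cm_gain
  }
  if (st$drift_uv > 0) {
    dr <- ar1_cpp(matrix(rnorm(n_frames * st$nch, 0, st$drift_innov),
                         n_frames, st$nch),
                  st$drift_state, st$drift_phi)
    st$drift_state <- dr[n_frames, ]
    eps <- eps + dr
  }
  eps
}

#' Spike insertion plan for the ground-truthed benchmark
#'
#' Spike templates are inserted into patches of 3x3 electrodes whose centres
#' are spaced `patch_spacing` electrodes apart. Within each patch, every
#' combination of 16 sub-electrode positions (a 4x4 grid spanning electrode
#' centre to cell corner), 16 sub-frame time lags and the requested
#' amplitudes is inserted once, with consecutive insertions separated by
#' `spacing_frames` frames chip-wide. The combination order is shuffled
#' (seeded) so amplitude and position do not drift systematically with time.
#'
#' @param geometry An [mea_geometry()].
#' @param amplitudes_uv Peak amplitudes `a0` of the inserted sources.
#' @param start_frame First insertion frame (leave room for detector
#'   burn-in).
#' @param spacing_frames Frames between consecutive insertions (default 256).
#' @param patch_spacing Electrode spacing of patch centres (default 4).
#' @param n_positions,n_lags Sub-electrode position and sub-frame lag counts
#'   (default 16 each).
#' @param seed RNG seed for the shuffle.
#' @return A tibble with one row per insertion: `frame` (trough frame),
#'   `patch`, `center_row`, `center_col`, `x_um`, `y_um`, `amplitude_uv`,
#'   `lag`, `position`.
#' @export
insertion_plan <- function(geometry, amplitudes_uv, start_frame = 5000,
                           spacing_frames = 256, patch_spacing = 4,
                           n_positions = 16, n_lags = 16, seed = 1) {
  rows <- seq(2, geometry$n_rows - 1, by = patch_spacing)
  cols <- seq(2, geometry$n_cols - 1, by = patch_spacing)
  patches <- tidyr::expand_grid(center_row = rows, center_col = cols)
  patches$patch <- seq_len(nrow(patches))
  npos_side <- round(sqrt(n_positions))
  offs <- (seq_len(npos_side) - 1) / (npos_side - 1) * geometry$pitch_um / 2
  pos <- tidyr::expand_grid(off_x = offs, off_y = offs)
  pos$position <- seq_len(nrow(pos))
  combos <- tidyr::expand_grid(position = pos$position,
                               lag = seq_len(n_lags) - 1L,
                               amplitude_uv = amplitudes_uv)
  set.seed(seed)
  combos <- combos[sample.int(nrow(combos)), ]
  combos$slot <- seq_len(nrow(combos))
  plan <- tidyr::expand_grid(patch = patches$patch, slot = combos$slot)
  plan <- left_join(plan, patches, by = "patch")
  plan <- left_join(plan, combos, by = "slot")
  plan <- left_join(plan, pos, by = "position")
  # stagger patches within a slot so only a few of the spatially separated
  # patches are ever co-active: simultaneous insertion into every patch
  # would deflect most channels at once and corrupt the global median
  stagger <- max(1L, spacing_frames %/% nrow(patches))
  mutate(plan,
         frame = start_frame + (.data$slot - 1L) * spacing_frames +
           (.data$patch - 1L) * stagger,
         x_um = (.data$center_col - 1) * geometry$pitch_um + .data$off_x,
         y_um = (.data$center_row - 1) * geometry$pitch_um + .data$off_y) |>
    select("frame", "patch", "center_row", "center_col", "x_um", "y_um",
           "amplitude_uv", "lag", "position")
}

#' Insert (or subtract) spikes into a voltage matrix
#'
#' Adds, for every planned insertion, the spike template scaled by the
#' per-electrode attenuation of the source amplitude to the 3x3 patch
#' electrodes. With `sign = -1` a previous insertion is removed exactly.
#'
#' @param x Frames x channels matrix (microvolts); modified copy returned.
#' @param plan Tibble from [insertion_plan()] (any subset of rows).
#' @param geometry An [mea_geometry()].
#' @param sampling_rate_hz Sampling rate.
#' @param model An [attenuation_model()].
#' @param sign +1 to insert, -1 to subtract.
#' @param frame_offset Frame number of row 1 of `x` (for chunked insertion).
#' @param ... Passed to [spike_waveform()].
#' @return The modified matrix.
#' @export
insert_spikes <- function(x, plan, geometry, sampling_rate_hz,
                          model = attenuation_model(), sign = 1,
                          frame_offset = 1, ...) {
  if (nrow(plan) == 0) return(x)
  waves <- lapply(0:15, function(l)
    spike_waveform(sampling_rate_hz, lag = l, ...))
  troughs <- vapply(waves, attr, integer(1), "trough")
  nf <- nrow(x)
  for (i in seq_len(nrow(plan))) {
    w <- waves[[plan$lag[i] + 1L]]
    m0 <- troughs[plan$lag[i] + 1L]
    f1 <- plan$frame[i] - m0 + 1L          # global frame of template sample 1
    r1 <- f1 - frame_offset + 1L           # row in x
    rows_w <- seq_along(w)
    keep <- r1 + rows_w - 1 >= 1 & r1 + rows_w - 1 <= nf
    if (!any(keep)) next
    for (dr in -1:1) for (dc in -1:1) {
      er <- plan$center_row[i] + dr; ec <- plan$center_col[i] + dc
      if (er < 1 || er > geometry$n_rows || ec < 1 || ec > geometry$n_cols) next
      ch <- channel_index(geometry, er, ec)
      amp <- attenuate(plan$amplitude_uv[i],
                       abs((ec - 1) * geometry$pitch_um - plan$x_um[i]),
                       abs((er - 1) * geometry$pitch_um - plan$y_um[i]), model)
      x[r1 + rows_w[keep] - 1, ch] <-
        x[r1 + rows_w[keep] - 1, ch] + sign * amp * w[rows_w[keep]]
    }
  }
  x
}

#' Write a full synthetic benchmark recording to disk
#'
#' Streams noise generation and spike insertion chunk-wise through a
#' flat-binary writer, so arbitrarily long recordings fit in memory.
#'
#' @inheritParams generate_noise
#' @param path Output path for the recording.
#' @param duration_s Recording duration in seconds.
#' @param plan Insertion plan from [insertion_plan()], or NULL for pure
#'   noise.
#' @param model An [attenuation_model()].
#' @param adc_scale_uv Quantization step of the int16 container.
#' @param chunk_frames Frames per generation chunk.
#' @param ... Passed to [spike_waveform()].
#' @return The opened recording (invisible); the plan is its ground truth.
#' @export
simulate_recording <- function(path, geometry, duration_s, sampling_rate_hz,
                               rms_uv = 26, seed = 1, plan = NULL,
                               model = attenuation_model(),
                               adc_scale_uv = 0.1, chunk_frames = NULL,
                               channel_sd_spread = 0.15, noisy_fraction = 0.02,
                               noisy_gain = 3, drift_uv = 2,
                               drift_phi = 0.999, colored_fraction = 0.5,
                               colored_phi = 0.45, common_mode_uv = 10,
                               common_mode_phi = 0.8,
                               common_mode_gain_sd = 0.1,
                               heavy_tail_df = Inf, ...) {
  n_frames <- round(duration_s * sampling_rate_hz)
  chunk_frames <- chunk_frames %||% round(sampling_rate_hz)
  set.seed(seed)
  st <- noise_state(geometry, rms_uv, channel_sd_spread, noisy_fraction,
                    noisy_gain, drift_uv, drift_phi, heavy_tail_df,
                    colored_fraction, colored_phi, common_mode_uv,
                    common_mode_phi, common_mode_gain_sd)
  w <- recording_writer(path, geometry, sampling_rate_hz, adc_scale_uv)
  margin <- 64L
  done <- 0
  while (done < n_frames) {
    n <- min(chunk_frames, n_frames - done)
    x <- noise_chunk(st, n)
    if (!is.null(plan)) {
      sub <- plan[plan$frame >= done + 1 - margin &
                  plan$frame <= done + n + margin, , drop = FALSE]
      x <- insert_spikes(x, sub, geometry, sampling_rate_hz, model,
                         frame_offset = done + 1, ...)
    }
    writer_append(w, x)
    done <- done + n
  }
  writer_close(w)
  invisible(open_recording(path))
}

#' Simulated spike-train rasters for the correlation classifier
#'
#' `simulate_poisson_rasters()` draws independent homogeneous Poisson units;
#' `simulate_burst_rasters()` adds population bursts: burst onsets form a
#' Poisson process, each unit fires in a burst with probability `p_fire`
#' (jittered by `burst_sd_s`), and an independent Poisson "noise" admixture
#' contributes a known per-unit fraction of events. Units sit on a square
#' grid with `spacing_um` between neighbours; burst spikes carry somewhat
#' larger amplitudes than noise spikes, emulating threshold-crossing noise
#' events on real arrays.
#'
#' @param n_units Number of units.
#' @param duration_s Raster duration (seconds).
#' @param rate_hz Poisson rate per unit (pure-Poisson case and noise floor).
#' @param seed RNG seed.
#' @param spacing_um Grid spacing of unit locations (default 42).
#' @param rate_spread Log-normal sd of per-unit rate variation.
#' @return A list with `events` (tibble: `unit`, `time_s`, `amplitude`,
#'   `x_um`, `y_um`, `is_noise`) and `units` (tibble: `unit`, `x_um`,
#'   `y_um`, `rate_hz`, `true_noise_fraction`).
#' @export
simulate_poisson_rasters <- function(n_units, duration_s, rate_hz = 0.2,
                                     seed = 1, spacing_um = 42,
                                     rate_spread = 0.3) {
  set.seed(seed)
  units <- raster_units(n_units, spacing_um, rate_hz, rate_spread)
  ev <- purrr::map(seq_len(n_units), function(u) {
    n <- rpois(1, units$rate_hz[u] * duration_s)
    if (n == 0) return(NULL)
    tibble(unit = u, time_s = sort(runif(n, 0, duration_s)),
           amplitude = 6 + rexp(n, 2), is_noise = TRUE)
  })
  ev <- bind_rows(ev)
  units$true_noise_fraction <- 1
  list(events = left_join(ev, units[c("unit", "x_um", "y_um")], by = "unit"),
       units = units)
}

#' @rdname simulate_poisson_rasters
#' @param burst_rate_hz Rate of population burst onsets.
#' @param p_fire Probability that a unit fires in a given burst.
#' @param burst_sd_s Temporal jitter (sd) of spikes around the burst centre.
#' @param noise_fraction Expected fraction of per-unit events that are
#'   independent Poisson noise (ground truth stored per unit).
#' @export
simulate_burst_rasters <- function(n_units, duration_s, burst_rate_hz = 0.2,
                                   p_fire = 0.8, burst_sd_s = 0.03,
                                   noise_fraction = 0.2, seed = 1,
                                   spacing_um = 42) {
  set.seed(seed)
  units <- raster_units(n_units, spacing_um, rate_hz = burst_rate_hz * p_fire,
                        rate_spread = 0)
  n_bursts <- rpois(1, burst_rate_hz * duration_s)
  burst_t <- sort(runif(n_bursts, 0, duration_s))
  ev <- purrr::map(seq_len(n_units), function(u) {
    fire <- runif(n_bursts) < p_fire
    bt <- rnorm(sum(fire), burst_t[fire], burst_sd_s)
    bt <- bt[bt > 0 & bt < duration_s]
    nn <- rpois(1, length(bt) * noise_fraction / (1 - noise_fraction))
    nt <- runif(nn, 0, duration_s)
    tibble(unit = u,
           time_s = c(bt, nt),
           amplitude = c(6 + rexp(length(bt), 1 / 1.5), 6 + rexp(nn, 2)),
           is_noise = rep(c(FALSE, TRUE), c(length(bt), nn))) |>
      arrange(.data$time_s)
  })
  ev <- bind_rows(ev)
  truef <- ev |> group_by(.data$unit) |>
    summarise(true_noise_fraction = mean(.data$is_noise))
  units <- left_join(units, truef, by = "unit")
  units$true_noise_fraction[is.na(units$true_noise_fraction)] <- 0
  list(events = left_join(ev, units[c("unit", "x_um", "y_um")], by = "unit"),
       units = units)
}

raster_units <- function(n_units, spacing_um, rate_hz, rate_spread) {
  side <- ceiling(sqrt(n_units))
  g <- tidyr::expand_grid(row = seq_len(side), col = seq_len(side))[
    seq_len(n_units), ]
  tibble(unit = seq_len(n_units),
         x_um = (g$col - 1) * spacing_um, y_um = (g$row - 1) * spacing_um,
         rate_hz = rate_hz * exp(rnorm(n_units, 0, rate_spread)))
}
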