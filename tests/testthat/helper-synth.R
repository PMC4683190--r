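# shared fixtures built in code

# small noisy recording written to a temp file; optionally with insertions
tmp_recording <- function(n_rows = 6, n_cols = 6, duration_s = 3, fs = 7563,
                          rms = 20, seed = 11, plan = NULL, drift_uv = 1,
                          noisy_fraction = 0) {
  path <- tempfile(fileext = ".bin")
  geom <- mea_geometry(n_rows, n_cols)
  simulate_recording(path, geom, duration_s, fs, rms_uv = rms, seed = seed,
                     plan = plan, drift_uv = drift_uv,
                     noisy_fraction = noisy_fraction)
}

# single-insertion plan at a given sub-electrode offset
one_insertion <- function(geom, frame, center_row, center_col, a0,
                          off_x = 0, off_y = 0, lag = 0) {
  tibble::tibble(frame = frame, patch = 1L,
                 center_row = center_row, center_col = center_col,
                 x_um = (center_col - 1) * geom$pitch_um + off_x,
                 y_um = (center_row - 1) * geom$pitch_um + off_y,
                 amplitude_uv = a0, lag = as.integer(lag), position = 1L)
}

# hand-built cut-out (see ?localization): channel amplitudes `amps` are
# injected as a 3-frame pulse at the detection peak; baselines zero
make_cutout <- function(amps, virtual = FALSE, chan = NULL, det = NULL,
                        center_slot = if (virtual) NA else 5L,
                        d_pitch = 42, tau_pre = 7L, tau_post = 15L,
                        noise_sd = 0, seed = 1) {
  S <- length(amps)
  T <- tau_pre + tau_post + 1L
  i0 <- tau_pre + 1L
  set.seed(seed)
  snip <- matrix(rnorm(S * T, 0, noise_sd), S, T)
  # pulse shaped so the 4-tap smoother reproduces the amplitude at its peak
  snip[, i0] <- snip[, i0] - amps * 2
  snip[, i0 + 1] <- snip[, i0 + 1] - amps * 1
  if (is.null(chan)) chan <- seq_len(S)
  ir <- (seq_len(S) - 1) %/% 3 - if (virtual) 1.5 else 1
  ic <- (seq_len(S) - 1) %% 3 - if (virtual) 1.5 else 1
  if (is.null(det)) {
    det <- if (!virtual) abs(ir) + abs(ic) <= 1
           else abs(ir) == 0.5 & abs(ic) == 0.5
  }
  coords <- cbind(ic * d_pitch + 5 * d_pitch, ir * d_pitch + 5 * d_pitch)
  list(snip = snip, g = rep(0, T + 1), b = rep(0, S), vbar = rep(1, S),
       hbar = rep(0, S), chan = chan, det = det, center_slot = center_slot,
       coords = coords, detect_x = 5 * d_pitch, detect_y = 5 * d_pitch,
       tau_pre = tau_pre, tau_post = tau_post, d_pitch = d_pitch)
}

# quick event table constructor for dedup tests
ev_table <- function(frame, x, y, amp, channel = seq_along(frame)) {
  tibble::tibble(frame = as.integer(frame), time_s = frame / 7563,
                 channel = as.integer(channel), x_um = x, y_um = y,
                 amplitude = amp, repolarizing = FALSE)
}
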