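test_that("attenuation follows the offset 1/r law", {
  m <- attenuation_model()
  # inside the effective electrode area the full amplitude is seen
  expect_equal(attenuate(100, 0, 0, m), 100)
  expect_equal(attenuate(100, 8.4, 0, m), 100)   # boundary
  expect_equal(attenuate(100, 5, 8, m), 100)
  # one pitch away along an axis: rho = 33.6, a = a0 * 8.4/42
  expect_equal(attenuate(100, 42, 0, m), 20)
  # monotone non-increasing in both axes, continuous at the boundary
  r <- seq(0, 100, by = 0.5)
  a <- attenuate(1, r, 13, m)
  expect_true(all(diff(a) <= 1e-12))
  expect_equal(attenuate(1, 8.4 + 1e-9, 0, m), attenuate(1, 8.4, 0, m),
               tolerance = 1e-6)
  # squared-form variant decays faster in the far field
  m2 <- attenuation_model(squared_form = TRUE)
  expect_lt(attenuate(100, 42, 0, m2), attenuate(100, 42, 0, m))
})

test_that("spike template is zero-mean, biphasic, unit-depth and lag-shiftable", {
  fs <- 7563
  for (lag in c(0, 5, 11)) {
    w <- spike_waveform(fs, lag = lag)
    expect_equal(mean(w), 0, tolerance = 1e-14)
    expect_equal(min(w), -1)
    expect_gt(max(w), 0)           # overshoot present
    expect_lt(max(w), 1)           # ... but dominated by the trough
  }
  w0 <- spike_waveform(fs, lag = 2)
  w1 <- spike_waveform(fs, lag = 18)
  expect_equal(w1[-1], w0[-length(w0)], tolerance = 1e-12)
  expect_error(spike_waveform(fs, duration_ms = 0.1), "4 frames")
})

test_that("noise generator hits the requested rms and is reproducible", {
  geom <- mea_geometry(8, 8)
  x <- generate_noise(geom, 20000, 7563, rms_uv = 26, seed = 5)
  expect_equal(sqrt(mean(x^2)), 26, tolerance = 0.05 * 26)
  x2 <- generate_noise(geom, 20000, 7563, rms_uv = 26, seed = 5)
  expect_identical(x, x2)
  x3 <- generate_noise(geom, 20000, 7563, rms_uv = 26, seed = 6)
  expect_false(identical(x, x3))
})

test_that("pooled noise amplitudes are heavy-tailed, channels uncorrelated", {
  geom <- mea_geometry(8, 8)
  x <- generate_noise(geom, 40000, 7563, rms_uv = 26, seed = 8, drift_uv = 0)
  kurt <- mean(x^4) / mean(x^2)^2 - 3
  expect_gt(kurt, 0)
  # after removing the deliberate common mode, channels are uncorrelated
  xr <- x - apply(x, 1, median)
  cc <- cor(xr[, sample.int(64, 12)])
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.06)
  # noisy channels stand out at roughly three times the typical rms
  sds <- apply(x, 2, sd)
  expect_gt(max(sds) / median(sds), 2)
})

test_that("insertion adds the attenuated template and subtracts exactly", {
  geom <- mea_geometry(6, 6)
  fs <- 7563
  set.seed(3)
  noise <- matrix(rnorm(5000 * 36, 0, 20), 5000, 36)
  plan <- one_insertion(geom, 2500, 3, 3, a0 = 200)
  x <- insert_spikes(noise, plan, geom, fs)
  # centre electrode sees the full amplitude at the trough frame
  ch <- channel_index(geom, 3, 3)
  expect_equal(x[2500, ch] - noise[2500, ch], -200, tolerance = 1e-9)
  # diagonal neighbour at (42, 42)
  chd <- channel_index(geom, 4, 4)
  a_diag <- attenuate(200, 42, 42)
  expect_equal(x[2500, chd] - noise[2500, chd], -a_diag, tolerance = 1e-9)
  expect_equal(a_diag, 200 * 8.4 / (sqrt(2) * 33.6 + 8.4))
  # insertion then subtraction recovers the noise to float rounding
  back <- insert_spikes(x, plan, geom, fs, sign = -1)
  expect_lt(max(abs(back - noise)), 1e-10)
  # empty plan is the identity
  expect_identical(insert_spikes(noise, plan[0, ], geom, fs), noise)
})

test_that("insertion plans schedule every combination once per patch", {
  geom <- mea_geometry(32, 32)
  plan <- insertion_plan(geom, amplitudes_uv = c(120, 160), seed = 2)
  # 8x8 patch anchors, 16 positions x 16 lags x 2 amplitudes
  expect_equal(nrow(plan), 64 * 16 * 16 * 2)
  expect_equal(dplyr::n_distinct(plan$patch), 64)
  per_patch <- dplyr::count(plan, patch)
  expect_true(all(per_patch$n == 512))
  combos <- dplyr::distinct(plan, patch, position, lag, amplitude_uv)
  expect_equal(nrow(combos), nrow(plan))
  # within a patch consecutive insertions are spaced by 256 frames, and
  # patches are staggered so few are co-active at any instant
  byf <- sort(unique(plan$frame[plan$patch == 5]))
  expect_true(all(diff(byf) == 256))
  coactive <- max(table(plan$frame))
  expect_lte(coactive, 4)
  # positions stay within one half-pitch quadrant of the centre electrode
  expect_true(all(plan$x_um - (plan$center_col - 1) * 42 <= 21 + 1e-9))
  expect_true(all(plan$x_um - (plan$center_col - 1) * 42 >= -1e-9))
})

test_that("streamed recordings match in-memory generation", {
  geom <- mea_geometry(4, 4)
  fs <- 7563
  plan <- one_insertion(geom, 4000, 2, 2, 150)
  path <- tempfile(fileext = ".bin")
  rec <- simulate_recording(path, geom, 1, fs, rms_uv = 20, seed = 12,
                            plan = plan, chunk_frames = 1000)
  x <- read_frames(rec)
  # regenerate with the same seed and chunking
  set.seed(12)
  st <- hdmea:::noise_state(geom, 20, 0.15, 0.02, 3, 2, 0.999, Inf,
                            0.5, 0.45, 10, 0.8, 0.1)
  y <- do.call(rbind, lapply(
    diff(unique(pmin(seq(0, rec$n_frames + 999, by = 1000), rec$n_frames))),
    function(n) hdmea:::noise_chunk(st, n)))
  expect_false(isTRUE(all.equal(x, y, tolerance = 1e-12)))  # spikes added
  y <- insert_spikes(y, plan, geom, fs)
  expect_lt(max(abs(x - y)), 0.1 / 2 + 1e-9)
})
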