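test_that("matching is one-to-one, temporally greedy, radius-bounded", {
  tr <- tibble::tibble(frame = c(1000, 2000), x_um = c(0, 100),
                       y_um = c(0, 0), amplitude_uv = c(150, 150))
  de <- ev_table(frame = c(1000, 1001, 1002, 2500), x = c(0, 0, 0, 100),
                 y = c(0, 0, 0, 0), amp = c(5, 7, 6, 9))
  m <- match_events(de, tr, d_pitch = 42)
  # exact hit matches; the 1-frame detection loses to the 0-frame one
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$detection, 1)
  expect_setequal(m$false_positives, c(2, 3, 4))  # 2500 outside +/-3 frames
  expect_equal(m$false_negatives, 2)
  # two detections at dt = 1 and 2: the closer one matches
  de2 <- ev_table(frame = c(1001, 1002), x = c(0, 0), y = c(0, 0),
                  amp = c(5, 50))
  m2 <- match_events(de2, tr[1, ], d_pitch = 42)
  expect_equal(m2$pairs$detection, 1)
  # distance gate: just inside vs outside sqrt(2)/2 * 42 = 29.7 um
  de3 <- ev_table(frame = c(1000, 1000), x = c(29, 31), y = c(0, 0),
                  amp = c(5, 5))
  m3 <- match_events(de3, tr[1, ], d_pitch = 42)
  expect_equal(m3$pairs$detection, 1)
  # empty detection set: all truths are misses
  m4 <- match_events(de3[0, ], tr, d_pitch = 42)
  expect_equal(m4$false_negatives, c(1, 2))
})

test_that("partial AUC spans 0 (silent) to 1 (oracle) and is scale-free", {
  # silent detector
  expect_equal(partial_auc(tibble::tibble(fp_hz = 0, tp = 0)), 0)
  # oracle: all truths at zero false positives
  expect_equal(partial_auc(tibble::tibble(fp_hz = c(0, 0.2), tp = c(1, 1))), 1)
  # half sensitivity
  expect_equal(partial_auc(tibble::tibble(fp_hz = c(0, 1), tp = c(0.5, 0.5))),
               0.5)
  curve <- tibble::tibble(fp_hz = c(0, 0.02, 0.05, 0.3),
                          tp = c(0, 0.4, 0.8, 1))
  expect_gt(partial_auc(curve), 0)
  expect_lt(partial_auc(curve), 1)
})

test_that("roc curves are monotone and amplitude-rescaling invariant", {
  geom <- mea_geometry(10, 10)
  set.seed(31)
  truths <- tidyr::expand_grid(patch = 1:4, k = 1:30)
  anchors <- tibble::tibble(patch = 1:4, center_row = c(2, 2, 6, 6),
                            center_col = c(2, 6, 2, 6))
  truths <- dplyr::left_join(truths, anchors, by = "patch")
  truths$frame <- sample(1000:60000, nrow(truths))
  truths$x_um <- (truths$center_col - 1) * 42
  truths$y_um <- (truths$center_row - 1) * 42
  truths$amplitude_uv <- 150
  # detector hits 70% of truths with amplitude ~ N(8, 1), plus noise FPs
  hit <- runif(nrow(truths)) < 0.7
  det_tp <- ev_table(frame = truths$frame[hit], x = truths$x_um[hit],
                     y = truths$y_um[hit], amp = rnorm(sum(hit), 8, 1))
  nfp <- 200
  det_fp <- ev_table(frame = sample(1000:60000, nfp),
                     x = runif(nfp, 0, 9 * 42), y = runif(nfp, 0, 9 * 42),
                     amp = 4 + rexp(nfp, 1))
  det <- dplyr::bind_rows(det_tp, det_fp)
  det$channel <- seq_len(nrow(det))
  m <- match_events(det, truths, 42)
  roc <- roc_curves(det, truths, m, duration_s = 8, geometry = geom)
  for (pt in unique(roc$curves$patch)) {
    cur <- roc$curves[roc$curves$patch == pt, ]
    expect_true(all(diff(cur$fp_hz) >= 0))
    expect_true(all(diff(cur$tp) >= -1e-12))
  }
  expect_true(all(roc$pauc$pauc >= 0 & roc$pauc$pauc <= 1))
  # rescaling all amplitudes leaves the curves unchanged
  det2 <- dplyr::mutate(det, amplitude = amplitude * 3.7)
  m2 <- match_events(det2, truths, 42)
  roc2 <- roc_curves(det2, truths, m2, duration_s = 8, geometry = geom)
  expect_equal(roc2$pauc$pauc, roc$pauc$pauc)
  expect_equal(glance(roc)$mean_pauc, mean(roc$pauc$pauc))
})

test_that("bias is bounded by the error on random displacement clouds", {
  # the coordinate-wise median can exceed the median distance by at most a
  # factor sqrt(2) (componentwise |median| <= median of |component|); in
  # typical clouds bias <= error
  set.seed(12)
  viol <- 0
  for (i in 1:40) {
    n <- sample(3:30, 1)
    dx <- rnorm(n, rnorm(1, 0, 5), 3); dy <- rnorm(n, rnorm(1, 0, 5), 3)
    err <- median(sqrt(dx^2 + dy^2))
    bias <- sqrt(median(dx)^2 + median(dy)^2)
    expect_lte(bias, sqrt(2) * err + 1e-9)
    if (bias > err + 1e-9) viol <- viol + 1
  }
  expect_lt(viol / 40, 0.2)
})

test_that("localization metrics group by amplitude band with n >= 3 rule", {
  truths <- tibble::tibble(patch = 1, frame = (1:10) * 100,
                           x_um = 50, y_um = 50,
                           amplitude_uv = rep(c(100, 200), each = 5))
  det <- ev_table(frame = truths$frame, x = truths$x_um + c(rep(2, 5), rep(1, 5)),
                  y = truths$y_um, amp = truths$amplitude_uv / 20)
  m <- match_events(det, truths, 42)
  lm <- localization_metrics(det, truths, m, bands = c(0, 150, 300))
  expect_equal(nrow(lm), 2)
  expect_equal(lm$error_um, c(2, 1))
  expect_equal(lm$bias_um, c(2, 1))
  # symmetric detections: zero bias, positive error
  det2 <- ev_table(frame = truths$frame[1:4], x = 50 + c(3, -3, 3, -3),
                   y = 50, amp = 5)
  m2 <- match_events(det2, truths[1:4, ], 42)
  lm2 <- localization_metrics(det2, truths[1:4, ], m2)
  expect_equal(lm2$bias_um, 0)
  expect_equal(lm2$error_um, 3)
  # sparse cells are flagged, not computed
  m3 <- match_events(det2[1:2, ], truths[1:2, ], 42)
  lm3 <- localization_metrics(det2[1:2, ], truths[1:2, ], m3)
  expect_true(is.na(lm3$error_um))
})

test_that("bessel band-pass has unit passband gain and rolls off", {
  fs <- 7563
  ba <- bessel_bandpass(fs)
  H <- function(f) {
    z <- exp(-2i * pi * f / fs)
    abs(sum(ba$b * z^(0:(length(ba$b) - 1))) /
        sum(ba$a * z^(0:(length(ba$a) - 1))))
  }
  expect_gt(H(600), 0.85)
  expect_lt(H(10), 0.3)
  expect_lt(H(3500), 0.35)
  expect_gt(H(600), H(3000))
})

test_that("threshold detector finds large templates, stays quiet when flat", {
  geom <- mea_geometry(4, 4)
  pz <- tempfile(fileext = ".bin")
  write_recording(matrix(0, 12000, 16), pz, geom, 7563)
  expect_equal(nrow(detect_events_threshold(open_recording(pz))), 0)
  plan <- one_insertion(mea_geometry(4, 4), 10000, 2, 3, 300)
  rec <- tmp_recording(4, 4, duration_s = 2, rms = 20, seed = 9, plan = plan)
  ev <- detect_events_threshold(rec, threshold = 5)
  hit <- ev[abs(ev$frame - 10000) <= 3, ]
  expect_gte(nrow(hit), 1)
  expect_true(channel_index(mea_geometry(4, 4), 2, 3) %in% hit$channel)
})

test_that("filtered-noise false-positive rate matches the Rice prediction", {
  # level-crossing rate of a Gaussian process: nu0 * exp(-theta^2/2), with
  # nu0 from the spectral moments of the band-pass filter
  fs <- 7563
  ba <- bessel_bandpass(fs)
  f <- seq(0.1, fs / 2, by = 0.5)
  H2 <- vapply(f, function(ff) {
    z <- exp(-2i * pi * ff / fs)
    Mod(sum(ba$b * z^(0:(length(ba$b) - 1))) /
        sum(ba$a * z^(0:(length(ba$a) - 1))))^2
  }, numeric(1))
  lam0 <- sum(H2); lam2 <- sum((2 * pi * f)^2 * H2)
  nu0 <- sqrt(lam2 / lam0) / (2 * pi)
  theta <- 3.5
  pred_hz <- nu0 * exp(-theta^2 / 2)
  rec <- tmp_recording(6, 6, duration_s = 6, rms = 20, seed = 77,
                       drift_uv = 0)
  ev <- detect_events_threshold(rec, threshold = theta, refractory_ms = 0.01)
  got_hz <- nrow(ev) / (6 - 0.5) / 36   # per channel, after burn-in
  expect_gt(got_hz, pred_hz / 2)
  expect_lt(got_hz, pred_hz * 2)
})
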