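test_that("channel amplitudes: kernel arithmetic and degenerate snippets", {
  # flat snippet -> amplitude 0 on every channel
  cut <- make_cutout(rep(0, 9))
  expect_equal(channel_amplitudes(cut), rep(0, 9))
  # constant offset c: baseline shifts with the signal, amplitude unchanged
  cut2 <- make_cutout(rep(0, 9))
  cut2$snip <- cut2$snip + 3.7
  expect_equal(channel_amplitudes(cut2), rep(0, 9))
  # unit impulse at t0: the 4-tap kernel (1/6, 1/3, 1/3, 1/6) passes 1/3
  cut3 <- make_cutout(rep(0, 9))
  cut3$snip[5, cut3$tau_pre + 1] <- -1
  expect_equal(channel_amplitudes(cut3)[5], 1 / 3)
  # missing channels give NA until repaired
  cut4 <- make_cutout(rep(1, 9), chan = c(0, 2:9))
  expect_true(is.na(channel_amplitudes(cut4)[1]))
})

test_that("boundary surrogates and outlier clipping follow the local sums", {
  co <- make_cutout(rep(0, 9))$coords
  det <- make_cutout(rep(0, 9))$det
  # no missing channels, no outliers: only the 20th-percentile shift
  A <- c(1, 1, 1, 1, 5, 1, 1, 1, 1)
  out <- repair_boundary_outliers(A, rep(TRUE, 9), det, co, 42, 5L)
  expect_equal(out, A - as.numeric(quantile(A, 0.2)))
  # missing corner with 3 available neighbours of median m -> 3m/8
  A2 <- c(NA, 2, 9, 4, 9, 9, 9, 9, 9)
  avail <- c(FALSE, rep(TRUE, 8))
  out2 <- repair_boundary_outliers(A2, avail, det, co, 42, 5L)
  # corner slot 1 is adjacent to slots 2, 4, 5; median(2, 4, 9) = 4
  surrogate <- 3 / 8 * 4
  expect_equal(out2[1], surrogate - as.numeric(
    quantile(c(surrogate, A2[-1]), 0.2)))
  # a non-centre channel towering over its neighbourhood is clipped
  A3 <- c(0, 0, 0, 0, 1, 0, 0, 0, 100)
  out3 <- repair_boundary_outliers(A3, rep(TRUE, 9), det, co, 42, 5L)
  A3s <- pmax(A3, 0) - as.numeric(quantile(A3, 0.2))
  s9 <- sum(A3s[c(5, 6, 8, 9)])   # slot 9 neighbourhood: 5, 6, 8 + itself
  expect_equal(out3[9], s9 / 3)   # non-detection channel: 1/3 rule
  expect_lt(out3[9], A3s[9])
  # the centre channel is never clipped
  A4 <- c(0, 0, 0, 0, 100, 0, 0, 0, 0)
  out4 <- repair_boundary_outliers(A4, rep(TRUE, 9), det, co, 42, 5L)
  expect_equal(out4[5], pmax(A4, 0)[5] - as.numeric(quantile(A4, 0.2)))
})

test_that("localization lands on symmetry points exactly", {
  # amplitudes symmetric about the centre electrode
  cut <- make_cutout(c(1, 2, 1, 2, 8, 2, 1, 2, 1))
  res <- localize_cutout(cut)
  expect_equal(res$x_um, cut$detect_x)
  expect_equal(res$y_um, cut$detect_y)
  expect_gt(res$amplitude, 0)
  # equal amplitudes on a 2x2 block, zero elsewhere -> block midpoint
  amps <- rep(0, 9); amps[c(5, 6, 8, 9)] <- 4
  cut2 <- make_cutout(amps)
  res2 <- localize_cutout(cut2)
  expect_equal(res2$x_um, cut$detect_x + 21)
  expect_equal(res2$y_um, cut$detect_y + 21)
  # degenerate: nothing above the median -> detection centre, amplitude 0
  cut3 <- make_cutout(rep(1, 9))
  res3 <- localize_cutout(cut3)
  expect_equal(res3$x_um, cut$detect_x)
  expect_equal(res3$amplitude, 0)
})

test_that("location is invariant under amplitude scaling and stays in hull", {
  set.seed(5)
  for (i in 1:25) {
    amps <- rexp(9, 1 / 3)
    cut <- make_cutout(amps)
    res <- localize_cutout(cut)
    cutk <- make_cutout(amps * 7.5)
    resk <- localize_cutout(cutk)
    expect_equal(res$x_um, resk$x_um, tolerance = 1e-9)
    expect_equal(res$y_um, resk$y_um, tolerance = 1e-9)
    expect_equal(resk$amplitude, 7.5 * res$amplitude, tolerance = 1e-9)
    # within the bounding box of contributing channels
    expect_gte(res$x_um, min(cut$coords[, 1]))
    expect_lte(res$x_um, max(cut$coords[, 1]))
    expect_gte(res$y_um, min(cut$coords[, 2]))
    expect_lte(res$y_um, max(cut$coords[, 2]))
  }
})

test_that("vectorized batch localization equals the per-event reference", {
  set.seed(16)
  geom <- mea_geometry(10, 10)
  SL <- 12L; T <- 23L
  n <- 30
  ev <- tibble::tibble(
    on_virtual = rep(c(FALSE, TRUE), length.out = n),
    row = ifelse(rep(c(FALSE, TRUE), length.out = n),
                 sample(3:7, n, TRUE) + 0.5, sample(3:8, n, TRUE)),
    col = ifelse(rep(c(FALSE, TRUE), length.out = n),
                 sample(3:7, n, TRUE) + 0.5, sample(3:8, n, TRUE)))
  ev$x_grid_um <- (ev$col - 1) * 42
  ev$y_grid_um <- (ev$row - 1) * 42
  used <- ifelse(ev$on_virtual, 12L, 9L)
  snip <- array(0, c(T, SL, n)); b <- vb <- hb <- ch <- dt <- matrix(0, SL, n)
  g <- matrix(rnorm((T + 1) * n, 0, 0.2), T + 1, n)
  for (e in seq_len(n)) {
    u <- seq_len(used[e])
    ir <- (u - 1) %/% 3 - if (ev$on_virtual[e]) 1.5 else 1
    ic <- (u - 1) %% 3 - if (ev$on_virtual[e]) 1.5 else 1
    for (s in u) {
      miss <- runif(1) < 0.08
      ch[s, e] <- if (miss) 0 else s + (e - 1) * SL
      dt[s, e] <- if (ev$on_virtual[e]) abs(ir[s]) == 0.5 && abs(ic[s]) == 0.5
                  else abs(ir[s]) + abs(ic[s]) <= 1
      if (!miss) {
        b[s, e] <- rnorm(1, 0, 2)
        vb[s, e] <- rexp(1) + 0.5
        hb[s, e] <- runif(1, -0.2, 0.8)
        snip[, s, e] <- rnorm(T, b[s, e], 1) - c(rep(0, 7), 8 * rexp(1),
                                                 rep(0, 15))
      }
    }
  }
  out <- list(snip = as.numeric(snip), g = as.numeric(g), b = as.numeric(b),
              vbar = as.numeric(vb), hbar = as.numeric(hb),
              chan = as.integer(ch), det = as.integer(dt),
              slots = SL, snip_len = T)
  p <- interp_params(7000)  # 1 ms / 2.2 ms -> 7 / 15 frames
  got <- hdmea:::localize_batch(out, ev, geom, p)
  for (e in seq_len(n)) {
    u <- seq_len(used[e])
    ir <- (u - 1) %/% 3 - if (ev$on_virtual[e]) 1.5 else 1
    ic <- (u - 1) %% 3 - if (ev$on_virtual[e]) 1.5 else 1
    cut <- list(snip = t(snip[, u, e]), g = g[, e], b = b[u, e],
                vbar = vb[u, e], hbar = hb[u, e], chan = ch[u, e],
                det = dt[u, e] > 0,
                center_slot = if (ev$on_virtual[e]) NA else 5L,
                coords = cbind((ev$col[e] - 1 + ic) * 42,
                               (ev$row[e] - 1 + ir) * 42),
                detect_x = ev$x_grid_um[e], detect_y = ev$y_grid_um[e],
                tau_pre = 7L, tau_post = 15L, d_pitch = 42)
    ref <- localize_cutout(cut)
    expect_equal(got$x_um[e], ref$x_um, tolerance = 1e-9)
    expect_equal(got$y_um[e], ref$y_um, tolerance = 1e-9)
    expect_equal(got$amplitude[e], ref$amplitude, tolerance = 1e-9)
  }
})

test_that("localization bias points towards electrode centres on average", {
  # high-amplitude sources offset from an electrode centre: the estimate is
  # pulled towards the centre (documented bias), with error < half a pitch
  geom <- mea_geometry(6, 6)
  offs <- c(7, 14, 21)
  errs <- c(); pulls <- c()
  for (k in seq_along(offs)) {
    plan <- one_insertion(geom, 12000, 3, 4, 300, off_x = offs[k], off_y = 0)
    rec <- tmp_recording(6, 6, duration_s = 2.2, rms = 16, seed = 40 + k,
                         plan = plan)
    ev <- detect_events_interp(rec)
    hit <- ev[abs(ev$frame - 12000) <= 3, ]
    if (nrow(hit) == 1) {
      errs <- c(errs, sqrt((hit$x_um - plan$x_um)^2 +
                           (hit$y_um - plan$y_um)^2))
      pulls <- c(pulls, hit$x_um - plan$x_um)  # negative = towards centre
    }
  }
  expect_gte(length(errs), 2)
  expect_lt(median(errs), 21)
})
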