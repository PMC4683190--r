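test_that("expected coincidence counts follow the rank-window formula", {
  # tau_corr * n_i * n_j / sum(n_k) = 20 * 100 * 50 / 1000 = 100
  set.seed(1)
  ranked <- tibble::tibble(
    unit = rep(c(1L, 2L, 3L), c(100, 50, 850)),
    ref_unit = ifelse(rep(c(1, 2, 3), c(100, 50, 850)) == 2, 2L, NA_integer_),
    amplitude = 7, is_real = TRUE, is_clock = FALSE)
  ranked$rank <- sample(nrow(ranked))
  sel <- list(units = tibble::tibble(unit = 1:3, x_um = c(0, 500, 900),
                                     y_um = 0, n_events = c(100, 50, 850),
                                     is_reference = c(FALSE, TRUE, FALSE)),
              ref_units = tibble::tibble(ref_unit = 2L, x_um = 500, y_um = 0,
                                         n_events = 50, excluded = FALSE))
  links <- build_links(ranked, sel, tau_corr = 20, d_min_um = 42)
  p12 <- links$pairs[links$pairs$unit == 1 & links$pairs$ref_unit == 2, ]
  expect_equal(p12$expected, 20 * 100 * 50 / 1000)
  # shrinking the window shrinks the expectation towards zero
  links2 <- build_links(ranked, sel, tau_corr = 2, d_min_um = 42)
  p12b <- links2$pairs[links2$pairs$unit == 1 & links2$pairs$ref_unit == 2, ]
  expect_equal(p12b$expected, 2 * 100 * 50 / 1000)
  # pairs closer than the distance floor are never tested
  sel$units$x_um[1] <- 480
  links3 <- build_links(ranked, sel, tau_corr = 20, d_min_um = 42)
  expect_false(any(links3$pairs$unit == 1 & links3$pairs$ref_unit == 2))
})

test_that("correlated unit pairs link; independent Poisson pairs do not", {
  linked_frac <- function(sim, seed) {
    cls <- classify_events(sim$events, duration_s = 200,
                           sampling_rate_hz = 800, seed = seed)
    pr <- cls$links$pairs
    pr <- pr[pr$ref_unit != 0 & !pr$removed, ]
    mean(pr$linked)
  }
  burst <- vapply(1:5, function(s)
    linked_frac(simulate_burst_rasters(20, 200, seed = s), s), numeric(1))
  pois <- vapply(1:5, function(s)
    linked_frac(simulate_poisson_rasters(20, 200, rate_hz = 0.5, seed = s + 50),
                s), numeric(1))
  expect_true(all(burst > 0.5))
  expect_true(all(pois < 0.25))
})

test_that("correlation index matches brute-force enumeration", {
  # constructed neighbourhood: 4 reference events, 2 from linked units that
  # are mutually linked -> CI = (2/4) * (1/1) = 0.5
  ranked <- tibble::tibble(
    unit = c(1L, 2L, 3L, 4L, 4L),
    ref_unit = c(NA, 2L, 3L, 4L, 4L),
    rank = c(100L, 90L, 95L, 105L, 110L),
    amplitude = 7, is_real = TRUE, is_clock = FALSE)
  links <- make_links(units = 1:4, ref_ids = c(0L, 2L, 3L, 4L),
                      linked_pairs = list(c(1, 2), c(1, 3), c(2, 3), c(3, 2)))
  got <- correlation_index(ranked, links)
  expect_equal(got$ci[1], 0.5)
  expect_equal(got$ci, ci_bruteforce(ranked, links))
  # no coactive reference events -> CI 0
  ranked2 <- ranked; ranked2$rank[1] <- 1000L
  expect_equal(correlation_index(ranked2, links)$ci[1], 0)
  # all coactive from linked, mutually linked units -> CI 1
  ranked3 <- ranked[1:3, ]
  expect_equal(correlation_index(ranked3, links)$ci[1], 1)
  # randomized configurations against the oracle
  set.seed(33)
  for (i in 1:10) {
    n <- 60
    units <- 1:6; refs <- c(0L, 2L, 5L, 6L)
    rk <- tibble::tibble(
      unit = sample(units, n, TRUE),
      amplitude = rexp(n) + 6,
      rank = sample(500L, n),
      is_clock = FALSE)
    rk$is_real <- TRUE
    rk$ref_unit <- ifelse(rk$unit %in% c(2L, 5L, 6L), rk$unit, NA_integer_)
    clock <- tibble::tibble(unit = NA_integer_, amplitude = NA_real_,
                            rank = seq(5L, 500L, by = 25L),
                            is_clock = TRUE, is_real = FALSE,
                            ref_unit = 0L)
    rk <- dplyr::bind_rows(rk, clock)
    pairs <- list()
    for (u in units) for (j in c(2L, 5L, 6L))
      if (runif(1) < 0.4) pairs <- c(pairs, list(c(u, j)))
    links_i <- make_links(units, refs, pairs, tau_corr = sample(c(40, 100), 1))
    got <- correlation_index(rk, links_i)
    expect_equal(got$ci, ci_bruteforce(rk, links_i))
  }
})

test_that("surrogates are uniform in population rank", {
  sim <- simulate_poisson_rasters(30, 400, rate_hz = 0.5, seed = 2)
  sel <- select_reference_units(sim$events, mode = "online")
  ranked <- rank_events(sel, duration_s = 400, sampling_rate_hz = 800,
                        surrogate_rate_hz = 0.5, seed = 7)
  surr <- ranked$rank[!ranked$is_real & !ranked$is_clock]
  expect_gt(length(surr), 500)
  ks <- suppressWarnings(ks.test(surr / nrow(ranked), "punif"))
  expect_gt(ks$p.value, 0.01)
  # clock events appear every fourth frame
  ck <- sort(ranked$time_s[ranked$is_clock])
  expect_equal(diff(ck)[1], 4 / 800)
  # reference units receive no surrogates
  refu <- sel$units$unit[sel$units$is_reference]
  expect_equal(sum(ranked$unit %in% refu & !ranked$is_real), 0)
})

test_that("units matching their surrogate CI distribution classify as noise", {
  set.seed(41)
  v <- round(runif(120), 3)
  indexed <- tibble::tibble(
    unit = 1L,
    ref_unit = NA_integer_,
    rank = seq_len(240),
    amplitude = c(rexp(120) + 6, rep(NA, 120)),
    is_real = rep(c(TRUE, FALSE), each = 120),
    is_clock = FALSE,
    ci = c(v, v))
  cls <- classify_units(indexed)
  expect_equal(cls$units$method, "conservative")
  expect_gte(cls$units$fraction_uncorrelated, 0.95)
  # perfectly separated: all events correlated
  indexed2 <- indexed
  indexed2$ci <- rep(c(1, 0), each = 120)
  cls2 <- classify_units(indexed2)
  expect_lte(cls2$units$fraction_uncorrelated, 0.05)
  p2 <- cls2$events$p_uncorrelated
  expect_true(all(p2 <= 0.05))
  # unit without surrogates is flagged
  indexed3 <- indexed[indexed$is_real, ]
  cls3 <- classify_units(indexed3)
  expect_equal(cls3$units$method, "flagged")
})

test_that("per-event probabilities renormalize to the uncorrelated count", {
  set.seed(6)
  # mixed unit: low-CI events are mostly surrogate-like
  ci <- c(runif(60, 0, 0.4), runif(140, 0.3, 1))
  surr <- runif(70, 0, 0.45)
  P <- 60
  p <- sliding_window_probability(ci, surr, P)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(abs(sum(p) - P), 1 + 0.1 * sum(p > 1 - 1e-9))
  # low-CI events carry higher uncorrelated probability
  expect_gt(mean(p[ci < 0.3]), mean(p[ci > 0.6]))
  # no surrogates anywhere -> all probabilities zero
  expect_equal(sliding_window_probability(c(0.1, 0.5, 0.9), numeric(0), 2),
               rep(0, 3))
  # degenerate all-equal CIs -> uniform P/N
  expect_equal(sliding_window_probability(rep(0.5, 4), rep(0.5, 3), 2),
               rep(0.5, 4))
})

test_that("window length optimization matches exhaustive search", {
  set.seed(14)
  for (i in 1:8) {
    n <- sample(20:120, 1)
    ns <- sample(10:60, 1)
    ci <- round(runif(n), 2)
    surr <- round(runif(ns, 0, 0.7), 2)
    P <- sample(seq_len(n), 1)
    ref <- brute_L(ci, surr, P)
    got <- sliding_window_probability(ci, surr, P)
    want <- numeric(n); want[order(ci)] <- ref$p_sorted
    expect_equal(got, want)
  }
})

test_that("reference selection finds activity maxima", {
  # single active channel is a vacuous local maximum
  ev <- tibble::tibble(unit = 1L, channel = 1L, x_um = 0, y_um = 0,
                       time_s = 1:5, amplitude = 7)
  sel <- select_reference_units(ev, mode = "online")
  expect_true(sel$units$is_reference)
  # clustered blobs on a fine raster: maxima recovered near the centres,
  # and maxima closer than 15 um merge
  set.seed(3)
  geom <- mea_geometry(16, 16)
  centers <- tibble::tibble(x = c(100, 300, 500), y = c(120, 350, 200))
  ev2 <- purrr::map_dfr(seq_len(nrow(centers)), function(i)
    tibble::tibble(x_um = rnorm(300, centers$x[i], 6),
                   y_um = rnorm(300, centers$y[i], 6)))
  ev2$time_s <- runif(nrow(ev2), 0, 60)
  ev2$amplitude <- 7
  sel2 <- select_reference_units(ev2, geometry = geom, mode = "interp",
                                 n_exclude = 0)
  ref <- sel2$ref_units
  expect_gte(nrow(ref), 3)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((ref$x_um - centers$x[i])^2 + (ref$y_um - centers$y[i])^2)
    expect_lt(min(d), 15)
  }
  # most-active exclusion drops the requested number of reference units
  sel3 <- select_reference_units(ev2, geometry = geom, mode = "interp",
                                 n_exclude = 1)
  expect_equal(sum(sel3$ref_units$excluded), 1)
})
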