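#' Select reference units for the correlation analysis
#'
#' Coincidences are counted against a limited set of high-activity
#' "reference" units. For single-electrode detections (`mode = "online"`,
#' also appropriate for pre-binned unit rasters) a unit is a channel, and
#' channels whose event rate is a local maximum (no more active unit within
#' `d_local_um`) become references. For interpolating detections
#' (`mode = "interp"`) event locations are first rastered into
#' `bins_coarse^2` bins, grouped 3x3 into units; a finer raster
#' (`bins_fine^2`), smoothed with a cone-shaped kernel, yields local density
#' maxima separated by at least `max_sep_um`; events within `ref_radius_um`
#' of a maximum form the reference units (overlaps resolved towards the
#' closer maximum). In both modes the `n_exclude` most active reference
#' units are dropped, as extreme activity is suspicious of noise.
#'
#' @param events Event tibble with locations; either a `unit` column
#'   (pre-binned) or `channel` (online mode), or continuous `x_um`, `y_um`
#'   (interp mode).
#' @param geometry An [mea_geometry()] (needed for interp binning).
#' @param mode `"online"` or `"interp"`.
#' @param d_local_um Local-maximum neighbourhood for online mode (42 um).
#' @param n_exclude Number of most-active reference units to exclude (10).
#' @param bins_coarse,bins_fine Raster resolutions for interp mode.
#' @param kernel_radius_um Cone-kernel radius for density smoothing (15 um).
#' @param max_sep_um Minimum separation of density maxima (15 um).
#' @param ref_radius_um Radius around a maximum collecting reference events
#'   (21 um).
#' @return A list: `events` (input plus `unit` and `ref_unit` columns),
#'   `units` (tibble `unit`, `x_um`, `y_um`, `n_events`, `is_reference`) and
#'   `ref_units` (tibble `ref_unit`, `x_um`, `y_um`, `n_events`, `excluded`).
#' @export
select_reference_units <- function(events, geometry = NULL,
                                   mode = c("online", "interp"),
                                   d_local_um = 42, n_exclude = 10,
                                   bins_coarse = 192, bins_fine = 320,
                                   kernel_radius_um = 15, max_sep_um = 15,
                                   ref_radius_um = 21) {
  mode <- match.arg(mode)
  if (nrow(events) == 0)
    return(list(events = events,
                units = tibble(unit = integer(0), x_um = numeric(0),
                               y_um = numeric(0), n_events = integer(0),
                               is_reference = logical(0)),
                ref_units = tibble(ref_unit = integer(0), x_um = numeric(0),
                                   y_um = numeric(0), n_events = integer(0),
                                   excluded = logical(0))))
  if (mode == "online") {
    if (!"unit" %in% names(events)) events$unit <- events$channel
    units <- events |>
      group_by(.data$unit) |>
      summarise(x_um = .data$x_um[1], y_um = .data$y_um[1],
                n_events = dplyr::n(), .groups = "drop")
    # local maximum: no unit within d_local has a strictly higher count
    # (ties resolved towards the lower unit id)
    is_ref <- vapply(seq_len(nrow(units)), function(i) {
      d <- sqrt((units$x_um - units$x_um[i])^2 +
                (units$y_um - units$y_um[i])^2)
      nb <- which(d <= d_local_um + 1e-9 & d > 1e-9)
      all(units$n_events[nb] < units$n_events[i] |
            (units$n_events[nb] == units$n_events[i] &
             units$unit[nb] > units$unit[i]))
    }, logical(1))
    units$is_reference <- is_ref
    events$ref_unit <- ifelse(events$unit %in% units$unit[is_ref],
                              events$unit, NA_integer_)
  } else {
    if (is.null(geometry)) abort("interp mode needs the grid geometry")
    span_x <- geometry$n_cols * geometry$pitch_um
    span_y <- geometry$n_rows * geometry$pitch_um
    ox <- -geometry$pitch_um / 2; oy <- -geometry$pitch_um / 2
    bx <- pmin(pmax(floor((events$x_um - ox) / (span_x / bins_coarse)), 0),
               bins_coarse - 1)
    by <- pmin(pmax(floor((events$y_um - oy) / (span_y / bins_coarse)), 0),
               bins_coarse - 1)
    gx <- bx %/% 3L; gy <- by %/% 3L
    events$unit <- as.integer(gy * (bins_coarse / 3) + gx + 1L)
    units <- events |>
      group_by(.data$unit) |>
      summarise(x_um = ox + (mean(.data$x_um) * 0 +
                  ((.data$unit[1] - 1L) %% (bins_coarse / 3) + 0.5) * 3 *
                    span_x / bins_coarse),
                y_um = oy + (((.data$unit[1] - 1L) %/% (bins_coarse / 3) + 0.5) *
                  3 * span_y / bins_coarse),
                n_events = dplyr::n(), .groups = "drop")
    mx <- density_maxima(events$x_um - ox, events$y_um - oy, span_x, span_y,
                         bins_fine, kernel_radius_um, max_sep_um)
    mx$x <- mx$x + ox; mx$y <- mx$y + oy
    if (nrow(mx) == 0) {
      units$is_reference <- FALSE
      events$ref_unit <- NA_integer_
    } else {
      # nearest maximum within ref_radius claims the event
      dist2 <- outer(events$x_um, mx$x, "-")^2 + outer(events$y_um, mx$y, "-")^2
      nearest <- max.col(-dist2, ties.method = "first")
      dmin <- sqrt(dist2[cbind(seq_len(nrow(events)), nearest)])
      events$ref_unit <- ifelse(dmin <= ref_radius_um, nearest, NA_integer_)
      units$is_reference <- units$unit %in%
        unique(events$unit[!is.na(events$ref_unit)])
    }
  }
  ref <- events |>
    filter(!is.na(.data$ref_unit)) |>
    group_by(.data$ref_unit) |>
    summarise(x_um = mean(.data$x_um), y_um = mean(.data$y_um),
              n_events = dplyr::n(), .groups = "drop")
  ref <- arrange(ref, desc(.data$n_events))
  nex <- min(n_exclude, max(nrow(ref) - 1, 0))
  ref$excluded <- seq_len(nrow(ref)) <= nex
  drop_ids <- ref$ref_unit[ref$excluded]
  events$ref_unit[events$ref_unit %in% drop_ids] <- NA_integer_
  list(events = events, units = units, ref_units = arrange(ref, .data$ref_unit))
}

# smoothed 2-D histogram maxima: cone kernel, minimum separation
density_maxima <- function(x, y, span_x, span_y, bins, kernel_radius_um,
                           max_sep_um, min_rel = 0) {
  wx <- span_x / bins; wy <- span_y / bins
  ix <- pmin(pmax(floor(x / wx), 0), bins - 1) + 1
  iy <- pmin(pmax(floor(y / wy), 0), bins - 1) + 1
  h <- matrix(0, bins, bins)
  cnt <- table(factor(ix + (iy - 1) * bins, levels = seq_len(bins * bins)))
  h[] <- as.numeric(cnt)
  kr <- ceiling(kernel_radius_um / min(wx, wy))
  kx <- outer(-kr:kr * wx, -kr:kr * wy,
              function(a, b) pmax(1 - sqrt(a^2 + b^2) / kernel_radius_um, 0))
  sm <- conv2d_same(h, kx / sum(kx))
  rad <- ceiling(max_sep_um / min(wx, wy))
  if (min_rel > 0) sm[sm < min_rel * max(sm)] <- 0
  mx <- local_maxima(sm, rad)
  if (nrow(mx) == 0) return(tibble(x = numeric(0), y = numeric(0)))
  pts <- tibble(x = (mx[, 1] - 0.5) * wx, y = (mx[, 2] - 0.5) * wy,
                v = sm[mx])
  pts <- arrange(pts, desc(.data$v))
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    d <- sqrt((pts$x - pts$x[i])^2 + (pts$y - pts$y[i])^2)
    keep[d < max_sep_um & seq_len(nrow(pts)) > i] <- FALSE
  }
  pts[keep, c("x", "y")]
}

conv2d_same <- function(h, k) {
  kr <- (nrow(k) - 1) / 2
  n <- nrow(h); m <- ncol(h)
  hp <- matrix(0, n + 2 * kr, m + 2 * kr)
  hp[kr + seq_len(n), kr + seq_len(m)] <- h
  out <- matrix(0, n, m)
  for (i in seq_len(nrow(k)))
    for (j in seq_len(ncol(k)))
      if (k[i, j] != 0)
        out <- out + k[i, j] *
          hp[(i - 1) + seq_len(n), (j - 1) + seq_len(m)]
  out
}

local_maxima <- function(m, rad) {
  n <- nrow(m); p <- ncol(m)
  res <- NULL
  cand <- which(m > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    nb <- m[max(1, i - rad):min(n, i + rad),
            max(1, j - rad):min(p, j + rad)]
    if (m[i, j] >= max(nb)) res <- rbind(res, c(i, j))
  }
  res %||% matrix(numeric(0), 0, 2)
}

#' Rank events on a population-rank time axis
#'
#' All real events plus a clock unit (one reference event every
#' `clock_every_frames` frames, bounding the real-time extent of rank
#' windows) are ordered by time; Poisson surrogate events — uniform in
#' population rank, preserving relative rate changes — are inserted at
#' `surrogate_rate_hz` per non-reference unit. The resulting global rank
#' replaces time for all subsequent coincidence analysis.
#'
#' @param sel Result of [select_reference_units()] (or a compatible list).
#' @param duration_s Recording duration.
#' @param sampling_rate_hz Sampling rate defining the clock interval.
#' @param clock_every_frames Clock period in frames (default 4).
#' @param surrogate_rate_hz Surrogate rate per eligible unit (default 0.1).
#' @param seed RNG seed.
#' @return A tibble of ranked events: `unit`, `ref_unit`, `rank`, `time_s`,
#'   `amplitude`, `is_real`, `is_clock` (plus any extra event columns).
#' @export
rank_events <- function(sel, duration_s, sampling_rate_hz,
                        clock_every_frames = 4, surrogate_rate_hz = 0.1,
                        seed = 1) {
  ev <- sel$events
  base <- tibble(unit = ev$unit, ref_unit = ev$ref_unit,
                 time_s = ev$time_s, amplitude = ev$amplitude,
                 is_real = TRUE, is_clock = FALSE)
  if ("is_noise" %in% names(ev)) base$is_noise <- ev$is_noise
  clock_t <- seq(0, duration_s, by = clock_every_frames / sampling_rate_hz)
  clock <- tibble(unit = NA_integer_, ref_unit = 0L, time_s = clock_t,
                  amplitude = NA_real_, is_real = FALSE, is_clock = TRUE)
  if ("is_noise" %in% names(base)) clock$is_noise <- NA
  timed <- bind_rows(base, clock)
  timed <- timed[order(timed$time_s), ]
  timed$key <- seq_len(nrow(timed))
  set.seed(seed)
  ref_ids <- sel$units$unit[sel$units$is_reference]
  elig <- setdiff(sel$units$unit, ref_ids)
  n_s <- rpois(length(elig), surrogate_rate_hz * duration_s)
  surr <- tibble(unit = rep(elig, n_s), ref_unit = NA_integer_,
                 time_s = NA_real_, amplitude = NA_real_,
                 is_real = FALSE, is_clock = FALSE,
                 key = runif(sum(n_s), 0.5, nrow(timed) + 0.5))
  if ("is_noise" %in% names(timed)) surr$is_noise <- NA
  allv <- bind_rows(timed, surr)
  allv <- allv[order(allv$key), ]
  allv$rank <- seq_len(nrow(allv))
  select(allv, -"key")
}

#' Pairwise coincidence links between units and reference units
#'
#' For every (unit, reference) pair further apart than `d_min_um`, the
#' number of event pairs closer than `tau_corr/2` in rank is compared to the
#' Poisson expectation `tau_corr * n_i * n_j / sum(n_k)`. Pairs with
#' significantly fewer coincidences than chance (one-sided Poisson
#' p < `p_deficit`) are removed from the statistics (channels following an
#' entirely different activity pattern should not make others look
#' correlated); pairs with a significant excess (one-sided p < `p_excess`)
#' are linked: `A[i, j] = 1`.
#'
#' @param ranked Tibble from [rank_events()].
#' @param sel The [select_reference_units()] result (for unit positions).
#' @param tau_corr Rank window (events), default 100.
#' @param d_min_um Minimum unit-reference distance (default 42).
#' @param p_deficit,p_excess One-sided Poisson significance levels.
#' @return Object of class `mea_links`: list with `pairs` (tibble),
#'   `A` (units x references 0/1 matrix), `tau_corr`.
#' @export
build_links <- function(ranked, sel, tau_corr = 100, d_min_um = 42,
                        p_deficit = 1e-6, p_excess = 0.1) {
  w <- tau_corr / 2
  total <- nrow(ranked)
  if (total == 0) abort("no events to link")
  counts <- ranked |> filter(!is.na(.data$unit)) |>
    group_by(.data$unit) |> summarise(n = dplyr::n(), .groups = "drop")
  units <- sel$units
  refs <- sel$ref_units |> filter(!.data$excluded)
  ref_ids <- c(0L, refs$ref_unit)  # 0 = clock
  ref_ranks <- lapply(ref_ids, function(j) {
    if (j == 0L) sort(ranked$rank[ranked$is_clock])
    else sort(ranked$rank[!is.na(ranked$ref_unit) & ranked$ref_unit == j &
                          ranked$is_real])
  })
  ref_n <- lengths(ref_ranks)
  unit_ranks <- split(ranked$rank[!is.na(ranked$unit)],
                      ranked$unit[!is.na(ranked$unit)])
  rows <- list(); r <- 0
  for (ui in seq_len(nrow(units))) {
    u <- units$unit[ui]
    ri <- unit_ranks[[as.character(u)]]
    if (is.null(ri)) next
    for (jj in seq_along(ref_ids)) {
      j <- ref_ids[jj]
      if (j == 0L) { dist <- Inf } else {
        rj <- refs[refs$ref_unit == j, ]
        dist <- sqrt((units$x_um[ui] - rj$x_um)^2 +
                     (units$y_um[ui] - rj$y_um)^2)
      }
      if (dist <= d_min_um) next
      Rj <- ref_ranks[[jj]]
      if (length(Rj) == 0) next
      cnt <- sum(findInterval(ri + w, Rj) - findInterval(ri - w - 1e-9, Rj))
      if (j != 0L) {
        shared <- ranked$is_real & !is.na(ranked$unit) & ranked$unit == u &
          !is.na(ranked$ref_unit) & ranked$ref_unit == j
        cnt <- cnt - sum(shared)
      }
      expd <- tau_corr * length(ri) * length(Rj) / total
      r <- r + 1
      rows[[r]] <- tibble(unit = u, ref_unit = j, observed = cnt,
                          expected = expd)
    }
  }
  pairs <- bind_rows(rows)
  if (nrow(pairs) == 0)
    return(structure(list(pairs = pairs,
                          A = matrix(0, 0, 0), tau_corr = tau_corr),
                     class = "mea_links"))
  pairs$p_deficit <- ppois(pairs$observed, pairs$expected)
  pairs$p_excess <- ppois(pairs$observed - 1, pairs$expected,
                          lower.tail = FALSE)
  pairs$removed <- pairs$p_deficit < p_deficit
  pairs$linked <- !pairs$removed & pairs$p_excess < p_excess
  A <- matrix(0L, nrow(units), length(ref_ids),
              dimnames = list(units$unit, ref_ids))
  A[cbind(match(pairs$unit, units$unit), match(pairs$ref_unit, ref_ids))] <-
    as.integer(pairs$linked)
  structure(list(pairs = pairs, A = A, tau_corr = tau_corr,
                 ref_ids = ref_ids), class = "mea_links")
}

#' Per-event correlation index
#'
#' For every (real or surrogate) event, the reference events within
#' `tau_corr/2` ranks are collected; the correlation index is the fraction
#' of them coming from units linked to the event's unit, multiplied by the
#' fraction of mutually linked pairs among those linked units (1 if at most
#' one such unit is present). Events with no coactive reference events get
#' index 0.
#'
#' @param ranked Tibble from [rank_events()].
#' @param links [build_links()] result.
#' @return `ranked` with a `ci` column (NA for clock events).
#' @export
correlation_index <- function(ranked, links) {
  w <- links$tau_corr / 2
  ref_ids <- links$ref_ids
  ranked$ci <- NA_real_
  rows <- which(!ranked$is_clock)
  if (length(rows) == 0 || length(ref_ids) == 0) return(ranked)
  rk <- ranked$rank[rows]
  M <- length(ref_ids)
  N <- matrix(0, length(rows), M)
  for (jj in seq_len(M)) {
    j <- ref_ids[jj]
    Rj <- if (j == 0L) sort(ranked$rank[ranked$is_clock]) else
      sort(ranked$rank[!is.na(ranked$ref_unit) & ranked$ref_unit == j &
                       ranked$is_real])
    if (length(Rj) == 0) next
    N[, jj] <- findInterval(rk + w, Rj) - findInterval(rk - w - 1e-9, Rj)
  }
  # an event inside a reference unit coincides with itself: remove
  own <- match(ranked$ref_unit[rows], ref_ids)
  self_rows <- which(!is.na(own) & ranked$is_real[rows])
  N[cbind(self_rows, own[self_rows])] <- N[cbind(self_rows, own[self_rows])] - 1
  tot <- rowSums(N)
  ci <- numeric(length(rows))
  Arr <- links$A  # units x refs
  unit_of <- ranked$unit[rows]
  # reference units are units too: rows of A indexed by unit id
  ref_row <- match(ref_ids, rownames(Arr))
  Aref <- matrix(0L, M, M)
  okr <- !is.na(ref_row)
  Aref[okr, ] <- Arr[ref_row[okr], , drop = FALSE]
  Aref <- pmax(Aref, t(Aref))  # a pair counts as linked in either direction
  diag(Aref) <- 0L
  for (u in unique(unit_of[!is.na(unit_of)])) {
    ur <- which(!is.na(unit_of) & unit_of == u)
    arow <- Arr[match(as.character(u), rownames(Arr)), ]
    linked <- which(arow == 1L)
    if (length(linked) == 0 || length(ur) == 0) { ci[ur] <- 0; next }
    Nu <- N[ur, , drop = FALSE]
    f1 <- rowSums(Nu[, linked, drop = FALSE]) / pmax(tot[ur], 1)
    B <- (Nu[, linked, drop = FALSE] > 0) + 0
    k <- rowSums(B)
    As <- Aref[linked, linked, drop = FALSE]
    pl <- rowSums((B %*% As) * B) / 2
    npair <- k * (k - 1) / 2
    f2 <- ifelse(k >= 2, pl / npair, 1)
    ci[ur] <- ifelse(tot[ur] == 0, 0, f1 * f2)
  }
  ci[is.na(unit_of)] <- 0
  ranked$ci[rows] <- ci
  ranked
}

# combined rank statistic of amplitude ranks and surrogate-referenced CI
# ranks; under independence it follows the cumulative uniform distribution
unit_xstat <- function(ci, amp, surr_sorted) {
  N <- length(ci)
  ns <- length(surr_sorted)
  FP <- findInterval(ci, surr_sorted) / ns
  ord_ci <- order(ci)
  rA <- rank(amp, ties.method = "average") / N
  t1 <- cumsum(rA[ord_ci]); t1 <- 0.5 * t1 / t1[N]
  ord_amp <- order(amp)
  s2 <- cumsum(FP[ord_amp])
  t2 <- if (s2[N] > 0) 0.5 * s2 / s2[N] else 0.5 * seq_len(N) / N
  list(X = t1 + t2, ord_ci = ord_ci)
}

#' Classify units into correlated and uncorrelated event fractions
#'
#' Per unit, the distribution of a combined statistic of amplitude ranks and
#' correlation indices (referred to the unit's surrogate-event CI
#' distribution) is tested against uniformity with a one-sided
#' Kolmogorov-Smirnov test. If the deficit is significant (p < `alpha`),
#' the boundary between uncorrelated (low CI) and correlated events is
#' placed at the maximum of the Brownian-bridge-normalized deviation. If
#' not, a conservative per-event estimator is averaged: the excess of the
#' surrogate CI cdf over the unit's own CI cdf, renormalized and clipped to
#' [0, 1] (zero when both distributions agree, one when they do not
#' overlap). Units without surrogate events (reference units) are flagged
#' and left unclassified.
#'
#' @param indexed Tibble from [correlation_index()].
#' @param alpha KS significance level (default 0.01).
#' @return Object of class `mea_classification`: list with `units` (per-unit
#'   summary), `events` (real events with per-event uncorrelated
#'   probability, see [per_event_probability()]).
#' @export
classify_units <- function(indexed, alpha = 0.01) {
  real <- indexed |> filter(.data$is_real)
  surr <- indexed |> filter(!.data$is_real, !.data$is_clock)
  out <- list(); evout <- list()
  for (u in sort(unique(real$unit))) {
    re <- real[real$unit == u, ]
    su <- sort(surr$ci[surr$unit == u])
    N <- nrow(re)
    if (length(su) == 0 || N < 2) {
      out[[length(out) + 1]] <- tibble(
        unit = u, n = N, n_surr = length(su), ks_stat = NA_real_,
        ks_p = NA_real_, method = "flagged", boundary = NA_integer_,
        fraction_uncorrelated = NA_real_)
      re$p_uncorrelated <- NA_real_
      evout[[length(evout) + 1]] <- re
      next
    }
    xs <- unit_xstat(re$ci, re$amplitude, su)
    k <- seq_len(N)
    dev <- k / N - xs$X
    D <- max(dev)
    ks_p <- exp(-2 * N * max(D, 0)^2)
    if (D > 0 && ks_p < alpha) {
      kk <- seq_len(N - 1)
      wstat <- dev[kk] * N / (2 * sqrt(kk * (N - kk) / N))
      P <- which.max(wstat)
      frac_unc <- P / N
      method <- "boundary"
    } else {
      q <- findInterval(re$ci, su, left.open = TRUE) / length(su)
      uu <- (rank(re$ci, ties.method = "min") - 1) / N
      ce <- pmin(pmax((q - uu) / (1 - uu), 0), 1)
      frac_unc <- 1 - mean(ce)
      P <- round(frac_unc * N)
      method <- "conservative"
    }
    p <- sliding_window_probability(re$ci, su, P)
    re$p_uncorrelated <- p
    evout[[length(evout) + 1]] <- re
    out[[length(out) + 1]] <- tibble(
      unit = u, n = N, n_surr = length(su), ks_stat = D, ks_p = ks_p,
      method = method, boundary = as.integer(P),
      fraction_uncorrelated = frac_unc)
  }
  structure(list(units = bind_rows(out), events = bind_rows(evout)),
            class = "mea_classification")
}

#' Per-event probability of being uncorrelated
#'
#' Real and surrogate events of one unit are merged and sorted by
#' correlation index; around each real event the local fraction of
#' surrogates is computed in a sliding window of half-width `L` with
#' reflective boundaries. `L` is the smallest value for which no event's
#' renormalized fraction exceeds 1.1; the fractions are then scaled so they
#' sum to the unit's estimated uncorrelated count `P` and clipped to [0, 1].
#'
#' @param ci Correlation indices of the unit's real events.
#' @param surr_ci Correlation indices of its surrogate events.
#' @param P Estimated number of uncorrelated events.
#' @return Probabilities in the order of `ci`.
#' @export
sliding_window_probability <- function(ci, surr_ci, P) {
  N <- length(ci)
  merged <- c(ci, surr_ci)
  is_surr <- rep(c(FALSE, TRUE), c(N, length(surr_ci)))
  if (length(unique(merged)) <= 1) return(rep(P / N, N))
  o <- order(merged)
  xs <- as.numeric(is_surr[o])
  M <- length(xs)
  qpos <- which(!is_surr[o])          # positions of real events, CI-sorted
  for (L in seq_len(M)) {
    f <- reflect_window_mean(xs, qpos, L) * (2 * L + 1) / (2 * L)
    sf <- sum(f)
    if (sf == 0) { p_sorted <- rep(0, N); break }
    p <- f * P / sf
    if (max(p) <= 1.1 || L == M) { p_sorted <- pmin(pmax(p, 0), 1); break }
  }
  # map back from CI-sorted real events to input order
  p_out <- numeric(N)
  p_out[order(ci)] <- p_sorted
  p_out
}

reflect_window_mean <- function(xs, centers, L) {
  M <- length(xs)
  idx <- outer(centers, (-L):L, "+")
  idx <- abs(idx - 1) %% (2 * (M - 1))
  idx <- ifelse(idx >= M - 1, 2 * (M - 1) - idx, idx) + 1
  matx <- matrix(xs[idx], nrow = length(centers))
  rowMeans(matx)
}

#' Full correlation-classification pipeline
#'
#' Convenience driver: reference selection, ranking with surrogates and
#' clock, link building, correlation indices, unit classification and
#' per-event probabilities.
#'
#' @inheritParams select_reference_units
#' @inheritParams rank_events
#' @inheritParams build_links
#' @param alpha KS significance level.
#' @return An `mea_classification` with additional elements `links`,
#'   `ranked`, `sel`.
#' @export
classify_events <- function(events, duration_s, sampling_rate_hz,
                            geometry = NULL, mode = "online",
                            tau_corr = 100, clock_every_frames = 4,
                            surrogate_rate_hz = 0.1, d_min_um = 42,
                            n_exclude = 10, seed = 1, alpha = 0.01) {
  sel <- select_reference_units(events, geometry, mode,
                                n_exclude = n_exclude)
  ranked <- rank_events(sel, duration_s, sampling_rate_hz,
                        clock_every_frames, surrogate_rate_hz, seed)
  links <- build_links(ranked, sel, tau_corr, d_min_um)
  indexed <- correlation_index(ranked, links)
  cls <- classify_units(indexed, alpha)
  cls$links <- links
  cls$ranked <- indexed
  cls$sel <- sel
  cls
}
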