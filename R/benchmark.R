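#' Match detections to inserted ground-truth events
#'
#' Greedy one-to-one assignment: a detection can claim a truth if they are
#' within `max_dt_frames` frames and within a radius of half the electrode
#' diagonal (`sqrt(2)/2 * d_pitch`). Candidate pairs are assigned in order of
#' increasing temporal distance, so when several detections fall in range the
#' temporally closer one is used. Unmatched detections are false positives,
#' unmatched truths false negatives.
#'
#' @param detections Event tibble with `frame`, `x_um`, `y_um`, `amplitude`.
#' @param truths Tibble with `frame`, `x_um`, `y_um` (one row per insertion).
#' @param d_pitch Electrode pitch (micrometres).
#' @param max_dt_frames Temporal matching window (default 3 frames).
#' @param radius_um Matching radius; default `sqrt(2)/2 * d_pitch`.
#' @return A list with `pairs` (tibble: `truth`, `detection`, `dt_frames`,
#'   `dist_um`), `false_positives` and `false_negatives` (row indices).
#' @export
match_events <- function(detections, truths, d_pitch,
                         max_dt_frames = 3,
                         radius_um = sqrt(2) / 2 * d_pitch) {
  nd <- nrow(detections); nt <- nrow(truths)
  if (nd == 0 || nt == 0)
    return(list(pairs = tibble(truth = integer(0), detection = integer(0),
                               dt_frames = numeric(0), dist_um = numeric(0)),
                false_positives = seq_len(nd), false_negatives = seq_len(nt)))
  ord <- order(detections$frame)
  df <- detections$frame[ord]
  lo <- findInterval(truths$frame - max_dt_frames - 0.5, df) + 1L
  hi <- findInterval(truths$frame + max_dt_frames + 0.5, df)
  sizes <- pmax(hi - lo + 1L, 0L)
  ti <- rep.int(seq_len(nt), sizes)
  di <- ord[sequence(sizes, from = lo)]
  dist <- sqrt((detections$x_um[di] - truths$x_um[ti])^2 +
               (detections$y_um[di] - truths$y_um[ti])^2)
  ok <- dist <= radius_um
  ti <- ti[ok]; di <- di[ok]; dist <- dist[ok]
  dt <- abs(detections$frame[di] - truths$frame[ti])
  o <- order(dt, -detections$amplitude[di], di)
  t_used <- logical(nt); d_used <- logical(nd)
  keep <- logical(length(o))
  for (k in o) {
    if (!t_used[ti[k]] && !d_used[di[k]]) {
      t_used[ti[k]] <- TRUE; d_used[di[k]] <- TRUE; keep[k] <- TRUE
    }
  }
  list(pairs = tibble(truth = ti[keep], detection = di[keep],
                      dt_frames = dt[keep], dist_um = dist[keep]),
       false_positives = which(!d_used),
       false_negatives = which(!t_used))
}

#' Per-patch ROC curves by amplitude-threshold sweep
#'
#' The detector runs once at a permissive base threshold with amplitudes
#' retained; sweeping an amplitude cut then trades false-positive rate
#' against true-positive fraction. Rates are per channel (false positives in
#' the 3x3 patch area divided by duration and the nine electrodes), so they
#' are comparable across detectors and patch sizes.
#'
#' @param detections,truths As in [match_events()]; `truths` must carry a
#'   `patch`, `center_row`, `center_col` column set ([insertion_plan()]).
#' @param matches Result of [match_events()] on these tables.
#' @param duration_s Recording duration (denominator of the rate).
#' @param geometry An [mea_geometry()].
#' @return Object of class `mea_roc`: list with `curves` (tibble: `patch`,
#'   `fp_hz`, `tp`) and `pauc` (per-patch partial AUC, see [partial_auc()]).
#' @export
roc_curves <- function(detections, truths, matches, duration_s, geometry,
                       max_fp_hz = 0.1) {
  pitch <- geometry$pitch_um
  tp_amp <- rep(NA_real_, nrow(truths))
  tp_amp[matches$pairs$truth] <- detections$amplitude[matches$pairs$detection]
  fp <- detections[matches$false_positives, ]
  patches <- unique(truths[c("patch", "center_row", "center_col")])
  curves <- vector("list", nrow(patches))
  paucs <- numeric(nrow(patches))
  for (i in seq_len(nrow(patches))) {
    pt <- patches[i, ]
    cx <- (pt$center_col - 1) * pitch; cy <- (pt$center_row - 1) * pitch
    in_patch <- abs(fp$x_um - cx) <= 1.5 * pitch &
                abs(fp$y_um - cy) <= 1.5 * pitch
    fpa <- sort(fp$amplitude[in_patch], decreasing = TRUE)
    ta <- tp_amp[truths$patch == pt$patch]
    nt <- length(ta)
    # at a false-positive count of k the threshold sits just above the
    # (k+1)-th false-positive amplitude, so all strictly larger true
    # positives are kept; the final point admits every detection
    fp_hz <- c(0, seq_along(fpa)) / (duration_s * 9)
    tp <- c(vapply(seq_along(fpa), function(k)
      sum(!is.na(ta) & ta > fpa[k]) / nt, numeric(1)),
      sum(!is.na(ta)) / nt)
    cur <- tibble(patch = pt$patch, fp_hz = fp_hz, tp = tp)
    curves[[i]] <- cur
    paucs[i] <- partial_auc(cur, max_fp_hz)
  }
  structure(list(curves = bind_rows(curves),
                 pauc = tibble(patch = patches$patch, pauc = paucs),
                 max_fp_hz = max_fp_hz, duration_s = duration_s),
            class = "mea_roc")
}

#' Partial area under an ROC curve
#'
#' Trapezoidal area under the true-positive fraction as a function of
#' false-positive rate, restricted to rates up to `max_fp_hz` and normalized
#' by `max_fp_hz`, so a perfect detector scores 1 and a silent one 0. Curves
#' ending below `max_fp_hz` are extended horizontally at their final
#' true-positive fraction.
#'
#' @param curve Tibble with `fp_hz` and `tp`, ordered by `fp_hz`.
#' @param max_fp_hz Upper false-positive rate bound (default 0.1 Hz).
#' @return A number in [0, 1].
#' @export
partial_auc <- function(curve, max_fp_hz = 0.1) {
  x <- curve$fp_hz; y <- curve$tp
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  if (max(x) < max_fp_hz) { x <- c(x, max_fp_hz); y <- c(y, y[length(y)]) }
  keep <- x <= max_fp_hz
  if (max(x[keep]) < max_fp_hz) {
    yend <- approx(x, y, xout = max_fp_hz, ties = "ordered")$y
    x <- c(x[keep], max_fp_hz); y <- c(y[keep], yend)
  } else { x <- x[keep]; y <- y[keep] }
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) / max_fp_hz
}

#' Design a digital Bessel band-pass filter
#'
#' Third-order analog Bessel low-pass prototype (maximally flat group
#' delay), frequency-normalized to its -3 dB point, transformed to a
#' band-pass and discretized with the bilinear transform.
#'
#' @param sampling_rate_hz Sampling rate.
#' @param low_hz,high_hz Band edges (defaults 100 and 2000 Hz).
#' @return List with transfer-function coefficients `b`, `a`.
#' @export
bessel_bandpass <- function(sampling_rate_hz, low_hz = 100, high_hz = 2000) {
  # reverse Bessel polynomial s^3 + 6 s^2 + 15 s + 15
  p <- polyroot(c(15, 15, 6, 1))
  mag2 <- function(w) Mod(15 / ((1i * w)^3 + 6 * (1i * w)^2 + 15i * w + 15))^2
  w3 <- stats::uniroot(function(w) mag2(w) - 0.5, c(0.5, 5), tol = 1e-12)$root
  sp <- p / w3
  sg <- 15 / w3^3
  T <- 2
  W <- 2 / T * tan(pi * c(low_hz, high_hz) / sampling_rate_hz)
  bp <- signal::sftrans(Sz = numeric(0), Sp = sp, Sg = sg, W = W, stop = FALSE)
  dz <- signal::bilinear(Sz = bp$zero, Sp = bp$pole, Sg = bp$gain, T = T)
  ba <- signal::as.Arma(signal::Zpg(zero = dz$zero, pole = dz$pole,
                                    gain = dz$gain))
  list(b = Re(ba$b), a = Re(ba$a))
}

#' Conventional band-pass threshold detection
#'
#' The comparison baseline: each channel is band-pass filtered (0.1-2 kHz,
#' 3-pole Bessel) and local minima below `-threshold` times the channel's
#' noise standard deviation are reported. The SD is estimated robustly
#' (median absolute deviation) from the filtered signal over `sd_window_s`
#' seconds at the start of the recording, which the benchmark keeps free of
#' insertions. A same-channel refractory keeps the largest event within 1 ms.
#'
#' @inheritParams detect_events_online
#' @param threshold Detection threshold in noise-SD units.
#' @param band_hz Band edges in Hz.
#' @param sd_window_s Seconds of data used for the noise-SD estimate.
#' @param noise_sd Optional per-channel SD vector (overrides estimation).
#' @return An event tibble; amplitudes are in SD units.
#' @export
detect_events_threshold <- function(rec, threshold = 6, band_hz = c(100, 2000),
                                    sd_window_s = 0.9, noise_sd = NULL,
                                    chunk_frames = NULL, refractory_ms = 1,
                                    burn_in_s = 0.5) {
  geom <- rec$geometry
  fs <- rec$sampling_rate_hz
  ba <- bessel_bandpass(fs, band_hz[1], band_hz[2])
  if (is.null(noise_sd)) {
    nwin <- min(round(sd_window_s * fs), rec$n_frames)
    x0 <- read_frames(rec, 1, nwin)
    xf <- apply(x0, 2, function(col) signal::filter(ba$b, ba$a, col))
    xf <- xf[-seq_len(min(200, nwin - 1)), , drop = FALSE]  # filter transient
    med <- col_medians_cpp(xf)
    noise_sd <- 1.4826 * col_medians_cpp(abs(t(t(xf) - med)))
    noise_sd <- pmax(noise_sd, 1e-6)
  }
  det <- thresh_new(n_channels(geom), ba$b, ba$a, noise_sd, threshold,
                    as.integer(round(burn_in_s * fs)))
  plan <- chunk_plan(rec, chunk_frames)
  for (i in seq_len(nrow(plan)))
    thresh_feed(det, read_frames(rec, plan$start[i], plan$n[i]))
  ev <- as_tibble(thresh_take(det))
  if (nrow(ev) == 0) return(empty_events())
  pos <- channel_position(geom, as.integer(ev$channel))
  ev <- tibble(frame = as.integer(ev$frame),
               time_s = (as.integer(ev$frame) - 1) / fs,
               channel = as.integer(ev$channel),
               x_um = pos$x_um, y_um = pos$y_um,
               amplitude = ev$amplitude, repolarizing = NA)
  refractory_filter(ev, refractory_ms, fs)
}

#' Localization error and bias per amplitude band
#'
#' For matched detection/truth pairs, the per-event displacement is the
#' detected minus the inserted location. Within each group (amplitude band,
#' optionally per patch) the localization error is the median displacement
#' length and the bias the length of the median displacement vector; groups
#' with fewer than 3 pairs are flagged unreliable (`NA`).
#'
#' @param detections,truths,matches As in [roc_curves()].
#' @param bands Numeric vector of band edges over `amplitude_uv` (passed to
#'   `cut`), or NULL to group by exact inserted amplitude.
#' @param by_patch Also split by patch.
#' @return A tibble with `band`, `n`, `error_um`, `bias_um`, `jitter_um`
#'   (median absolute deviation of displacements around their median).
#' @export
localization_metrics <- function(detections, truths, matches, bands = NULL,
                                 by_patch = FALSE) {
  pr <- matches$pairs
  d <- tibble(
    patch = if ("patch" %in% names(truths)) truths$patch[pr$truth] else 1L,
    amplitude_uv = truths$amplitude_uv[pr$truth],
    dx = detections$x_um[pr$detection] - truths$x_um[pr$truth],
    dy = detections$y_um[pr$detection] - truths$y_um[pr$truth])
  d$band <- if (is.null(bands)) factor(d$amplitude_uv) else
    cut(d$amplitude_uv, bands, include.lowest = TRUE)
  grp <- if (by_patch) c("band", "patch") else "band"
  d |>
    group_by(across(all_of(grp))) |>
    summarise(n = dplyr::n(),
              error_um = if (dplyr::n() >= 3)
                median(sqrt(.data$dx^2 + .data$dy^2)) else NA_real_,
              bias_um = if (dplyr::n() >= 3)
                sqrt(median(.data$dx)^2 + median(.data$dy)^2) else NA_real_,
              jitter_um = if (dplyr::n() >= 3)
                median(abs(sqrt((.data$dx - median(.data$dx))^2 +
                                (.data$dy - median(.data$dy))^2))) else
                  NA_real_,
              .groups = "drop")
}

#' Bootstrap comparison of per-patch partial AUCs
#'
#' Resamples patches with replacement and recomputes the mean partial AUC of
#' each detector, giving bootstrap summaries of the pairwise margins.
#'
#' @param pauc_list Named list of per-patch pAUC tibbles (from `mea_roc$pauc`),
#'   one per detector, sharing the patch set.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed RNG seed.
#' @return A list with `mean` (named vector), `boot` (matrix of resampled
#'   means, n_boot x detectors).
#' @export
bootstrap_pauc <- function(pauc_list, n_boot = 100, seed = 1) {
  wide <- purrr::reduce(
    purrr::imap(pauc_list, function(x, nm) {
      names(x)[names(x) == "pauc"] <- nm; x
    }),
    function(a, b) left_join(a, b, by = "patch"))
  m <- as.matrix(wide[, -1, drop = FALSE])
  set.seed(seed)
  boot <- t(vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(m), replace = TRUE)
    colMeans(m[idx, , drop = FALSE])
  }, numeric(ncol(m))))
  colnames(boot) <- colnames(m)
  list(mean = colMeans(m), boot = boot)
}

#' Ground-truthed detector benchmark
#'
#' Runs the full synthetic benchmark: a noise recording with spike templates
#' inserted into 3x3-electrode patches ([insertion_plan()]), all three
#' detectors at permissive base thresholds (amplitude sweeps then trade
#' false-positive rate against sensitivity), matching, per-patch ROC curves
#' and localization metrics for the interpolating detector.
#'
#' @param geometry An [mea_geometry()].
#' @param amplitudes_uv Inserted source amplitudes.
#' @param duration_s Recording duration; must cover the insertion schedule.
#' @param sampling_rate_hz Sampling rate (default 7563).
#' @param rms_uv Noise level (default 26).
#' @param seed RNG seed.
#' @param detectors Subset of `c("interp", "online", "threshold")`.
#' @param base_thresholds Permissive detection thresholds used before the
#'   ROC amplitude sweep.
#' @param path Recording file path (default: temporary file, deleted).
#' @param keep_recording Keep the file on disk.
#' @param verbose Emit per-stage progress messages.
#' @return A list with `truth`, per-detector `events`, `matches`, `roc`
#'   (`mea_roc`), and `metrics` (localization metrics of the interpolating
#'   detector, per amplitude).
#' @export
run_detection_benchmark <- function(geometry, amplitudes_uv, duration_s,
                                    sampling_rate_hz = 7563, rms_uv = 26,
                                    seed = 1,
                                    detectors = c("interp", "online",
                                                  "threshold"),
                                    base_thresholds = c(interp = 2.5,
                                                        online = 4.5,
                                                        threshold = 3.5),
                                    path = tempfile(fileext = ".bin"),
                                    keep_recording = FALSE, verbose = TRUE) {
  fs <- sampling_rate_hz
  plan <- insertion_plan(geometry, amplitudes_uv,
                         start_frame = round(1.2 * fs), seed = seed)
  need_s <- (max(plan$frame) + 0.1 * fs) / fs
  if (duration_s < need_s)
    abort(sprintf("duration %.1f s does not cover the %.1f s insertion schedule",
                  duration_s, need_s))
  t0 <- Sys.time()
  stamp <- function(fmt, ...) if (verbose)
    message(sprintf("[%6.1f s] ", as.numeric(Sys.time() - t0, units = "secs")),
            sprintf(fmt, ...))
  rec <- simulate_recording(path, geometry, duration_s, fs, rms_uv = rms_uv,
                            seed = seed, plan = plan)
  stamp("simulated %d insertions over %.0f s", nrow(plan), duration_s)
  if (!keep_recording) on.exit(unlink(c(path, paste0(path, ".json"))))
  out <- list(truth = plan, events = list(), matches = list(), roc = list())
  for (d in detectors) {
    ev <- switch(d,
      interp = detect_events_interp(
        rec, interp_params(fs, threshold = base_thresholds[["interp"]])),
      online = detect_events_online(
        rec, online_params(fs, threshold = base_thresholds[["online"]])),
      threshold = detect_events_threshold(
        rec, threshold = base_thresholds[["threshold"]]))
    stamp("%s: %d events", d, nrow(ev))
    m <- match_events(ev, plan, geometry$pitch_um)
    out$events[[d]] <- ev
    out$matches[[d]] <- m
    out$roc[[d]] <- roc_curves(ev, plan, m, duration_s, geometry)
    stamp("%s: %d matched, %d false positives", d, nrow(m$pairs),
          length(m$false_positives))
  }
  if ("interp" %in% detectors)
    out$metrics <- localization_metrics(out$events$interp, plan,
                                        out$matches$interp)
  out
}
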