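#' Event localization from raw cut-outs
#'
#' For every detected event a short raw-data cut-out spanning
#' `[t0 - tau_pre, t0 + tau_post]` on 9 channels (3x3 block around a
#' real-grid detection) or 12 channels (3x4 block with the 2x2 core centred,
#' for virtual-grid detections) is reduced to per-channel peak amplitudes,
#' cleaned of boundary and outlier effects, and summarized by an iteratively
#' re-weighted barycentre: the continuous current-source location estimate.
#' The location deliberately trades a bias towards electrode centres for a
#' reduced spread of estimates from the same source.
#'
#' A cut-out is a list with elements `snip` (channels x frames matrix of
#' median-subtracted raw voltages, microvolts), `g` (global median trace, one
#' frame longer at the front), `b` (online baseline at detection time, uV),
#' `vbar`, `hbar` (recording-averaged variability and global-coupling
#' coefficient per channel), `chan` (channel ids, 0 = missing), `det`
#' (logical: channels used in the detection), `center_slot` (index of the
#' detection electrode, NA on the virtual grid), `coords` (channels x 2
#' matrix, micrometres), `detect_x`, `detect_y`, `tau_pre`, `tau_post`,
#' `d_pitch`.
#'
#' @name localization
NULL

#' Per-channel peak amplitudes of a cut-out
#'
#' Each snippet is normalized (global median increment scaled by the stored
#' coupling coefficient subtracted, divided by the time-averaged
#' variability), a per-channel baseline is taken as the median of a composite
#' array of the stored online baseline, the earliest pre-peak frames and the
#' post-peak tail, and the amplitude is the maximum of baseline minus the
#' 4-tap smoothed signal (kernel 1/6, 1/3, 1/3, 1/6) within two frames of
#' the detection peak. Missing channels give `NA`.
#'
#' @param cutout A cut-out list (see [localization]).
#' @return Numeric vector of amplitudes in units of `v` (>= 0 not enforced).
#' @export
channel_amplitudes <- function(cutout) {
  S <- nrow(cutout$snip); T <- ncol(cutout$snip)
  tau_pre <- cutout$tau_pre; i0 <- tau_pre + 1L
  dg <- diff(cutout$g)
  A <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    if (cutout$chan[s] == 0) next
    xt <- (cutout$snip[s, ] - cutout$hbar[s] * dg) / cutout$vbar[s]
    z <- c(rep(cutout$b[s] / cutout$vbar[s], floor(tau_pre / 2)),
           xt[seq_len(floor((tau_pre + 1) / 2))],
           xt[(2L * tau_pre + 1L):T])
    base <- median(z)
    sm <- vapply((i0 - 2):(i0 + 2), function(t)
      (xt[t - 1] + 2 * xt[t] + 2 * xt[t + 1] + xt[t + 2]) / 6, numeric(1))
    A[s] <- max(base - sm)
  }
  A
}

slot_adjacency <- function(coords, d_pitch) {
  d <- as.matrix(stats::dist(coords))
  adj <- d > 1e-9 & d <= 1.5 * d_pitch
  diag(adj) <- FALSE
  adj
}

#' Boundary and outlier repair of channel amplitudes
#'
#' Missing channels (chip boundary, saturated amplifiers) receive a surrogate
#' amplitude: the number of available adjacent channels times 1/8 of the
#' median of their amplitudes. Amplitudes are then floored at zero and the
#' 20th percentile is subtracted. Off-centre amplitudes exceeding the sum of
#' their adjacent amplitudes (detection channels) or 2/3 of it (others) are
#' clipped to 1/2 resp. 1/3 of the amplitude sum over the full one-pitch
#' neighbourhood.
#'
#' @param A Amplitudes from [channel_amplitudes()] (NA = missing).
#' @param avail Logical availability mask.
#' @param det Logical detection-channel mask.
#' @param coords Channel coordinates (channels x 2, micrometres).
#' @param d_pitch Electrode pitch (micrometres).
#' @param center_slot Index of the centre (detection) electrode or NA.
#' @return Adjusted amplitude vector.
#' @export
repair_boundary_outliers <- function(A, avail, det, coords, d_pitch,
                                     center_slot = NA) {
  adj <- slot_adjacency(coords, d_pitch)
  for (s in which(!avail)) {
    nb <- which(adj[s, ] & avail)
    A[s] <- if (length(nb) == 0) 0 else length(nb) / 8 * median(A[nb])
  }
  A <- pmax(A, 0)
  A <- A - as.numeric(quantile(A, 0.2))
  s9 <- as.numeric((adj + diag(nrow(adj))) %*% pmax(A, 0))
  s8 <- s9 - pmax(A, 0)
  out <- A
  for (s in seq_along(A)) {
    if (!is.na(center_slot) && s == center_slot) next
    if (det[s] && A[s] > s8[s]) out[s] <- s9[s] / 2
    else if (!det[s] && A[s] > 2 / 3 * s8[s]) out[s] <- s9[s] / 3
  }
  out
}

#' Localize a single event from its cut-out
#'
#' Subtracts the median amplitude, clips at zero and computes a barycentre;
#' then twice re-weights amplitudes by distance from the current estimate
#' (weight `2 - r/d_pitch` clipped to `[0, 1]` in the first pass and to
#' `[-0.1, 1]` in the second, so that channels beyond twice the pitch count
#' slightly negatively) and recomputes the barycentre. The reported amplitude
#' is half the sum of the final weighted amplitudes. Degenerate cut-outs
#' (no amplitude above the median) return the detection location with
#' amplitude zero.
#'
#' @inheritParams channel_amplitudes
#' @return A list with `x_um`, `y_um`, `amplitude` and the per-channel
#'   amplitudes `A` after repair.
#' @export
localize_cutout <- function(cutout) {
  A <- channel_amplitudes(cutout)
  avail <- cutout$chan != 0
  A <- repair_boundary_outliers(A, avail, cutout$det, cutout$coords,
                                cutout$d_pitch, cutout$center_slot)
  res <- localize_amplitudes(A, cutout$coords, cutout$d_pitch,
                             cutout$detect_x, cutout$detect_y)
  c(res, list(A = A))
}

localize_amplitudes <- function(A, coords, d_pitch, detect_x, detect_y) {
  A1 <- pmax(A - median(A), 0)
  s1 <- sum(A1)
  if (s1 <= 1e-9)
    return(list(x_um = detect_x, y_um = detect_y, amplitude = 0))
  bx <- sum(A1 * coords[, 1]) / s1; by <- sum(A1 * coords[, 2]) / s1
  r <- sqrt((coords[, 1] - bx)^2 + (coords[, 2] - by)^2) / d_pitch
  A2 <- A1 * pmin(pmax(2 - r, 0), 1)
  s2 <- sum(A2)
  if (abs(s2) > 1e-6) {
    bx <- sum(A2 * coords[, 1]) / s2; by <- sum(A2 * coords[, 2]) / s2
  }
  r <- sqrt((coords[, 1] - bx)^2 + (coords[, 2] - by)^2) / d_pitch
  A3 <- A2 * pmin(pmax(2 - r, -0.1), 1)
  s3 <- sum(A3)
  if (abs(s3) > 1e-6) {
    bx <- sum(A3 * coords[, 1]) / s3; by <- sum(A3 * coords[, 2]) / s3
  }
  bx <- min(max(bx, min(coords[, 1])), max(coords[, 1]))
  by <- min(max(by, min(coords[, 2])), max(coords[, 2]))
  list(x_um = bx, y_um = by, amplitude = max(s3, 0) / 2)
}

# vectorized localization of a batch of events returned by the streaming
# interpolating detector (see interp_take); equivalent to localize_cutout
# applied per event
localize_batch <- function(out, ev, geom, p) {
  n <- nrow(ev)
  SL <- out$slots; T <- out$snip_len
  snip <- array(out$snip, dim = c(T, SL, n))
  gmat <- matrix(out$g, nrow = T + 1)
  bmat <- matrix(out$b, nrow = SL)
  vbar <- matrix(out$vbar, nrow = SL)
  hbar <- matrix(out$hbar, nrow = SL)
  chan <- matrix(out$chan, nrow = SL)
  detm <- matrix(out$det, nrow = SL) > 0
  dg <- gmat[-1, , drop = FALSE] - gmat[-(T + 1), , drop = FALSE]
  tau_pre <- p$tau_pre; i0 <- tau_pre + 1L
  n1 <- floor(tau_pre / 2); idx2 <- seq_len(floor((tau_pre + 1) / 2))
  idx3 <- (2L * tau_pre + 1L):T
  A <- matrix(0, SL, n)
  for (s in seq_len(SL)) {
    xt <- (snip[, s, , drop = TRUE] - t(t(dg) * hbar[s, ]))
    if (n == 1) xt <- matrix(xt, ncol = 1)
    xt <- t(t(xt) / vbar[s, ])          # frames x events, normalized
    z <- rbind(matrix(rep(bmat[s, ] / vbar[s, ], each = max(n1, 1))[
                 seq_len(n1 * n)], nrow = n1),
               xt[idx2, , drop = FALSE], xt[idx3, , drop = FALSE])
    base <- col_medians_cpp(z)
    win <- (i0 - 2):(i0 + 2)
    sm <- (xt[win - 1, , drop = FALSE] + 2 * xt[win, , drop = FALSE] +
           2 * xt[win + 1, , drop = FALSE] + xt[win + 2, , drop = FALSE]) / 6
    A[s, ] <- base - do.call(pmin, lapply(seq_len(5), function(k) sm[k, ]))
  }
  res <- matrix(NA_real_, n, 3)
  pitch <- geom$pitch_um
  for (virt in c(FALSE, TRUE)) {
    sel <- which(ev$on_virtual == virt)
    if (length(sel) == 0) next
    S <- if (virt) 12L else 9L
    u <- seq_len(S)
    ir <- (u - 1) %/% 3 - if (virt) 1.5 else 1
    ic <- (u - 1) %% 3 - if (virt) 1.5 else 1
    adj <- abs(outer(ir, ir, "-")) <= 1.001 & abs(outer(ic, ic, "-")) <= 1.001
    diag(adj) <- FALSE
    cxm <- outer(ic, ev$col[sel] - 1, "+") * pitch
    cym <- outer(ir, ev$row[sel] - 1, "+") * pitch
    Au <- A[u, sel, drop = FALSE]
    av <- chan[u, sel, drop = FALSE] != 0
    dt <- detm[u, sel, drop = FALSE]
    miss <- which(!av, arr.ind = TRUE)
    for (k in seq_len(nrow(miss))) {
      s <- miss[k, 1]; e <- miss[k, 2]
      nb <- which(adj[s, ] & av[, e])
      Au[s, e] <- if (length(nb) == 0) 0 else
        length(nb) / 8 * median(Au[nb, e])
    }
    Au <- pmax(Au, 0)
    Au <- sweep(Au, 2, col_quantile_cpp(Au, 0.2))
    Ap <- pmax(Au, 0)
    S9 <- (adj + diag(S)) %*% Ap
    S8 <- S9 - Ap
    outA <- Au
    cd <- dt & Au > S8
    co <- !dt & Au > 2 / 3 * S8
    outA[cd] <- (S9 / 2)[cd]
    outA[co] <- (S9 / 3)[co]
    if (!virt) outA[5, ] <- Au[5, ]  # centre channel exempt from clipping
    # iterative barycentre
    A1 <- pmax(sweep(outA, 2, col_medians_cpp(outA)), 0)
    s1 <- colSums(A1)
    deg <- s1 <= 1e-9
    s1s <- ifelse(deg, 1, s1)
    bx <- colSums(A1 * cxm) / s1s; by <- colSums(A1 * cym) / s1s
    r <- sqrt(sweep(cxm, 2, bx)^2 + sweep(cym, 2, by)^2) / pitch
    A2 <- A1 * pmin(pmax(2 - r, 0), 1)
    s2 <- colSums(A2)
    ok <- abs(s2) > 1e-6 & !deg
    bx[ok] <- (colSums(A2 * cxm) / s2)[ok]
    by[ok] <- (colSums(A2 * cym) / s2)[ok]
    r <- sqrt(sweep(cxm, 2, bx)^2 + sweep(cym, 2, by)^2) / pitch
    A3 <- A2 * pmin(pmax(2 - r, -0.1), 1)
    s3 <- colSums(A3)
    ok <- abs(s3) > 1e-6 & !deg
    bx[ok] <- (colSums(A3 * cxm) / s3)[ok]
    by[ok] <- (colSums(A3 * cym) / s3)[ok]
    bx <- pmin(pmax(bx, cxm[1, ]), cxm[S, ])
    by <- pmin(pmax(by, cym[1, ]), cym[S, ])
    amp <- pmax(s3, 0) / 2
    bx[deg] <- ev$x_grid_um[sel][deg]
    by[deg] <- ev$y_grid_um[sel][deg]
    amp[deg] <- 0
    res[sel, ] <- cbind(bx, by, amp)
  }
  tibble(x_um = res[, 1], y_um = res[, 2], amplitude = res[, 3])
}
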