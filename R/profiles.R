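#' Direction-bias map of coincident activity
#'
#' For each event, unit vectors towards all events inside a spatial annulus
#' (`r_min_um` to `r_max_um`) and within `rank_window` event ranks are
#' summed: an estimate of the direction towards the centre of mass of
#' coincident activity. Sums are accumulated on a square grid of
#' `cell_um`-wide cells, the local mean direction over a large sliding
#' window (`background_um` square) is subtracted to remove the global bias
#' towards the chip centre, and the residual is scaled so that a magnitude
#' of 1 corresponds to three standard deviations of the random-walk null
#' (per-component SD `sqrt(N/2)` for `N` pooled unit vectors).
#'
#' @param events Tibble with `x_um`, `y_um` and `rank` (see
#'   [rank_events()]; any integer event order works).
#' @param cell_um Spatial sliding-window width (default 17.5).
#' @param r_min_um,r_max_um Annulus bounds (defaults 82 and 1092).
#' @param rank_window Temporal window in event ranks (default 30).
#' @param background_um Side length of the background window (default 336);
#'   `NULL` skips the background subtraction and reports raw directions.
#' @return Object of class `mea_biasmap`: tibble with cell centres `x_um`,
#'   `y_um`, vector components `bias_x`, `bias_y`, magnitude `bias` (1 = 3
#'   null SD) and pooled vector count `n`.
#' @export
direction_bias_map <- function(events, cell_um = 17.5, r_min_um = 82,
                               r_max_um = 1092, rank_window = 30,
                               background_um = 336) {
  ev <- arrange(events, .data$rank)
  n <- nrow(ev)
  sx <- numeric(n); sy <- numeric(n); cnt <- numeric(n)
  x <- ev$x_um; y <- ev$y_um; rk <- ev$rank
  lo <- findInterval(rk - rank_window - 0.5, rk) + 1L
  hi <- findInterval(rk + rank_window + 0.5, rk)
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    d <- sqrt(dx^2 + dy^2)
    ok <- d > r_min_um & d < r_max_um
    if (!any(ok)) next
    sx[i] <- sum(dx[ok] / d[ok]); sy[i] <- sum(dy[ok] / d[ok])
    cnt[i] <- sum(ok)
  }
  cx <- floor(x / cell_um); cy <- floor(y / cell_um)
  cells <- tibble(cx = cx, cy = cy, sx = sx, sy = sy, n = cnt) |>
    group_by(.data$cx, .data$cy) |>
    summarise(sx = sum(.data$sx), sy = sum(.data$sy), n = sum(.data$n),
              .groups = "drop")
  # background: mean unit vector over the large window
  bgx <- bgy <- numeric(nrow(cells))
  if (!is.null(background_um)) {
    half <- ceiling(background_um / cell_um / 2)
    for (i in seq_len(nrow(cells))) {
      nb <- abs(cells$cx - cells$cx[i]) <= half &
            abs(cells$cy - cells$cy[i]) <= half
      ntot <- sum(cells$n[nb])
      if (ntot > 0) {
        bgx[i] <- sum(cells$sx[nb]) / ntot
        bgy[i] <- sum(cells$sy[nb]) / ntot
      }
    }
  }
  sdnull <- 3 * sqrt(pmax(cells$n, 1) / 2)
  bias_x <- (cells$sx - cells$n * bgx) / sdnull
  bias_y <- (cells$sy - cells$n * bgy) / sdnull
  out <- tibble(x_um = (cells$cx + 0.5) * cell_um,
                y_um = (cells$cy + 0.5) * cell_um,
                bias_x = bias_x, bias_y = bias_y,
                bias = sqrt(bias_x^2 + bias_y^2), n = cells$n)
  out$bias[out$n == 0] <- NA_real_
  class(out) <- c("mea_biasmap", class(out))
  out
}

#' Event density as a function of distance from anchor points
#'
#' Computes the event density found at least a distance `x` away from the
#' nearest anchor (e.g. stained somata), normalized by the same curve for a
#' homogeneous surrogate point set over the same region, plus the mutual
#' association of smoothed event-density maxima and anchors.
#'
#' @param events Tibble with `x_um`, `y_um`.
#' @param anchors Tibble with `x_um`, `y_um` (must be non-empty).
#' @param max_distance_um Largest distance evaluated (default 84).
#' @param step_um Distance step (default 2).
#' @param bounds Region as `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   anchor bounding box.
#' @param n_surrogate Homogeneous surrogate sample size.
#' @param assoc_radius_um Radius for maxima/anchor association (default 40).
#' @param kernel_radius_um Smoothing radius for the density maxima.
#' @param seed RNG seed for the surrogate.
#' @return A list: `curve` (tibble `distance_um`, `density`,
#'   `density_raw`), `maxima` (tibble of density maxima),
#'   `frac_maxima_near_anchor`, `frac_anchors_near_maximum`.
#' @export
point_proximity_curves <- function(events, anchors, max_distance_um = 84,
                                   step_um = 2, bounds = NULL,
                                   n_surrogate = 20000,
                                   assoc_radius_um = 40,
                                   kernel_radius_um = 15, seed = 1) {
  if (nrow(anchors) == 0) abort("anchor set is empty")
  if (is.null(bounds))
    bounds <- c(range(anchors$x_um), range(anchors$y_um))
  nearest_d <- function(px, py) {
    vapply(seq_along(px), function(i)
      sqrt(min((anchors$x_um - px[i])^2 + (anchors$y_um - py[i])^2)),
      numeric(1))
  }
  de <- nearest_d(events$x_um, events$y_um)
  set.seed(seed)
  sx <- runif(n_surrogate, bounds[1], bounds[2])
  sy <- runif(n_surrogate, bounds[3], bounds[4])
  ds <- nearest_d(sx, sy)
  xs <- seq(0, max_distance_um, by = step_um)
  frac_e <- vapply(xs, function(r) mean(de >= r), numeric(1))
  frac_s <- vapply(xs, function(r) mean(ds >= r), numeric(1))
  curve <- tibble(distance_um = xs, density_raw = frac_e,
                  density = ifelse(frac_s > 0, frac_e / frac_s, NA_real_))
  span_x <- bounds[2] - bounds[1]; span_y <- bounds[4] - bounds[3]
  bins <- max(16, round(max(span_x, span_y) / 10))
  mx <- density_maxima(events$x_um - bounds[1], events$y_um - bounds[3],
                       span_x, span_y, bins, kernel_radius_um,
                       kernel_radius_um, min_rel = 0.2)
  mx$x <- mx$x + bounds[1]; mx$y <- mx$y + bounds[3]
  fm <- if (nrow(mx) == 0) NA_real_ else
    mean(nearest_d(mx$x, mx$y) <= assoc_radius_um)
  fa <- if (nrow(mx) == 0) 0 else mean(vapply(seq_len(nrow(anchors)),
    function(i) min(sqrt((mx$x - anchors$x_um[i])^2 +
                         (mx$y - anchors$y_um[i])^2)) <= assoc_radius_um,
    logical(1)))
  list(curve = curve, maxima = mx,
       frac_maxima_near_anchor = fm, frac_anchors_near_maximum = fa)
}
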