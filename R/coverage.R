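#' Coverage of a circular activity spot by a 3x3 bin block
#'
#' The correlation analysis groups a fine spatial raster (by default 192
#' bins across a 64-electrode, 42-um-pitch array, i.e. three bins per
#' electrode pitch) into 3x3-bin units. This function quantifies, by
#' deterministic numeric integration, how much of the area of a circular
#' spot of activity of diameter `spot_diameter_um` is captured by the
#' best-aligned 3x3 block of bins, as a function of the spot centre within
#' a bin; because the block is chosen per spot, the centre position can be
#' reduced to one half-bin quadrant.
#'
#' @param bin_um Bin width in micrometres (default 42 * 64 / 192 = 14).
#' @param spot_diameter_um Spot diameter (default one pitch, 42).
#' @param n_centers Centre offsets per axis integrated over (default 25).
#' @param n_grid Integration resolution across the spot (default 201).
#' @return A list with `mean` (coverage fraction averaged over spot
#'   centres), `min` (worst-case centre), and the per-centre tibble `grid`.
#' @export
bin_block_coverage <- function(bin_um = 14, spot_diameter_um = 42,
                               n_centers = 25, n_grid = 201) {
  r <- spot_diameter_um / 2
  block <- 3 * bin_um
  # integration points over the disc
  g <- seq(-r, r, length.out = n_grid)
  gx <- rep(g, times = n_grid); gy <- rep(g, each = n_grid)
  inside <- gx^2 + gy^2 <= r^2
  gx <- gx[inside]; gy <- gy[inside]
  offs <- seq(0, bin_um / 2, length.out = n_centers)
  grid <- tidyr::expand_grid(off_x = offs, off_y = offs)
  cover <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    # candidate 3x3 blocks are bin-aligned; their centres sit on the bin
    # grid, displaced from the spot centre by (-off + multiples of a bin)
    best <- 0
    for (sx in bin_um * (-1:1)) for (sy in bin_um * (-1:1)) {
      cx <- sx - grid$off_x[i]; cy <- sy - grid$off_y[i]
      frac <- mean(abs(gx - cx) <= block / 2 & abs(gy - cy) <= block / 2)
      best <- max(best, frac)
    }
    cover[i] <- best
  }
  grid$coverage <- cover
  list(mean = mean(cover), min = min(cover), grid = grid)
}
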