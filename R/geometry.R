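#' Electrode grid geometry
#'
#' Describes a square multielectrode array: electrodes sit on a regular grid
#' with centre-to-centre spacing `pitch_um`. Electrode `(row, col)` (1-based)
#' has its centre at `((col - 1) * pitch_um, (row - 1) * pitch_um)` in
#' micrometres, and channels are numbered row-major:
#' `channel = (row - 1) * n_cols + col`.
#'
#' @param n_rows,n_cols Number of electrode rows / columns (>= 1).
#' @param pitch_um Centre-to-centre electrode spacing in micrometres.
#' @param electrode_size_um Electrode side length in micrometres.
#' @return An object of class `mea_geometry`.
#' @examples
#' geom <- mea_geometry(64, 64)
#' channel_position(geom, 1)
#' @export
mea_geometry <- function(n_rows, n_cols, pitch_um = 42, electrode_size_um = 21) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) abort("n_rows and n_cols must be >= 1")
  if (!is.finite(pitch_um) || pitch_um <= 0) abort("pitch_um must be > 0")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pitch_um = pitch_um,
         electrode_size_um = electrode_size_um),
    class = "mea_geometry")
}

#' @export
print.mea_geometry <- function(x, ...) {
  cat(sprintf("<mea_geometry> %d x %d electrodes, pitch %g um (%d channels)\n",
              x$n_rows, x$n_cols, x$pitch_um, x$n_rows * x$n_cols))
  invisible(x)
}

#' @rdname mea_geometry
#' @export
n_channels <- function(geom) geom$n_rows * geom$n_cols

#' Channel indexing helpers
#'
#' Row-major channel numbering: `channel = (row - 1) * n_cols + col` with
#' 1-based rows, columns and channels.
#'
#' @param geom An [mea_geometry()].
#' @param row,col Electrode row / column indices (1-based).
#' @param channel Channel index (1-based).
#' @return `channel_index()` returns integer channel ids; `channel_rowcol()`
#'   and `channel_position()` return tibbles with one row per channel.
#' @export
channel_index <- function(geom, row, col) {
  stopifnot(all(row >= 1L), all(row <= geom$n_rows),
            all(col >= 1L), all(col <= geom$n_cols))
  as.integer((row - 1L) * geom$n_cols + col)
}

#' @rdname channel_index
#' @export
channel_rowcol <- function(geom, channel) {
  channel <- as.integer(channel)
  stopifnot(all(channel >= 1L), all(channel <= n_channels(geom)))
  tibble(channel = channel,
         row = (channel - 1L) %/% geom$n_cols + 1L,
         col = (channel - 1L) %% geom$n_cols + 1L)
}

#' @rdname channel_index
#' @export
channel_position <- function(geom, channel) {
  rc <- channel_rowcol(geom, channel)
  mutate(rc, x_um = (.data$col - 1) * geom$pitch_um,
         y_um = (.data$row - 1) * geom$pitch_um)
}
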