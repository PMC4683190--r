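#' Broom-style tidiers
#'
#' `tidy()` returns the per-group results (per patch for ROC objects, per
#' unit for classifications), `glance()` a one-row summary, and `augment()`
#' (classification only) the per-event table with probabilities.
#'
#' @param x An `mea_roc`, `mea_links` or `mea_classification` object.
#' @param ... Unused.
#' @name hdmea-tidiers
NULL

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' @rdname hdmea-tidiers
#' @export
tidy.mea_roc <- function(x, ...) x$pauc

#' @rdname hdmea-tidiers
#' @export
glance.mea_roc <- function(x, ...) {
  tibble(n_patches = nrow(x$pauc),
         mean_pauc = mean(x$pauc$pauc),
         sd_pauc = sd(x$pauc$pauc),
         max_fp_hz = x$max_fp_hz)
}

#' @rdname hdmea-tidiers
#' @export
tidy.mea_classification <- function(x, ...) x$units

#' @rdname hdmea-tidiers
#' @export
glance.mea_classification <- function(x, ...) {
  ev <- x$events
  ok <- !is.na(ev$p_uncorrelated)
  tibble(n_units = nrow(x$units),
         n_units_boundary = sum(x$units$method == "boundary"),
         n_units_flagged = sum(x$units$method == "flagged"),
         n_events = nrow(ev),
         fraction_correlated_events =
           mean(ev$p_uncorrelated[ok] < 0.5))
}

#' @rdname hdmea-tidiers
#' @export
augment.mea_classification <- function(x, ...) x$events

#' @rdname hdmea-tidiers
#' @export
tidy.mea_links <- function(x, ...) x$pairs

#' @rdname hdmea-tidiers
#' @export
glance.mea_links <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         n_linked = sum(x$pairs$linked),
         n_removed = sum(x$pairs$removed),
         tau_corr = x$tau_corr)
}
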