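#' Tidy an FZCA analysis
#'
#' `tidy()` returns the per-protein crossing table; `glance()` a one-row
#' summary of the run statistic and regime call.
#'
#' @param x An `fzca_result` from [analyze_fzca()].
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' ts <- synth_species_ts(2e4, period = 4000, seed = 1)
#' fz <- analyze_fzca(ts, segment_length = 1e4, n_segments = 2)
#' tidy(fz)
#' glance(fz)
#' @export
tidy.fzca_result <- function(x, ...) {
  x$channels
}

#' @rdname tidy.fzca_result
#' @export
glance.fzca_result <- function(x, ...) {
  tibble(fzca_min = x$fzca_min, regime = x$regime,
         n_defined = sum(x$channels$defined),
         threshold = x$threshold, segment_length = x$segment_length,
         stride = x$stride)
}

#' Tidy a Hopf-bifurcation scan
#'
#' `tidy()` returns the per-grid-point classification; `glance()` counts
#' the oscillatory region and boundary points.
#'
#' @param x A `hopf_scan` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hopf_scan <- function(x, ...) {
  x$grid
}

#' @rdname tidy.hopf_scan
#' @export
glance.hopf_scan <- function(x, ...) {
  tibble(n_points = nrow(x$grid),
         n_oscillatory = sum(x$grid$class == "oscillatory", na.rm = TRUE),
         n_failed = sum(x$grid$failed),
         n_boundary = nrow(x$boundary))
}

#' Tidy a parameter sweep
#'
#' `tidy()` aggregates per-replicate FZCA values into mean +/- sd per sweep
#' point ([aggregate_sweep()]); `glance()` summarises the sweep extent.
#'
#' @param x A `sweep_result` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sweep_result <- function(x, ...) {
  aggregate_sweep(x)
}

#' @rdname tidy.sweep_result
#' @export
glance.sweep_result <- function(x, ...) {
  tibble(n_points = nrow(dplyr::distinct(
           as_tibble(x)[, intersect(c("scenario", "param", "value"),
                                    names(x))])),
         n_replicates = nrow(x),
         n_failed = sum(x$regime == "failed", na.rm = TRUE))
}
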