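#' Plot an ODE trajectory
#'
#' Protein copy numbers against time; in the oscillatory regime the three
#' curves are pairwise anti-synchronized.
#'
#' @param object An `ode_trajectory` from [integrate_ode()].
#' @param species Columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ode_trajectory <- function(object, species = c("P0", "P1", "P2"),
                                    ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[, c("t", species)],
                            -"t", names_to = "species",
                            values_to = "copies")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$copies,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (steps)", y = "copies per cell",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulated species time series
#'
#' @param object A `species_ts` from [simulate_circuit()].
#' @param species Columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.species_ts <- function(object, species = c("P0", "P1", "P2"), ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[, c("t", species)],
                            -"t", names_to = "species",
                            values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$count,
                                   colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "MC time step", y = "total molecules",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a gene layout
#'
#' Gene positions coloured by type, with confinement boxes outlined where
#' present (2D layouts; 3D layouts are shown as an x-y projection).
#'
#' @param object A `gene_layout` from [place_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_layout <- function(object, ...) {
  lat <- layout_lattice(object)
  df <- as_tibble(object)
  df$type <- factor(df$type)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        colour = .data$type)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_fixed(xlim = c(0, lat$R - 1), ylim = c(0, lat$R - 1)) +
    ggplot2::labs(x = "x", y = "y", colour = "gene type") +
    ggplot2::theme_minimal()
  org <- attr(object, "box_origins")
  r <- attr(object, "r")
  if (!is.null(org)) {
    boxes <- as_tibble(as.data.frame(org))
    p <- p + ggplot2::geom_rect(
      data = boxes, inherit.aes = FALSE, fill = NA, colour = "grey40",
      ggplot2::aes(xmin = .data$x - 0.5, xmax = .data$x + r - 0.5,
                   ymin = .data$y - 0.5, ymax = .data$y + r - 0.5))
  }
  p
}

#' Plot the averaged autocorrelation functions of an FZCA analysis
#'
#' One curve per protein with the first zero crossings marked; an
#' oscillatory run decays slowly and dips below zero near a quarter period,
#' a stationary run decorrelates almost immediately.
#'
#' @param object An `fzca_result` from [analyze_fzca()].
#' @param max_lag Largest lag to draw (recorded units; default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fzca_result <- function(object, max_lag = NULL, ...) {
  df <- purrr::imap_dfr(object$acf, function(a, ch) {
    if (is.null(a)) return(NULL)
    tibble(channel = ch, lag = a$lags * object$stride, acf = a$acf)
  })
  if (!is.null(max_lag)) df <- dplyr::filter(df, .data$lag <= max_lag)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$acf,
                                        colour = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (MC time steps)", y = "averaged ACF",
                  colour = NULL) +
    ggplot2::theme_minimal()
  tau <- dplyr::filter(object$channels, .data$defined)
  if (nrow(tau)) {
    p <- p + ggplot2::geom_vline(data = tau, linetype = "dashed",
                                 ggplot2::aes(xintercept = .data$tau0,
                                              colour = .data$channel))
  }
  p
}

#' Plot an aggregated parameter sweep
#'
#' Mean FZCA +/- 1 standard deviation per sweep point, one colour per
#' spatial scenario; the uniform reference (no swept value) is drawn as a
#' horizontal band.
#'
#' @param object A `sweep_result` (per-replicate tibble) or its
#'   [aggregate_sweep()] summary.
#' @param log_x Log-scale the swept value axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, log_x = TRUE, ...) {
  agg <- if ("fzca_min" %in% names(object)) aggregate_sweep(object)
         else as_tibble(object)
  ref <- dplyr::filter(agg, is.na(.data$value))
  agg <- dplyr::filter(agg, !is.na(.data$value))
  p <- ggplot2::ggplot(agg, ggplot2::aes(.data$value, .data$mean_fzca,
                                         colour = .data$scenario)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_fzca - .data$sd_fzca,
                                        ymax = .data$mean_fzca + .data$sd_fzca),
                           width = 0) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = unique(agg$param), y = "mean FZCA (MC time steps)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(ref)) {
    p <- p +
      ggplot2::geom_hline(data = ref, linetype = "solid",
                          ggplot2::aes(yintercept = .data$mean_fzca,
                                       colour = .data$scenario)) +
      ggplot2::geom_hline(data = ref, linetype = "dashed",
                          ggplot2::aes(yintercept = .data$mean_fzca +
                                         .data$sd_fzca,
                                       colour = .data$scenario)) +
      ggplot2::geom_hline(data = ref, linetype = "dashed",
                          ggplot2::aes(yintercept = .data$mean_fzca -
                                         .data$sd_fzca,
                                       colour = .data$scenario))
  }
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a Hopf-bifurcation scan
#'
#' Stability classification over the (alpha, tau_p) grid with the
#' interpolated Hopf boundary overlaid.
#'
#' @param object A `hopf_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hopf_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(.data$alpha, .data$tau_p)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$class)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(alpha), y = expression(tau[P]),
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (nrow(object$boundary)) {
    p <- p + ggplot2::geom_point(data = object$boundary, shape = 4)
  }
  p
}
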