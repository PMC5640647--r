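#' Quadrant dot plot of a BOX/PI co-stained sample
#'
#' FL1 (BOX) against FL3 (PI) on log-display scales with the quadrant cuts
#' drawn; the standard view for reading viability structure.
#'
#' @param events An [event_table()] with `FL1_A` and `FL3_A`.
#' @param thresholds Optional `quadrant_thresholds`; drawn as dashed lines
#'   and used to colour events by state.
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(events, thresholds = NULL, alpha = 0.2) {
  check_channel(events, c("FL1_A", "FL3_A"))
  df <- tibble(fl1 = log_display(events$FL1_A),
               fl3 = log_display(events$FL3_A))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fl3, y = .data$fl1))
  if (!is.null(thresholds)) {
    df$state <- classify_viability(events, thresholds)$labels
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fl3, y = .data$fl1,
                                          colour = .data$state)) +
      ggplot2::geom_vline(xintercept = log_display(thresholds$fl3_cut),
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = log_display(thresholds$fl1_cut),
                          linetype = "dashed")
  }
  p + ggplot2::geom_point(alpha = alpha, size = 0.4) +
    ggplot2::labs(x = "PI fluorescence, log10(FL3-A)",
                  y = "BOX fluorescence, log10(FL1-A)")
}

#' Scatter (morphology) dot plot
#'
#' SSC against FSC on log-display scales, optionally coloured by the
#' generating label of synthetic events.
#'
#' @param events An [event_table()].
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_scatter <- function(events, alpha = 0.2) {
  df <- tibble(fsc = log_display(events$FSC_A),
               ssc = log_display(events$SSC_A))
  aes <- ggplot2::aes(x = .data$ssc, y = .data$fsc)
  if (!is.null(events[["true_label"]])) {
    df$label <- events$true_label
    aes <- ggplot2::aes(x = .data$ssc, y = .data$fsc, colour = .data$label)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = alpha, size = 0.4) +
    ggplot2::labs(x = "log10(SSC-A)", y = "log10(FSC-A)")
}

#' @rdname plot_scatter
#' @param object An `event_tbl`.
#' @param ... Passed to [plot_scatter()].
#' @export
autoplot.event_tbl <- function(object, ...) plot_scatter(object, ...)

#' Histogram of a fitted fluorescence channel with mixture components
#'
#' @param object A `mixture_fit` from [fit_subpopulations()].
#' @param events The [event_table()] the fit was made on.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_fit <- function(object, events, bins = 80, ...) {
  x <- log_display(events[[object$channel]])
  df <- tibble(x = x)
  grid <- seq(min(x), max(x), length.out = 400)
  dens <- purrr::map_dfr(seq_len(object$k), function(i) {
    tibble(component = factor(i), x = grid,
           density = object$weights[[i]] *
             dnorm(grid, object$means[[i]], object$sds[[i]]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = sprintf("log10(%s)", object$channel), y = "density")
}

#' Condition-comparison bar panels
#'
#' One facet per metric, conditions in the order the comparison table
#' carries, error bars from the `dispersion` column where present — the
#' standard multi-condition summary figure.
#'
#' @param comparison A [compare_conditions()] table.
#' @param metrics Metrics to show (default: OD565, C_mag, stain MFIs, healthy
#'   fraction).
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparison,
                            metrics = c("od565", "cmag", "pyr546_mfi",
                                        "pgsk_mfi", "viability_healthy")) {
  df <- dplyr::filter(comparison, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$dispersion,
                   ymax = .data$value + .data$dispersion),
      width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
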