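#' Mean fluorescence intensity and dispersion of one channel
#'
#' MFI is the arithmetic mean on the linear scale (the instrument-software
#' meaning of "mean fluorescence intensity"); dispersion is the coefficient
#' of variation (sample sd / mean, n-1 denominator).
#'
#' @param events An [event_table()] with at least one event.
#' @param channel Channel name.
#' @return A tibble of class `fluorescence_summary` with columns `channel`,
#'   `mfi`, `cv`, `n_events`.
#' @export
#' @examples
#' ev <- event_table(data.frame(FSC_A = 1:3, SSC_A = 1:3, FL1_A = c(50, 150, 100)))
#' summarize_fluorescence(ev, "FL1_A")
summarize_fluorescence <- function(events, channel) {
  check_channel(events, channel)
  if (nrow(events) == 0L) {
    stop_magcyto("summarize_fluorescence needs at least one event.",
                 "magcyto_sample_size_error")
  }
  x <- events[[channel]]
  m <- mean(x)
  out <- tibble(channel = channel, mfi = m,
                cv = if (length(x) < 2L || m == 0) 0 else stats::sd(x) / m,
                n_events = length(x))
  class(out) <- c("fluorescence_summary", class(out))
  out
}

#' PG-SK iron index: fold-quench and estimated chelatable iron
#'
#' The iron probe PG-SK is quenched by chelatable Fe2+/Fe3+, so *lower*
#' fluorescence means *more* intracellular iron. Relative to an iron-free
#' reference, `fold_quench = reference_mfi / sample_mfi` is monotone in iron;
#' inverting the Stern-Volmer model gives an iron estimate
#' `(fold_quench - 1) / K_sv` in uM when a model is supplied.
#'
#' @param sample,reference [summarize_fluorescence()] results for the PG-SK
#'   (FL1) channel; `reference` is the iron-free (unquenched) condition.
#' @param model Optional [quench_model()]; without it only `fold_quench` is
#'   returned (`iron_um = NA`).
#' @return A tibble with columns `fold_quench`, `iron_um`.
#' @export
#' @examples
#' s <- tibble::tibble(channel = "FL1_A", mfi = 500, cv = 0.2, n_events = 100)
#' r <- tibble::tibble(channel = "FL1_A", mfi = 1000, cv = 0.2, n_events = 100)
#' iron_index(s, r, quench_model(f0 = 1000, K_sv = 0.1))
iron_index <- function(sample, reference, model = NULL) {
  if (sample$mfi <= 0) {
    stop_magcyto("sample MFI must be > 0 to form the quench ratio.",
                 "magcyto_division_error")
  }
  if (reference$mfi <= 0) {
    stop_magcyto("reference MFI must be > 0.", "magcyto_division_error")
  }
  fold <- reference$mfi / sample$mfi
  iron <- NA_real_
  if (!is.null(model)) {
    if (!inherits(model, "quench_model")) {
      stop_magcyto("`model` must be a quench_model().", "magcyto_param_error")
    }
    iron <- if (model$K_sv > 0) (fold - 1) / model$K_sv else NA_real_
  }
  tibble(fold_quench = fold, iron_um = iron)
}

## ---- count calibration -----------------------------------------------------

new_count_calibration <- function(mode, slope, r2, n_points, provenance) {
  if (!is.numeric(slope) || slope <= 0) {
    stop_magcyto("calibration slope must be > 0.", "magcyto_param_error")
  }
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) {
    stop_magcyto("r2 must be in [0, 1].", "magcyto_param_error")
  }
  structure(list(mode = mode, slope = slope, r2 = r2,
                 n_points = as.integer(n_points), provenance = provenance),
            class = "count_calibration")
}

#' Fit an OD565-to-concentration calibration
#'
#' Fits the proportional model `concentration = slope * OD565` by least
#' squares through the origin (the relation is a per-OD equivalence, so no
#' intercept), with `r2 = 1 - SS_res / SS_tot`, `SS_tot` about the mean
#' concentration.
#'
#' @param pairs Data frame with columns `od565` and `concentration`; at least
#'   3 pairs, at least 2 distinct OD values, all positive.
#' @param mode `"FCM"` (cytometric events) or `"CFU"` (colony counts).
#' @return A `count_calibration` with `slope`, `r2`, `n_points`; supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' fit_count_calibration(tibble::tibble(
#'   od565 = c(0.1, 0.5, 1.0),
#'   concentration = c(1.16e8, 5.8e8, 1.16e9)))
fit_count_calibration <- function(pairs, mode = c("FCM", "CFU")) {
  mode <- match.arg(mode)
  if (!all(c("od565", "concentration") %in% names(pairs))) {
    stop_magcyto("`pairs` needs columns od565 and concentration.",
                 "magcyto_param_error")
  }
  od <- pairs$od565; conc <- pairs$concentration
  if (length(od) < 3L) {
    stop_magcyto("need at least 3 calibration pairs.", "magcyto_fit_error")
  }
  if (any(od <= 0) || any(conc <= 0)) {
    stop_magcyto("all calibration pairs must be positive.",
                 "magcyto_validation_error")
  }
  if (length(unique(od)) < 2L) {
    stop_magcyto("degenerate design: need >= 2 distinct OD values.",
                 "magcyto_fit_error")
  }
  fit <- lm(conc ~ 0 + od)
  slope <- unname(stats::coef(fit)[[1L]])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((conc - mean(conc))^2)
  new_count_calibration(
    mode = mode, slope = slope,
    r2 = 1 - ss_res / ss_tot, n_points = length(od),
    provenance = sprintf("through-origin least squares on %d pairs", length(od))
  )
}

#' @export
print.count_calibration <- function(x, ...) {
  cat(sprintf("<count_calibration> 1 OD565 = %.3g %s/mL (r2 = %s, n = %d)\n",
              x$slope, if (x$mode == "CFU") "CFU" else "cells",
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)), x$n_points))
  invisible(x)
}

#' Convert an OD565 reading to a concentration
#'
#' @param od OD565 value(s), each >= 0.
#' @param calibration A `count_calibration` (fitted or packaged; see
#'   [load_calibration()]).
#' @return A tibble with columns `od565`, `concentration`, `mode`.
#' @export
#' @examples
#' od_to_concentration(1.0, load_calibration("fcm_unstained"))
od_to_concentration <- function(od, calibration) {
  if (!inherits(calibration, "count_calibration")) {
    stop_magcyto("`calibration` must be a count_calibration.",
                 "magcyto_param_error")
  }
  if (!is.numeric(od) || any(!is.finite(od)) || any(od < 0)) {
    stop_magcyto("`od` must be non-negative and finite.",
                 "magcyto_validation_error")
  }
  tibble(od565 = as.numeric(od), concentration = calibration$slope * od,
         mode = calibration$mode)
}

#' Volumetric event concentration from acquisition metadata
#'
#' Events per mL from the counted events, the acquisition volume
#' (`flow_rate [uL/min] * duration [s] / 60`, converted to mL) and the sample
#' dilution: `n_events * dilution_factor / volume_mL`.
#'
#' @param meta An [acquisition_meta()] with measured (non-sentinel)
#'   `flow_rate`, `duration` and `dilution_factor`.
#' @return Events per mL (numeric scalar).
#' @export
#' @examples
#' events_to_concentration(acquisition_meta(flow_rate = 35, duration = 120,
#'                                          n_events = 70000))
events_to_concentration <- function(meta) {
  if (!inherits(meta, "acquisition_meta")) {
    stop_magcyto("`meta` must be an acquisition_meta.", "magcyto_param_error")
  }
  needed <- c("flow_rate", "duration")
  if (is.na(meta$duration) || any(needed %in% meta$assumed)) {
    stop_magcyto(
      "acquisition metadata holds sentinel/assumed values for flow_rate or duration; cannot count volumetrically.",
      "magcyto_metadata_error")
  }
  volume_ml <- meta$flow_rate * meta$duration / 60 / 1000
  meta$n_events * meta$dilution_factor / volume_ml
}
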