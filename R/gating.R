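#' Log-display transform
#'
#' Cytometer dot plots are drawn on decade scales; this is the display
#' transform the gating and heterogeneity summaries use:
#' `log10(max(value, 1))`, i.e. intensities at or below 1 a.u. are floored at
#' 0 decades. Storage stays linear; this is applied only at use time.
#'
#' @param values Non-negative linear intensities (vectorised).
#' @return `log10(pmax(values, 1))`, monotone non-decreasing.
#' @export
#' @examples
#' log_display(c(0, 1, 10, 1000))
log_display <- function(values) {
  if (!is.numeric(values) || any(values < 0, na.rm = TRUE)) {
    stop_magcyto("`values` must be non-negative.", "magcyto_validation_error")
  }
  log10(pmax(values, 1))
}

#' Remove noise particles before analysis
#'
#' Discriminates cells from noise particles of similar size either by the
#' far-red DNA stain Syto62 (`mode = "syto62"`: keep events with
#' `FL4_A > cut`) or by forward scatter alone (`mode = "scatter"`:
#' `FSC_A > cut`). The retained fraction is recorded on the result as the
#' `retained_fraction` attribute.
#'
#' @param events An [event_table()].
#' @param mode `"syto62"` or `"scatter"`.
#' @param cut Linear-scale threshold; `cut = 0` retains everything.
#' @return The filtered [event_table()].
#' @export
noise_gate <- function(events, mode = c("syto62", "scatter"), cut) {
  mode <- match.arg(mode)
  check_number(cut, "cut", 0)
  channel <- if (mode == "syto62") "FL4_A" else "FSC_A"
  check_channel(events, channel)
  keep <- events[[channel]] > cut
  out <- event_table(as_tibble(events)[keep, , drop = FALSE],
                     event_meta(events))
  attr(out, "retained_fraction") <-
    if (nrow(events)) mean(keep) else NA_real_
  attr(out, "noise_gate") <- list(mode = mode, channel = channel, cut = cut)
  out
}

#' Place quadrant thresholds from a dye-negative control
#'
#' The BOX/PI quadrant cuts are the given nearest-rank percentile (default
#' 99.5) of the control sample's FL1 and FL3 intensities — standard
#' dye-negative gating: a stained event is called positive only if it exceeds
#' what 99.5% of unstained cells reach.
#'
#' @param control An [event_table()] of an unstained (or stain-negative)
#'   sample with `FL1_A` and `FL3_A`; at least 100 events.
#' @param percentile Percentile in (0, 100]; nearest-rank definition
#'   (`ceiling(p/100 * n)`-th order statistic).
#' @param control_id Identifier recorded as provenance.
#' @return A list of class `quadrant_thresholds` with `fl1_cut`, `fl3_cut`
#'   and `provenance`.
#' @export
estimate_thresholds <- function(control, percentile = 99.5,
                                control_id = "control") {
  check_channel(control, c("FL1_A", "FL3_A"))
  check_number(percentile, "percentile", 0, strict_min = TRUE)
  if (percentile > 100) {
    stop_magcyto("`percentile` must be <= 100.", "magcyto_param_error")
  }
  if (nrow(control) < 100L) {
    stop_magcyto(sprintf(
      "need >= 100 control events to place thresholds (got %d).",
      nrow(control)), "magcyto_sample_size_error")
  }
  cut <- function(x) nearest_rank(x, percentile)
  structure(
    list(fl1_cut = cut(control$FL1_A), fl3_cut = cut(control$FL3_A),
         provenance = list(control_id = control_id, percentile = percentile,
                           n_control = nrow(control))),
    class = "quadrant_thresholds"
  )
}

## nearest-rank percentile: the ceiling(p/100 * n)-th order statistic
nearest_rank <- function(x, p) {
  as.numeric(sort(x)[max(1L, ceiling(p / 100 * length(x)))])
}

#' @export
print.quadrant_thresholds <- function(x, ...) {
  cat(sprintf(
    "<quadrant_thresholds> FL1 (BOX) > %.4g, FL3 (PI) > %.4g  [p%.4g of %s, n=%d]\n",
    x$fl1_cut, x$fl3_cut, x$provenance$percentile,
    x$provenance$control_id, x$provenance$n_control))
  invisible(x)
}

#' Classify events into viability quadrants
#'
#' Quadrant scheme on the BOX (FL1, membrane-potential) x PI (FL3, membrane
#' integrity) plane:
#' * `healthy`: BOX- PI- (quadrant 1) — polarised, intact membrane;
#' * `injured`: BOX+ PI- (quadrant 2) — depolarised but intact;
#' * `dead`:    BOX+ PI+ (quadrant 3) — depolarised and permeabilised;
#' * `anomalous`: BOX- PI+ (quadrant 4) — reported separately, never folded
#'   into `dead`, since its biology is unresolved.
#'
#' Positivity is strict (`intensity > cut`); an event exactly on a cut counts
#' negative.
#'
#' @param events An [event_table()] with `FL1_A` and `FL3_A`.
#' @param thresholds A `quadrant_thresholds` from [estimate_thresholds()].
#' @return A list of class `viability_fractions`: tibble `fractions`
#'   (`state`, `fraction`, summing to 1), `labels` (per-event factor),
#'   `n_events`, `thresholds`, and `empty` flag. An empty table yields zero
#'   fractions, `n_events = 0` and a warning, not an error.
#' @export
classify_viability <- function(events, thresholds) {
  if (!inherits(thresholds, "quadrant_thresholds")) {
    stop_magcyto("`thresholds` must come from estimate_thresholds().",
                 "magcyto_param_error")
  }
  states <- c("healthy", "injured", "dead", "anomalous")
  if (nrow(events) == 0L) {
    warn("empty event table: viability fractions reported as 0 with n_events = 0.")
    return(structure(
      list(fractions = tibble(state = states, fraction = 0),
           labels = factor(character(), levels = states),
           n_events = 0L, thresholds = thresholds, empty = TRUE),
      class = "viability_fractions"))
  }
  check_channel(events, c("FL1_A", "FL3_A"))
  box_pos <- events$FL1_A > thresholds$fl1_cut
  pi_pos <- events$FL3_A > thresholds$fl3_cut
  lab <- dplyr::case_when(
    !box_pos & !pi_pos ~ "healthy",
    box_pos & !pi_pos ~ "injured",
    box_pos & pi_pos ~ "dead",
    TRUE ~ "anomalous"
  )
  lab <- factor(lab, levels = states)
  structure(
    list(fractions = tibble(state = states,
                            fraction = as.vector(table(lab)) / length(lab)),
         labels = lab, n_events = length(lab), thresholds = thresholds,
         empty = FALSE),
    class = "viability_fractions"
  )
}

#' @export
print.viability_fractions <- function(x, ...) {
  cat(sprintf("<viability_fractions> n = %d events\n", x$n_events))
  f <- x$fractions
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-9s %6.2f%%\n", f$state[[i]], 100 * f$fraction[[i]]))
  }
  invisible(x)
}

#' Scatter-channel morphology summary
#'
#' Per-channel mean and coefficient of variation of forward and side scatter,
#' plus a heterogeneity index — the CV of log-displayed FSC, which tracks the
#' visual spread of a count-vs-FSC histogram and separates homogeneous
#' liquid-grown populations from polydisperse, filamentous plate-grown ones.
#'
#' @param events An [event_table()] with `FSC_A` and `SSC_A` (>= 1 event).
#' @return A tibble with columns `channel`, `mean`, `cv`, `cv_log`,
#'   `n_events`; the `heterogeneity_index` attribute holds the FSC `cv_log`.
#' @export
scatter_summary <- function(events) {
  check_channel(events, c("FSC_A", "SSC_A"))
  if (nrow(events) == 0L) {
    stop_magcyto("scatter_summary needs at least one event.",
                 "magcyto_sample_size_error")
  }
  cv <- function(x) if (mean(x) == 0) 0 else stats::sd(x) / mean(x)
  out <- purrr::map_dfr(c("FSC_A", "SSC_A"), function(ch) {
    x <- events[[ch]]
    tibble(channel = ch, mean = mean(x), cv = cv(x),
           cv_log = cv(log_display(x)), n_events = length(x))
  })
  attr(out, "heterogeneity_index") <- out$cv_log[out$channel == "FSC_A"]
  out
}
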