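#' Acquisition metadata for an event table
#'
#' Records how the events were acquired so that volumetric cell counting
#' ([events_to_concentration()]) is possible. Fields that are not known are
#' left `NA` (the documented sentinel) and listed in `assumed`; operations
#' that need them refuse sentinel values rather than guessing.
#'
#' @param flow_rate Sample flow rate in uL/min. The default 35 uL/min is the
#'   medium flow-rate setting assumed throughout the package; it is flagged as
#'   assumed unless supplied explicitly.
#' @param duration Acquisition duration in seconds (`NA` if unknown).
#' @param dilution_factor Dimensionless dilution applied before acquisition
#'   (>= 1).
#' @param n_events Number of events; filled in by [event_table()].
#' @param instrument_id Free-text instrument identifier.
#' @param assumed Character vector naming fields whose values are defaults
#'   rather than measurements.
#'
#' @return A list of class `acquisition_meta`.
#' @export
acquisition_meta <- function(flow_rate = 35, duration = NA_real_,
                             dilution_factor = 1, n_events = 0L,
                             instrument_id = "synthetic-cytometer",
                             assumed = character()) {
  if (missing(flow_rate)) assumed <- union(assumed, "flow_rate")
  if (is.na(duration)) assumed <- union(assumed, "duration")
  check_number(flow_rate, "flow_rate", 0, strict_min = TRUE)
  if (!is.na(duration)) check_number(duration, "duration", 0, strict_min = TRUE)
  check_number(dilution_factor, "dilution_factor", 1)
  structure(
    list(flow_rate = flow_rate, duration = duration,
         dilution_factor = dilution_factor, n_events = as.integer(n_events),
         instrument_id = instrument_id, assumed = assumed),
    class = "acquisition_meta"
  )
}

#' Build an event table
#'
#' The central container: one row per detected particle, one column per
#' detector channel, intensities on the *linear* instrument scale (arbitrary
#' units, non-negative, finite). An optional `true_label` character column
#' carries generating subpopulation labels for synthetic data.
#'
#' @param data A data frame of per-event channel intensities; channel columns
#'   must be numeric. `FSC_A` and `SSC_A` are required.
#' @param meta An [acquisition_meta()]; `n_events` is overwritten with the row
#'   count.
#'
#' @return A tibble of class `event_tbl` with the metadata attached as the
#'   `meta` attribute.
#' @export
#' @examples
#' event_table(data.frame(FSC_A = c(120, 95), SSC_A = c(40, 52)))
event_table <- function(data, meta = acquisition_meta()) {
  data <- as_tibble(data)
  check_channel(data, c("FSC_A", "SSC_A"))
  chans <- event_channels(data)
  for (ch in chans) {
    v <- data[[ch]]
    if (!is.numeric(v)) {
      stop_magcyto(sprintf("channel `%s` is not numeric.", ch),
                   "magcyto_validation_error")
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      stop_magcyto(
        sprintf("channel `%s` has negative or non-finite intensity at row %d.",
                ch, bad[[1L]]),
        "magcyto_validation_error"
      )
    }
  }
  if (!is.null(data[["true_label"]])) {
    data$true_label <- as.character(data$true_label)
  }
  meta$n_events <- nrow(data)
  structure(data, meta = meta,
            class = c("event_tbl", class(as_tibble(data))))
}

#' @rdname event_table
#' @param x An object to coerce or query.
#' @export
is_event_table <- function(x) inherits(x, "event_tbl")

#' Acquisition metadata accessor
#' @param events An `event_tbl`.
#' @return The `acquisition_meta` attached to the table (a permissive default
#'   if the table was built by hand).
#' @export
event_meta <- function(events) {
  attr(events, "meta") %||% acquisition_meta(n_events = nrow(events))
}

#' @export
print.event_tbl <- function(x, ...) {
  m <- event_meta(x)
  cat(sprintf("<event_tbl> %d events x %d channels (%s)\n",
              nrow(x), length(event_channels(x)),
              paste(event_channels(x), collapse = ", ")))
  if (length(m$assumed)) {
    cat("  assumed metadata:", paste(m$assumed, collapse = ", "), "\n")
  }
  NextMethod()
}
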