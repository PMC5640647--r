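## shared validation helpers; every user-facing error carries a subclass so
## callers (and tests) can distinguish failure modes.

stop_magcyto <- function(message, class) {
  abort(message, class = c(class, "magcyto_error"))
}

check_number <- function(x, name, min = -Inf, strict_min = FALSE,
                         class = "magcyto_param_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_magcyto(sprintf("`%s` must be a single finite number.", name), class)
  }
  bad <- if (strict_min) x <= min else x < min
  if (bad) {
    op <- if (strict_min) ">" else ">="
    stop_magcyto(sprintf("`%s` must be %s %g (got %g).", name, op, min, x), class)
  }
  invisible(x)
}

check_channel <- function(events, channel, class = "magcyto_channel_error") {
  missing <- setdiff(channel, names(events))
  if (length(missing)) {
    stop_magcyto(sprintf("required channel(s) missing from event table: %s",
                         paste(missing, collapse = ", ")), class)
  }
  invisible(events)
}

## columns of an event table that carry intensities (everything non-annotation)
event_channels <- function(events) {
  setdiff(names(events), c("true_label", "viability"))
}

seed_check <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_magcyto("`seed` must be a single finite integer.", "magcyto_param_error")
  }
  as.integer(seed)
}
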