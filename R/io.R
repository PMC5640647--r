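#' Read flow-cytometry events
#'
#' Reads an event table from either an FCS 3.0/3.1 file or the package's
#' annotated CSV dialect (a header row of channel names preceded by
#' `#key=value` metadata comment lines). Intensities are returned on the
#' linear scale regardless of source; FCS amplification keywords `$PnE` with a
#' log decade count are de-logged on read so the single-source-of-truth rule
#' (linear storage, log display only at use time) holds.
#'
#' Acquisition metadata missing from the file is filled with documented
#' sentinels (`NA` duration, 35 uL/min flow rate) and flagged in
#' `event_meta(x)$assumed`.
#'
#' @param path Path to the file.
#' @param format `"fcs"` or `"csv"`; default guesses from the file extension.
#'
#' @return An [event_table()].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_events(event_table(data.frame(FSC_A = 1:3, SSC_A = 4:6)), tf)
#' read_events(tf)
read_events <- function(path, format = c("auto", "csv", "fcs")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_magcyto(sprintf("file not found: %s", path), "magcyto_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  switch(format, csv = read_events_csv(path), fcs = read_events_fcs(path))
}

#' Write flow-cytometry events
#'
#' Writes an event table so that [read_events()] reproduces it (within float32
#' rounding for FCS; full double precision for CSV). FCS output is one fixed
#' dialect: FCS 3.1, single dataset, little-endian 32-bit float data segment,
#' `$PnE/0,0/` (linear). The CSV dialect stores acquisition metadata in
#' `#key=value` lines before the header and keeps the optional `true_label`
#' column verbatim; FCS has no per-event text field, so `true_label` is
#' dropped from FCS output with a warning.
#'
#' @param events An [event_table()].
#' @param path Output path.
#' @param format `"fcs"` or `"csv"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "csv", "fcs")) {
  format <- match.arg(format)
  if (!is_event_table(events)) events <- event_table(events)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  switch(format,
         csv = write_events_csv(events, path),
         fcs = write_events_fcs(events, path))
  invisible(path)
}

## ---- CSV dialect -----------------------------------------------------------

write_events_csv <- function(events, path) {
  m <- event_meta(events)
  hdr <- c(
    sprintf("#flow_rate=%s", format(m$flow_rate, digits = 15)),
    sprintf("#duration=%s", format(m$duration, digits = 15)),
    sprintf("#dilution_factor=%s", format(m$dilution_factor, digits = 15)),
    sprintf("#instrument_id=%s", m$instrument_id)
  )
  tryCatch({
    con <- file(path, "w")
    writeLines(hdr, con)
    close(con)
  }, error = function(e) {
    stop_magcyto(sprintf("cannot open `%s` for writing: %s",
                         path, conditionMessage(e)), "magcyto_io_error")
  })
  df <- as_tibble(unclass(events)[names(events)])
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
}

read_events_csv <- function(path) {
  lines <- readLines(path, n = 64L)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta_raw <- setNames(
    vapply(kv, function(p) paste(p[-1L], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1L)
  )
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) stop_magcyto(
      sprintf("cannot parse `%s` as CSV events: %s", path, conditionMessage(e)),
      "magcyto_io_error")
  )
  if (!all(c("FSC_A", "SSC_A") %in% names(df))) {
    stop_magcyto(
      "no recognisable channel header (need at least FSC_A and SSC_A).",
      "magcyto_format_error")
  }
  for (ch in setdiff(names(df), "true_label")) {
    if (!is.numeric(df[[ch]])) df[[ch]] <- as.numeric(df[[ch]])
  }
  num <- function(key) {
    if (!key %in% names(meta_raw)) return(NA_real_)
    suppressWarnings(as.numeric(meta_raw[[key]]))
  }
  assumed <- character()
  fr <- num("flow_rate"); if (is.na(fr)) { fr <- 35; assumed <- c(assumed, "flow_rate") }
  du <- num("duration"); if (is.na(du)) assumed <- c(assumed, "duration")
  di <- num("dilution_factor"); if (is.na(di)) { di <- 1; assumed <- c(assumed, "dilution_factor") }
  instrument <- if ("instrument_id" %in% names(meta_raw)) {
    meta_raw[["instrument_id"]]
  } else "unknown"
  meta <- acquisition_meta(flow_rate = fr, duration = du, dilution_factor = di,
                           instrument_id = instrument, assumed = assumed)
  event_table(df, meta)
}

## ---- FCS 3.0/3.1 -----------------------------------------------------------
## Minimal but standard-conforming: writer emits FCS3.1 / $DATATYPE F /
## $BYTEORD 1,2,3,4 / $MODE L; reader additionally accepts FCS3.0, datatype
## D and I (16/32-bit), and big-endian byte order.

write_events_fcs <- function(events, path) {
  if (!is.null(events[["true_label"]])) {
    warn("FCS output has no per-event text field; dropping `true_label`.")
  }
  chans <- event_channels(events)
  mat <- as.matrix(as_tibble(unclass(events)[chans]))
  if (nrow(mat) == 0L) mat <- matrix(numeric(), 0L, length(chans))
  n <- nrow(mat); p <- ncol(mat)
  m <- event_meta(events)
  kw <- c(
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$PAR" = as.character(p), "$TOT" = as.character(n),
    "MAGCYTO_FLOWRATE" = format(m$flow_rate, digits = 15),
    "MAGCYTO_DURATION" = format(m$duration, digits = 15),
    "MAGCYTO_DILUTION" = format(m$dilution_factor, digits = 15),
    "$CYT" = m$instrument_id
  )
  for (i in seq_len(p)) {
    kw[sprintf("$P%dN", i)] <- chans[[i]]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(max(262144, ceiling(max(mat[, i], 0, na.rm = TRUE))),
                                      scientific = FALSE)
  }
  ## data offsets are fixed-width so the TEXT length is known up front
  kw <- c("$BEGINDATA" = "00000000", "$ENDDATA" = "00000000", kw)
  text_of <- function(kw) {
    paste0("/", paste0(names(kw), "/", kw, "/", collapse = ""))
  }
  text_start <- 58L
  text_len <- nchar(text_of(kw), type = "bytes")
  data_start <- text_start + text_len
  data_end <- if (n * p > 0) data_start + 4L * n * p - 1L else 0L
  kw[["$BEGINDATA"]] <- sprintf("%08d", if (n * p > 0) data_start else 0L)
  kw[["$ENDDATA"]] <- sprintf("%08d", data_end)
  txt <- text_of(kw)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_start + text_len - 1L,
                    if (n * p > 0) data_start else 0L, data_end, 0L, 0L)
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop_magcyto(sprintf("cannot open `%s` for writing: %s",
                         path, conditionMessage(e)), "magcyto_io_error")
  })
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  if (n * p > 0) {
    writeBin(as.vector(t(mat)), con, size = 4L, endian = "little")
  }
}

read_events_fcs <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 58L || !identical(rawToChar(raw[1:3]), "FCS")) {
    stop_magcyto(sprintf("`%s` is not an FCS file.", path), "magcyto_format_error")
  }
  version <- trimws(rawToChar(raw[1:6]))
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop_magcyto(sprintf("unsupported FCS version `%s`.", version),
                 "magcyto_format_error")
  }
  off <- function(a, b) as.integer(trimws(rawToChar(raw[a:b])))
  ts <- off(11L, 18L); te <- off(19L, 26L)
  ds <- off(27L, 34L); de <- off(35L, 42L)
  txt <- rawToChar(raw[(ts + 1L):(te + 1L)])
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- c(parts, "")
  kw <- setNames(parts[seq(2L, length(parts), 2L)],
                 toupper(parts[seq(1L, length(parts), 2L)]))
  p <- as.integer(kw[["$PAR"]]); n <- as.integer(kw[["$TOT"]])
  if (ds == 0L && !is.null(kw[["$BEGINDATA"]])) {
    ds <- as.integer(kw[["$BEGINDATA"]]); de <- as.integer(kw[["$ENDDATA"]])
  }
  dtype <- toupper(kw[["$DATATYPE"]] %||% "F")
  byteord <- kw[["$BYTEORD"]] %||% "1,2,3,4"
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  chans <- vapply(seq_len(p), function(i) {
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i)
  }, character(1))
  nvals <- n * p
  vals <- if (nvals == 0L) numeric() else {
    con <- rawConnection(raw[(ds + 1L):(de + 1L)])
    on.exit(close(con))
    switch(dtype,
      F = readBin(con, "numeric", n = nvals, size = 4L, endian = endian),
      D = readBin(con, "numeric", n = nvals, size = 8L, endian = endian),
      I = {
        bits <- as.integer(kw[[sprintf("$P%dB", 1L)]] %||% "32")
        readBin(con, "integer", n = nvals, size = bits %/% 8L,
                signed = bits > 16L, endian = endian)
      },
      stop_magcyto(sprintf("unsupported $DATATYPE `%s`.", dtype),
                   "magcyto_format_error")
    )
  }
  if (length(vals) != nvals) {
    stop_magcyto(sprintf(
      "FCS data segment truncated: expected %d values, read %d.",
      nvals, length(vals)), "magcyto_format_error")
  }
  mat <- matrix(as.numeric(vals), nrow = n, ncol = p, byrow = TRUE,
                dimnames = list(NULL, chans))
  ## de-log amplified channels so stored intensities are linear
  for (i in seq_len(p)) {
    pe <- kw[[sprintf("$P%dE", i)]]
    if (!is.null(pe)) {
      dec <- suppressWarnings(as.numeric(strsplit(pe, ",")[[1L]][1L]))
      if (isTRUE(dec > 0)) {
        rng <- as.numeric(kw[[sprintf("$P%dR", i)]] %||% "1024")
        mat[, i] <- 10^(dec * mat[, i] / rng)
      }
    }
  }
  num <- function(key) suppressWarnings(as.numeric(kw[[key]] %||% NA_real_))
  assumed <- character()
  fr <- num("MAGCYTO_FLOWRATE"); if (is.na(fr)) { fr <- 35; assumed <- c(assumed, "flow_rate") }
  du <- num("MAGCYTO_DURATION"); if (is.na(du)) assumed <- c(assumed, "duration")
  di <- num("MAGCYTO_DILUTION"); if (is.na(di)) { di <- 1; assumed <- c(assumed, "dilution_factor") }
  meta <- acquisition_meta(flow_rate = fr, duration = du, dilution_factor = di,
                           instrument_id = kw[["$CYT"]] %||% "unknown",
                           assumed = assumed)
  event_table(as_tibble(mat), meta)
}
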