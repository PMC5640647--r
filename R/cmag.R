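#' Read paired optical-density readings
#'
#' Magneto-spectrophotometry records the OD565 of a cell suspension twice:
#' with the Helmholtz-coil field in line with the light beam
#' (`od_parallel`) and perpendicular to it (`od_perpendicular`). CSV columns:
#' `sample_id`, `od_parallel`, `od_perpendicular`.
#'
#' @param path CSV file path.
#' @return A tibble of readings, validated (both ODs > 0).
#' @export
read_od_pairs <- function(path) {
  if (!file.exists(path)) {
    stop_magcyto(sprintf("file not found: %s", path), "magcyto_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "od_parallel", "od_perpendicular")
  if (!all(need %in% names(df))) {
    stop_magcyto(sprintf("OD-pair CSV needs columns %s.",
                         paste(need, collapse = ", ")), "magcyto_format_error")
  }
  validate_od_pairs(df)
  df
}

validate_od_pairs <- function(readings) {
  for (col in c("od_parallel", "od_perpendicular")) {
    v <- readings[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop_magcyto(sprintf("`%s` must be strictly positive and finite.", col),
                   "magcyto_validation_error")
    }
  }
  invisible(readings)
}

#' Scalar C_mag ratio
#'
#' @param od_parallel,od_perpendicular Positive OD565 readings (vectorised).
#' @return `od_parallel / od_perpendicular`. Magnetic cells realign between
#'   the two field orientations and change the suspension's optical density,
#'   so values above 1 indicate magnetic cells; non-magnetic suspensions give
#'   exactly 1 up to noise. Scale-invariant: both ODs may be multiplied by
#'   any common positive factor.
#' @export
#' @examples
#' cmag_ratio(0.50, 0.25)  # strongly magnetic
#' cmag_ratio(0.44, 0.40)  # weakly magnetic
cmag_ratio <- function(od_parallel, od_perpendicular) {
  if (any(!is.finite(od_parallel)) || any(od_parallel <= 0) ||
      any(!is.finite(od_perpendicular)) || any(od_perpendicular <= 0)) {
    stop_magcyto("OD readings must be strictly positive and finite.",
                 "magcyto_validation_error")
  }
  od_parallel / od_perpendicular
}

#' Compute C_mag for a table of paired OD readings
#'
#' @param readings Data frame with columns `od_parallel` and
#'   `od_perpendicular` (e.g. from [read_od_pairs()] or
#'   [generate_od_pairs()]).
#' @param tol Tolerance above unity for the magnetic call (see
#'   [classify_magnetic()]).
#' @return The input tibble with `cmag` and `magnetic` columns appended.
#' @export
#' @examples
#' compute_cmag(tibble::tibble(sample_id = "a", od_parallel = 0.5,
#'                             od_perpendicular = 0.25))
compute_cmag <- function(readings, tol = 0.05) {
  if (!is.data.frame(readings) ||
      !all(c("od_parallel", "od_perpendicular") %in% names(readings))) {
    stop_magcyto("`readings` needs columns od_parallel and od_perpendicular.",
                 "magcyto_param_error")
  }
  validate_od_pairs(readings)
  readings <- as_tibble(readings)
  readings$cmag <- cmag_ratio(readings$od_parallel, readings$od_perpendicular)
  readings$magnetic <- classify_magnetic(readings$cmag, tol = tol)
  readings
}

#' Call a culture magnetic or non-magnetic from its C_mag
#'
#' A culture is called `magnetic` when `cmag > 1 + tol`. The default
#' tolerance 0.05 absorbs instrument noise while still calling the weakly
#' magnetic value 1.1.
#'
#' @param cmag C_mag value(s), each > 0.
#' @param tol Non-negative tolerance above unity.
#' @return `"magnetic"` or `"non_magnetic"` per value.
#' @export
#' @examples
#' classify_magnetic(c(2.0, 1.04, 1.0))
classify_magnetic <- function(cmag, tol = 0.05) {
  if (any(!is.finite(cmag)) || any(cmag <= 0)) {
    stop_magcyto("`cmag` must be positive and finite.",
                 "magcyto_validation_error")
  }
  check_number(tol, "tol", 0)
  ifelse(cmag > 1 + tol, "magnetic", "non_magnetic")
}
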