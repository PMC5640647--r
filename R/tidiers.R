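#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a mixture fit into one row per component
#'
#' @param x A `mixture_fit` from [fit_subpopulations()].
#' @param ... Unused.
#' @return A tibble with columns `component`, `weight`, `mean`, `sd`
#'   (means/sds in log10 units).
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(component = seq_len(x$k), weight = x$weights,
         mean = x$means, sd = x$sds)
}

#' One-row model summary of a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return A tibble with `k`, `loglik`, `bic_k1`, `bic_k2`, `converged`,
#'   `n`, `channel`.
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik,
         bic_k1 = unname(x$bic[["1"]]),
         bic_k2 = unname(x$bic["2"]),
         converged = x$converged, n = x$n, channel = x$channel)
}

#' Tidy a count calibration
#'
#' @param x A `count_calibration`.
#' @param ... Unused.
#' @return One row: `term` (`"slope"`), `estimate`, `mode`.
#' @export
tidy.count_calibration <- function(x, ...) {
  tibble(term = "slope", estimate = x$slope, mode = x$mode)
}

#' One-row fit summary of a count calibration
#'
#' @param x A `count_calibration`.
#' @param ... Unused.
#' @return A tibble with `slope`, `r2`, `n_points`, `mode`, `provenance`.
#' @export
glance.count_calibration <- function(x, ...) {
  tibble(slope = x$slope, r2 = x$r2, n_points = x$n_points, mode = x$mode,
         provenance = x$provenance)
}

#' Tidy viability fractions
#'
#' @param x A `viability_fractions` from [classify_viability()].
#' @param ... Unused.
#' @return The `fractions` tibble (`state`, `fraction`) with `n_events`
#'   attached as a column.
#' @export
tidy.viability_fractions <- function(x, ...) {
  dplyr::mutate(x$fractions, n_events = x$n_events)
}
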