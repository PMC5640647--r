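## packaged config registries (scenarios, conditions, calibrations) live as
## YAML under inst/extdata so they are human-editable and diffable.

registry_path <- function(file) {
  p <- system.file("extdata", file, package = "magcyto")
  if (!nzchar(p)) {
    stop_magcyto(sprintf("packaged registry `%s` not found.", file),
                 "magcyto_io_error")
  }
  p
}

read_registry <- function(file, top) {
  yaml::read_yaml(registry_path(file))[[top]]
}

#' List packaged synthetic scenarios
#'
#' @return A tibble with columns `scenario` and `description`.
#' @export
#' @examples
#' list_scenarios()
list_scenarios <- function() {
  reg <- read_registry("scenarios.yaml", "scenarios")
  tibble(scenario = names(reg),
         description = vapply(reg, function(s) trimws(s$description %||% ""),
                              character(1)))
}

#' Load a packaged scenario as a scenario_spec
#'
#' The registry encodes the reference acquisitions the analyses are validated
#' against: growing / starving / ethanol-killed BOX-PI viability mixtures,
#' liquid- vs plate-grown scatter phenotypes, one- vs two-population PHA
#' stains, the iron-free PG-SK reference, and a Syto62 cells-plus-debris
#' suspension. Fractions and channel locations are fixed registry values;
#' only `n_events` and `seed` are chosen per draw.
#'
#' @param name Scenario name from [list_scenarios()].
#' @param n_events Events to draw (default 25000, the standard per-sample
#'   acquisition depth used throughout).
#' @param seed Integer seed.
#' @return A [scenario_spec()].
#' @export
#' @examples
#' gm <- load_scenario("growing_magnetic", n_events = 1000, seed = 11)
#' generate_scenario(gm)
load_scenario <- function(name, n_events = 25000L, seed = 1L) {
  reg <- read_registry("scenarios.yaml", "scenarios")
  entry <- reg[[name]]
  if (is.null(entry)) {
    stop_magcyto(sprintf("unknown scenario `%s`; see list_scenarios().", name),
                 "magcyto_param_error")
  }
  scenario_from_entry(name, entry, n_events, seed)
}

scenario_from_entry <- function(name, entry, n_events, seed) {
  pops <- purrr::map(entry$populations, function(p) {
    population_spec(p$label, p$fraction,
                    purrr::map(p$channels, as.numeric),
                    iron_um = p$iron_um)
  })
  st <- entry$stain %||% list()
  scenario_spec(
    scenario_id = name,
    populations = pops,
    n_events = n_events,
    seed = seed,
    stain = stain_spec(dye = st$dye %||% "NONE",
                       concentration = st$concentration %||% 0,
                       unit = st$unit %||% "ug/mL",
                       staining_time = st$staining_time %||% 0,
                       temperature = st$temperature %||% 30)
  )
}

#' List packaged culture conditions and condition sets
#'
#' @return A tibble with one row per condition: `condition_id`, `set`,
#'   `description`, `od565` and the noiseless C_mag implied by its generator
#'   parameters.
#' @export
list_conditions <- function() {
  reg <- yaml::read_yaml(registry_path("conditions.yaml"))
  sets <- purrr::imap_dfr(reg$sets, ~ tibble(condition_id = .x, set = .y))
  info <- purrr::imap_dfr(reg$conditions, function(cn, id) {
    tibble(condition_id = id,
           description = trimws(cn$description %||% ""),
           od565 = cn$od565,
           cmag_true = 1 + cn$cmag$alignment_contrast * cn$cmag$magnetic_fraction)
  })
  dplyr::left_join(sets, info, by = "condition_id")
}

condition_entry <- function(condition_id) {
  reg <- yaml::read_yaml(registry_path("conditions.yaml"))$conditions
  entry <- reg[[condition_id]]
  if (is.null(entry)) {
    stop_magcyto(sprintf("unknown condition `%s`; see list_conditions().",
                         condition_id), "magcyto_param_error")
  }
  entry
}

## scatter template shared by all liquid-culture condition scenarios
.liquid_scatter <- list(FSC_A = c(2.0, 0.15), SSC_A = c(1.8, 0.15))

#' Build the stained-sample scenarios for a packaged condition
#'
#' Each condition in the registry expands into three synthetic acquisitions:
#' a BOX/PI viability co-stain (quadrant fractions from the registry), a
#' Pyr-546 PHA stain and a PG-SK iron stain (single populations whose FL1
#' location is the registry's `pyr546_mu` / `pgsk_mu`).
#'
#' @param condition_id Condition name from [list_conditions()].
#' @param n_events Events per acquisition.
#' @param seed Integer seed; the three acquisitions use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return A named list of [scenario_spec()]s: `viability`, `pyr546`, `pgsk`.
#' @export
condition_scenarios <- function(condition_id, n_events = 25000L, seed = 1L) {
  entry <- condition_entry(condition_id)
  seed <- seed_check(seed)
  vf <- entry$viability
  quadrant_channels <- function(fl1_pos, fl3_pos) {
    c(.liquid_scatter,
      list(FL1_A = if (fl1_pos) c(3.2, 0.30) else c(1.0, 0.25),
           FL3_A = if (fl3_pos) c(3.2, 0.30) else c(1.0, 0.25)))
  }
  viability <- scenario_spec(
    paste0(condition_id, "_viability"),
    list(
      population_spec("healthy", vf$healthy, quadrant_channels(FALSE, FALSE)),
      population_spec("injured", vf$injured, quadrant_channels(TRUE, FALSE)),
      population_spec("dead", vf$dead, quadrant_channels(TRUE, TRUE)),
      population_spec("anomalous", vf$anomalous, quadrant_channels(FALSE, TRUE))
    ),
    n_events = n_events, seed = seed,
    stain = stain_spec("BOX", 10, "ug/mL", 600)
  )
  single <- function(suffix, label, mu, stain) {
    scenario_spec(
      paste0(condition_id, "_", suffix),
      list(population_spec(label, 1,
                           c(.liquid_scatter, list(FL1_A = c(mu, 0.25))))),
      n_events = n_events,
      seed = seed + switch(suffix, pyr546 = 1L, pgsk = 2L),
      stain = stain
    )
  }
  list(
    viability = viability,
    pyr546 = single("pyr546", "high_pha", entry$pyr546_mu,
                    stain_spec("PYR546", 0.5, "ug/mL", 70)),
    pgsk = single("pgsk", "pgsk_stained", entry$pgsk_mu,
                  stain_spec("PGSK", 5, "uM", 600))
  )
}

#' Packaged and custom OD-to-concentration calibrations
#'
#' Returns one of the calibration constants shipped with the package:
#' `"fcm_unstained"` (1 OD565 = 1.16e9 cells/mL, volumetric cytometric count
#' of unstained events), `"fcm_syto62"` (1.03e9 cells/mL with the DNA-dye
#' noise gate) or `"cfu"` (3.3e8 CFU/mL by plate counting, lower because
#' viable-but-non-culturable cells form no colonies). Packaged constants have
#' `n_points = 0` and carry their provenance string.
#'
#' @param name Calibration name.
#' @return A `count_calibration` object (see [fit_count_calibration()]).
#' @export
#' @examples
#' load_calibration("fcm_unstained")
load_calibration <- function(name = c("fcm_unstained", "fcm_syto62", "cfu")) {
  name <- match.arg(name)
  entry <- read_registry("calibrations.yaml", "calibrations")[[name]]
  new_count_calibration(
    mode = entry$mode, slope = entry$slope,
    r2 = entry$r2 %||% NA_real_, n_points = entry$n_points %||% 0L,
    provenance = trimws(entry$provenance %||% name)
  )
}
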