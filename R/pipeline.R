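#' Run the full per-sample analysis
#'
#' Composes the whole battery for one culture condition: read events, apply
#' the noise gate, place quadrant thresholds from the dye-negative control,
#' classify viability, summarise scatter and stain fluorescence, convert
#' OD565 to a calibrated cell concentration, and compute C_mag from the
#' paired OD readings. Fully deterministic given the input files and config.
#'
#' @param events_path Path to the BOX/PI-stained event file (CSV or FCS).
#' @param od_pairs_path Optional path to a CSV of paired parallel /
#'   perpendicular OD565 readings.
#' @param config A named list or YAML file path. Recognised keys:
#'   `condition_id`; `control_events` (path, required — dye-negative control
#'   for thresholds); `pyr546_events`, `pgsk_events`,
#'   `pgsk_reference_events` (paths, optional); `od565` (number);
#'   `threshold_percentile` (default 99.5); `noise_gate` (list with `mode`,
#'   `cut`; default scatter gate at 0, i.e. pass-through); `calibration`
#'   (packaged name, default `"fcm_unstained"`); `quench` (list `f0`,
#'   `K_sv` for the iron estimate); `cmag_tol` (default 0.05).
#' @return A list of class `condition_report`: `condition_id`, `od565`,
#'   `concentration`, `cmag`, `viability`, `scatter`, `pha`, `iron`,
#'   `provenance`, `flags`. Serialise with [write_report()].
#' @export
run_sample <- function(events_path, od_pairs_path = NULL, config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(
    list(condition_id = "sample", threshold_percentile = 99.5,
         noise_gate = list(mode = "scatter", cut = 0),
         calibration = "fcm_unstained", cmag_tol = 0.05,
         quench = list(f0 = 2000, K_sv = 0.1)),
    config)
  if (is.null(cfg$control_events)) {
    stop_magcyto("config must name `control_events` (dye-negative control for thresholds).",
                 "magcyto_config_error")
  }
  flags <- character()
  stage <- function(name, expr) {
    tryCatch(expr, magcyto_error = function(e) {
      stop_magcyto(sprintf("[stage %s] %s", name, conditionMessage(e)),
                   class(e)[[1L]])
    })
  }
  gate <- function(ev) {
    noise_gate(ev, mode = cfg$noise_gate$mode, cut = cfg$noise_gate$cut)
  }

  events <- stage("read_events", read_events(events_path))
  events <- stage("noise_gate", gate(events))
  control <- stage("read_control", read_events(cfg$control_events))
  thresholds <- stage("estimate_thresholds",
                      estimate_thresholds(control, cfg$threshold_percentile,
                                          control_id = basename(cfg$control_events)))
  viability <- withCallingHandlers(
    stage("classify_viability", classify_viability(events, thresholds)),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  scatter <- if (nrow(events)) {
    stage("scatter_summary", scatter_summary(events))
  } else {
    flags <- c(flags, "no events after gating: scatter summary skipped")
    NULL
  }

  summarise_file <- function(path, name) {
    if (is.null(path)) return(NULL)
    ev <- stage(paste0("read_", name), gate(read_events(path)))
    if (nrow(ev) == 0L) {
      flags <<- c(flags, sprintf("%s: no events after gating", name))
      return(NULL)
    }
    stage(paste0("summarize_", name), summarize_fluorescence(ev, "FL1_A"))
  }
  pha <- summarise_file(cfg$pyr546_events, "pyr546")
  pgsk <- summarise_file(cfg$pgsk_events, "pgsk")
  pgsk_ref <- summarise_file(cfg$pgsk_reference_events, "pgsk_reference")
  iron <- if (!is.null(pgsk) && !is.null(pgsk_ref)) {
    qm <- quench_model(f0 = cfg$quench$f0, K_sv = cfg$quench$K_sv)
    stage("iron_index", iron_index(pgsk, pgsk_ref, qm))
  } else NULL

  concentration <- if (!is.null(cfg$od565)) {
    cal <- stage("calibration", load_calibration(cfg$calibration))
    stage("od_to_concentration", od_to_concentration(cfg$od565, cal))
  } else NULL

  cmag <- if (!is.null(od_pairs_path)) {
    pairs <- stage("read_od_pairs", read_od_pairs(od_pairs_path))
    cc <- stage("compute_cmag", compute_cmag(pairs, tol = cfg$cmag_tol))
    tibble(cmag_mean = mean(cc$cmag),
           cmag_sd = if (nrow(cc) > 1L) stats::sd(cc$cmag) else 0,
           n_pairs = nrow(cc),
           magnetic = classify_magnetic(mean(cc$cmag), tol = cfg$cmag_tol))
  } else NULL

  structure(
    list(
      condition_id = cfg$condition_id,
      od565 = cfg$od565,
      concentration = concentration,
      cmag = cmag,
      viability = viability,
      scatter = scatter,
      pha = pha,
      iron = if (!is.null(iron)) list(summary = pgsk, index = iron) else
        list(summary = pgsk, index = NULL),
      provenance = list(
        events = events_path, od_pairs = od_pairs_path,
        control = cfg$control_events,
        pyr546 = cfg$pyr546_events, pgsk = cfg$pgsk_events,
        pgsk_reference = cfg$pgsk_reference_events,
        thresholds = list(fl1_cut = thresholds$fl1_cut,
                          fl3_cut = thresholds$fl3_cut,
                          percentile = cfg$threshold_percentile),
        noise_gate = cfg$noise_gate,
        retained_fraction = attr(events, "retained_fraction"),
        calibration = cfg$calibration,
        report_schema = "magcyto-report/1"
      ),
      flags = flags
    ),
    class = "condition_report"
  )
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report> %s (schema %s)\n", x$condition_id,
              x$provenance$report_schema))
  if (!is.null(x$od565)) cat(sprintf("  OD565: %.3g\n", x$od565))
  if (!is.null(x$cmag)) {
    cat(sprintf("  C_mag: %.3f +/- %.3f (%s)\n", x$cmag$cmag_mean,
                x$cmag$cmag_sd, x$cmag$magnetic))
  }
  if (!is.null(x$viability)) {
    f <- setNames(x$viability$fractions$fraction, x$viability$fractions$state)
    cat(sprintf("  viability: %.1f%% healthy / %.1f%% injured / %.1f%% dead / %.1f%% anomalous\n",
                100 * f[["healthy"]], 100 * f[["injured"]], 100 * f[["dead"]],
                100 * f[["anomalous"]]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Serialise a condition report to JSON
#'
#' Writing the same report twice produces byte-identical files, so report
#' determinism can be checked end to end.
#'
#' @param report A `condition_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- report_payload(report)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

report_payload <- function(report) {
  vi <- report$viability
  list(
    schema = report$provenance$report_schema,
    condition_id = report$condition_id,
    od565 = report$od565,
    concentration = report$concentration,
    cmag = report$cmag,
    viability = if (!is.null(vi)) list(
      fractions = vi$fractions, n_events = vi$n_events,
      thresholds = list(fl1_cut = vi$thresholds$fl1_cut,
                        fl3_cut = vi$thresholds$fl3_cut)),
    scatter = report$scatter,
    pha = report$pha,
    iron = report$iron,
    provenance = report$provenance,
    flags = as.list(report$flags)
  )
}

#' Long-format comparison of condition reports
#'
#' Assembles per-condition metrics into one long table —
#' `(condition, metric, value, dispersion)` — covering OD565, C_mag,
#' viability fractions, Pyr-546 and PG-SK MFI, the iron index and scatter
#' summaries. Conditions keep the order they were given in.
#'
#' @param reports List of `condition_report`s (>= 2, distinct
#'   `condition_id`s).
#' @return A tibble with columns `condition`, `metric`, `value`,
#'   `dispersion`.
#' @export
compare_conditions <- function(reports) {
  if (length(reports) < 2L) {
    stop_magcyto("need at least 2 reports to compare.", "magcyto_param_error")
  }
  ids <- vapply(reports, `[[`, character(1), "condition_id")
  if (anyDuplicated(ids)) {
    stop_magcyto(sprintf("duplicate condition_id: %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 "magcyto_validation_error")
  }
  one <- function(r) {
    rows <- list(tibble(metric = character(), value = numeric(),
                        dispersion = numeric()))
    add <- function(metric, value, dispersion = NA_real_) {
      rows[[length(rows) + 1L]] <<- tibble(metric = metric,
                                           value = as.numeric(value),
                                           dispersion = as.numeric(dispersion))
    }
    if (!is.null(r$od565)) add("od565", r$od565)
    if (!is.null(r$cmag)) add("cmag", r$cmag$cmag_mean, r$cmag$cmag_sd)
    if (!is.null(r$viability) && !isTRUE(r$viability$empty)) {
      f <- r$viability$fractions
      for (i in seq_len(nrow(f))) {
        add(paste0("viability_", f$state[[i]]), f$fraction[[i]])
      }
    }
    if (!is.null(r$pha)) add("pyr546_mfi", r$pha$mfi, r$pha$cv)
    if (!is.null(r$iron$summary)) {
      add("pgsk_mfi", r$iron$summary$mfi, r$iron$summary$cv)
    }
    if (!is.null(r$iron$index)) {
      add("iron_fold_quench", r$iron$index$fold_quench)
      add("iron_um", r$iron$index$iron_um)
    }
    if (!is.null(r$scatter)) {
      for (i in seq_len(nrow(r$scatter))) {
        add(paste0(tolower(sub("_A$", "", r$scatter$channel[[i]])), "_mean"),
            r$scatter$mean[[i]], r$scatter$cv[[i]])
      }
    }
    dplyr::bind_rows(rows)
  }
  out <- purrr::map2_dfr(reports, ids, function(r, id) {
    dplyr::mutate(one(r), condition = id, .before = 1L)
  })
  out$condition <- factor(out$condition, levels = ids)
  out
}

#' Generate packaged fixtures and run one condition end to end
#'
#' Expands a packaged condition into its three stained acquisitions (plus the
#' shared unstained control and the iron-free PG-SK reference), writes them
#' as annotated CSVs together with paired OD readings, and runs
#' [run_sample()] on the result. This is the one-call route from the
#' condition registry to a `condition_report`.
#'
#' @param condition_id Condition from [list_conditions()].
#' @param dir Directory for the generated fixture files.
#' @param n_events Events per acquisition.
#' @param n_pairs OD reading pairs (triplicate by default).
#' @param seed Integer seed for every random draw in the condition.
#' @return A `condition_report`.
#' @export
run_condition <- function(condition_id, dir = tempfile("magcyto_"),
                          n_events = 25000L, n_pairs = 3L, seed = 1L) {
  entry <- condition_entry(condition_id)
  seed <- seed_check(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scns <- condition_scenarios(condition_id, n_events = n_events, seed = seed)
  paths <- purrr::imap(scns, function(s, nm) {
    p <- file.path(dir, paste0(condition_id, "_", nm, ".csv"))
    write_events(generate_scenario(s), p)
    p
  })
  control_path <- file.path(dir, "unstained_control.csv")
  write_events(
    generate_scenario(load_scenario("unstained_control", n_events, seed = seed + 10L)),
    control_path)
  ref_path <- file.path(dir, "pgsk_reference.csv")
  write_events(
    generate_scenario(load_scenario("pgsk_reference", n_events, seed = seed + 11L)),
    ref_path)
  od_path <- file.path(dir, paste0(condition_id, "_od_pairs.csv"))
  readr::write_csv(
    generate_od_pairs(od_base = entry$od565,
                      magnetic_fraction = entry$cmag$magnetic_fraction,
                      alignment_contrast = entry$cmag$alignment_contrast,
                      noise_cv = entry$cmag$noise_cv,
                      n = n_pairs, seed = seed + 12L),
    od_path, progress = FALSE)
  run_sample(
    events_path = paths$viability, od_pairs_path = od_path,
    config = list(condition_id = condition_id, od565 = entry$od565,
                  control_events = control_path,
                  pyr546_events = paths$pyr546, pgsk_events = paths$pgsk,
                  pgsk_reference_events = ref_path))
}

#' Run a packaged condition set and compare it
#'
#' @param set `"headspace"` or `"medium_shift"` (see [list_conditions()]).
#' @param dir Directory for generated fixtures.
#' @param n_events Events per acquisition.
#' @param seed Base seed; condition `i` uses `seed + 100 * i`.
#' @return A list with `reports` (named list of `condition_report`s) and
#'   `comparison` (the [compare_conditions()] table).
#' @export
run_condition_set <- function(set = c("headspace", "medium_shift"),
                              dir = tempfile("magcyto_"), n_events = 25000L,
                              seed = 1L) {
  set <- match.arg(set)
  ids <- yaml::read_yaml(registry_path("conditions.yaml"))$sets[[set]]
  seed <- seed_check(seed)
  reports <- purrr::imap(setNames(ids, ids), function(id, nm) {
    run_condition(id, dir = file.path(dir, id), n_events = n_events,
                  seed = seed + 100L * match(id, ids))
  })
  list(reports = reports, comparison = compare_conditions(unname(reports)))
}
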