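# fluorescence summaries, mixture fits, iron index and calibrations

test_that("summarize_fluorescence: hand values, invariances, closed form", {
  mk <- function(x) event_table(data.frame(FSC_A = seq_along(x),
                                           SSC_A = seq_along(x), FL1_A = x))
  s1 <- summarize_fluorescence(mk(c(100, 100, 100)), "FL1_A")
  expect_identical(s1$mfi, 100)
  expect_identical(s1$cv, 0)

  s2 <- summarize_fluorescence(mk(c(50, 150)), "FL1_A")
  expect_identical(s2$mfi, 100)
  expect_equal(s2$cv, 70.71068 / 100, tolerance = 1e-6)  # sample sd, n-1

  # permutation invariance; mfi scales linearly, cv is scale-invariant
  x <- stats::runif(500, 10, 1000)
  a <- summarize_fluorescence(mk(x), "FL1_A")
  b <- summarize_fluorescence(mk(sample(x)), "FL1_A")
  d <- summarize_fluorescence(mk(3.7 * x), "FL1_A")
  expect_equal(a$mfi, b$mfi); expect_equal(a$cv, b$cv)
  expect_equal(d$mfi, 3.7 * a$mfi, tolerance = 1e-12)
  expect_equal(d$cv, a$cv, tolerance = 1e-12)

  # log-normal mean closed form: 10^mu * exp((sigma ln10)^2 / 2)
  pop <- population_spec("x", 1, list(FSC_A = c(2, 0.1), SSC_A = c(2, 0.1),
                                      FL1_A = c(2, 0.2)))
  ev <- sample_population(pop, 1e5, seed = 11)
  mfi_expect <- 10^2 * exp((0.2 * log(10))^2 / 2)
  expect_equal(summarize_fluorescence(ev, "FL1_A")$mfi, mfi_expect,
               tolerance = 0.02)

  expect_error(summarize_fluorescence(mk(numeric()), "FL1_A"),
               class = "magcyto_sample_size_error")
})

test_that("mixture fit selects k and recovers generating parameters", {
  # single log-normal population -> k = 1
  one <- sample_population(
    population_spec("x", 1, list(FSC_A = c(2, .2), SSC_A = c(2, .2),
                                 FL1_A = c(2.5, 0.25))), 5000, seed = 13)
  expect_identical(fit_subpopulations(one, "FL1_A")$k, 1L)

  # 40/60 mixture at log10 means 1.5 / 3.5 (sd 0.2), n = 25000
  scn <- load_scenario("magnetic_pha", 25000, seed = 17)
  ev <- generate_scenario(scn)
  fit <- fit_subpopulations(ev, "FL1_A")
  expect_identical(fit$k, 2L)
  expect_lt(max(abs(fit$weights - c(0.40, 0.60))), 0.03)
  expect_lt(max(abs(fit$means - c(1.5, 3.5))), 0.05)
  expect_true(all(diff(fit$means) > 0))  # ordered components
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)

  # packaged one-population PHA scenario -> k = 1
  nm <- generate_scenario(load_scenario("nonmagnetic_pha", 25000, seed = 19))
  expect_identical(fit_subpopulations(nm, "FL1_A")$k, 1L)

  expect_error(fit_subpopulations(one[1:100, ], "FL1_A"),
               class = "magcyto_sample_size_error")
})

test_that("forced-k recovery holds across 20 seeds with at most one failure", {
  fails <- 0L
  for (s in 1:20) {
    ev <- generate_scenario(load_scenario("magnetic_pha", 25000, seed = s))
    fit <- fit_subpopulations(ev, "FL1_A", k = 2, seed = s)
    ok <- max(abs(fit$weights - c(0.4, 0.6))) <= 0.03 &&
      max(abs(fit$means - c(1.5, 3.5))) <= 0.05
    if (!ok) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("mixture EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  ev <- generate_scenario(load_scenario("magnetic_pha", 10000, seed = 23))
  fit <- fit_subpopulations(ev, "FL1_A", k = 2)
  x <- log_display(ev$FL1_A)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(sort(fit$weights), sort(as.numeric(mc$parameters$pro)),
               tolerance = 0.02)
})

test_that("iron index inverts the quench model", {
  qm <- quench_model(f0 = 1000, K_sv = 0.1)
  mk <- function(mfi) tibble::tibble(channel = "FL1_A", mfi = mfi, cv = 0.2,
                                     n_events = 1000L)
  same <- iron_index(mk(1000), mk(1000), qm)
  expect_identical(same$fold_quench, 1)
  expect_equal(same$iron_um, 0, tolerance = 1e-15)

  ii <- iron_index(mk(500), mk(1000), qm)
  expect_identical(ii$fold_quench, 2)
  expect_equal(ii$iron_um, 10, tolerance = 1e-12)

  # noiseless round-trip through the expected-MFI closed form is exact
  for (iron in c(0, 5, 25)) {
    rt <- iron_index(mk(pgsk_expected_mfi(iron, qm)), mk(qm$f0), qm)
    expect_equal(rt$iron_um, iron, tolerance = 1e-9)
  }
  expect_error(iron_index(mk(0), mk(1000), qm),
               class = "magcyto_division_error")
})

test_that("simulated PG-SK events recover generating iron within 10%", {
  qm <- quench_model(f0 = 2000, K_sv = 0.1)
  sim <- function(iron, seed) {
    scn <- scenario_spec(
      paste0("iron_", iron),
      list(population_spec("cells", 1,
                           list(FSC_A = c(2, .15), SSC_A = c(1.8, .15),
                                FL1_A = c(3, 0.25)),
                           iron_um = iron)),
      n_events = 25000, seed = seed,
      stain = stain_spec("PGSK", 5, "uM", 600), quench = qm)
    summarize_fluorescence(generate_scenario(scn), "FL1_A")
  }
  ref <- sim(0, seed = 31)
  for (iron in c(10, 50)) {
    est <- iron_index(sim(iron, seed = 31 + iron), ref, qm)$iron_um
    expect_lt(abs(est - iron) / iron, 0.10)
  }
})

test_that("count calibration: exact fit, conversions, volumetric counting", {
  exact <- tibble::tibble(od565 = c(0.1, 0.5, 1.0),
                          concentration = c(1.16e8, 5.8e8, 1.16e9))
  fit <- fit_count_calibration(exact)
  expect_equal(fit$slope, 1.16e9, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_identical(fit$n_points, 3L)

  expect_error(fit_count_calibration(exact[1:2, ]), class = "magcyto_fit_error")
  expect_error(fit_count_calibration(
    tibble::tibble(od565 = rep(0.5, 4), concentration = 1:4 * 1e8)),
    class = "magcyto_fit_error")

  expect_identical(od_to_concentration(0, fit)$concentration, 0)
  expect_error(od_to_concentration(-1, fit), class = "magcyto_validation_error")

  # packaged constants
  expect_identical(
    od_to_concentration(1, load_calibration("fcm_unstained"))$concentration,
    1.16e9)
  expect_identical(
    od_to_concentration(1, load_calibration("fcm_syto62"))$concentration,
    1.03e9)
  expect_identical(od_to_concentration(1, load_calibration("cfu"))$mode, "CFU")

  # volumetric: 70000 events in 35 uL/min * 120 s = 0.07 mL
  m <- acquisition_meta(flow_rate = 35, duration = 120, n_events = 70000L)
  expect_equal(events_to_concentration(m), 1e6, tolerance = 1e-12)
  m100 <- acquisition_meta(flow_rate = 35, duration = 120,
                           dilution_factor = 100, n_events = 70000L)
  expect_equal(events_to_concentration(m100), 1e8, tolerance = 1e-12)
  m0 <- acquisition_meta(flow_rate = 35, duration = 120, n_events = 0L)
  expect_identical(events_to_concentration(m0), 0)
  expect_error(events_to_concentration(acquisition_meta(n_events = 10L)),
               class = "magcyto_metadata_error")
})

test_that("tidiers expose fits as tibbles", {
  ev <- generate_scenario(load_scenario("magnetic_pha", 5000, seed = 3))
  fit <- fit_subpopulations(ev, "FL1_A", k = 2)
  td <- tidy(fit)
  expect_identical(names(td), c("component", "weight", "mean", "sd"))
  expect_identical(nrow(td), 2L)
  gl <- glance(fit)
  expect_identical(gl$k, 2L)
  expect_true(gl$converged)

  cal <- load_calibration("fcm_unstained")
  expect_identical(tidy(cal)$estimate, 1.16e9)
  expect_identical(glance(cal)$n_points, 0L)
})
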