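# synthetic-cytometer generators: determinism, closed forms, composition

test_that("sample_population draws a seeded log-normal cloud", {
  spec <- population_spec("healthy", 1, list(
    FSC_A = c(2, 0.25), SSC_A = c(1.8, 0.2)))

  expect_identical(nrow(sample_population(spec, 0, seed = 1)), 0L)

  # degenerate spread concentrates at 10^mu
  tight <- population_spec("healthy", 1, list(FSC_A = c(2, 1e-6),
                                              SSC_A = c(1, 1e-6)))
  ev <- sample_population(tight, 1000, seed = 3)
  expect_true(all(abs(ev$FSC_A - 100) / 100 < 0.01))

  # law of large numbers against the generating location
  big <- sample_population(spec, 1e5, seed = 42)
  expect_equal(mean(log10(big$FSC_A)), 2, tolerance = 0.01 / 2)
  expect_identical(unique(big$true_label), "healthy")

  # bit-reproducible given seed, different under another seed
  expect_identical(sample_population(spec, 100, seed = 7),
                   sample_population(spec, 100, seed = 7))
  expect_false(identical(sample_population(spec, 100, seed = 7)$FSC_A,
                         sample_population(spec, 100, seed = 8)$FSC_A))

  bad <- spec; bad$channels$FSC_A <- c(2, 0)
  expect_error(population_spec("x", 1, bad$channels),
               class = "magcyto_param_error")
})

test_that("generate_scenario pools multinomial counts at the stated fractions", {
  one <- scenario_spec("solo", list(population_spec("dead", 1, list(
    FSC_A = c(2, 0.2), SSC_A = c(2, 0.2)))), n_events = 500, seed = 1)
  expect_identical(unique(generate_scenario(one)$true_label), "dead")

  # empirical label fractions converge to spec fractions (3 binomial sd at 1e5)
  scn <- load_scenario("ethanol_killed", n_events = 1e5, seed = 7)
  ev <- generate_scenario(scn)
  fr <- vapply(scn$populations, `[[`, numeric(1), "fraction")
  names(fr) <- vapply(scn$populations, `[[`, character(1), "label")
  for (lab in names(fr)) {
    tol <- 3 * sqrt(fr[[lab]] * (1 - fr[[lab]]) / 1e5)
    expect_lt(abs(mean(ev$true_label == lab) - fr[[lab]]), tol + 1e-12)
  }

  # fractions must sum to one
  expect_error(scenario_spec("bad", list(
    population_spec("a", 0.6, list(FSC_A = c(2, .2), SSC_A = c(2, .2))),
    population_spec("b", 0.5, list(FSC_A = c(2, .2), SSC_A = c(2, .2)))
  )), class = "magcyto_param_error")

  # bit-reproducibility of the full draw
  expect_identical(generate_scenario(scn, n_events = 2000, seed = 9),
                   generate_scenario(scn, n_events = 2000, seed = 9))
})

test_that("staining kinetics follow the closed form and saturate fast", {
  kp <- kinetics_params(k = 0.2)
  expect_identical(stain_saturation(0, kp), 0)
  expect_equal(stain_saturation(15, kp), 1 - exp(-3), tolerance = 1e-12)
  expect_equal(stain_saturation(15, kp), 0.950213, tolerance = 1e-6)
  # saturated by 15 s, flat between 70 and 300 s with the default rate
  expect_gte(stain_saturation(15, kp), 0.95)
  expect_lte(stain_saturation(300, kp) / stain_saturation(70, kp), 1.02)
  # monotone non-decreasing
  t <- seq(0, 300, by = 0.5)
  expect_true(all(diff(stain_saturation(t, kp)) >= 0))
  expect_error(stain_saturation(-1, kp), class = "magcyto_param_error")
})

test_that("Stern-Volmer quenching matches its closed form and is monotone", {
  qm <- quench_model(f0 = 1000, K_sv = 0.1)
  expect_identical(pgsk_expected_mfi(0, qm), 1000)
  expect_equal(pgsk_expected_mfi(10, qm), 500, tolerance = 1e-12)
  iron <- seq(0, 100, by = 0.5)
  expect_true(all(diff(pgsk_expected_mfi(iron, qm)) < 0))
  expect_error(pgsk_expected_mfi(-1, qm), class = "magcyto_param_error")
})

test_that("paired OD generation obeys its noiseless closed form", {
  # non-magnetic limit: every pair has C_mag exactly 1
  p0 <- generate_od_pairs(0.5, 0, 1, noise_cv = 0, n = 5, seed = 1)
  expect_identical(compute_cmag(p0)$cmag, rep(1, 5))
  # strongly magnetic limit: C_mag exactly 2
  p2 <- generate_od_pairs(0.5, 1, 1, noise_cv = 0, n = 5, seed = 1)
  expect_equal(compute_cmag(p2)$cmag, rep(2, 5), tolerance = 1e-15)
  # intermediate: 1 + contrast * fraction exactly
  p <- generate_od_pairs(0.4, 0.3, 0.8, noise_cv = 0, n = 4, seed = 2)
  expect_equal(compute_cmag(p)$cmag, rep(1 + 0.8 * 0.3, 4), tolerance = 1e-15)
  # Monte-Carlo mean within 2% of noiseless value at modest noise
  pn <- generate_od_pairs(0.5, 1, 1, noise_cv = 0.02, n = 200, seed = 3)
  expect_equal(mean(compute_cmag(pn)$cmag), 2, tolerance = 0.02)
  expect_error(generate_od_pairs(0, 0.5, 1), class = "magcyto_param_error")
})

test_that("dilution series drives the calibration fit as specified", {
  ods <- seq(0.05, 1, length.out = 8)
  exact <- generate_dilution_series(1.16e9, ods, cv = 0, seed = 1)
  fit <- fit_count_calibration(exact)
  expect_equal(fit$slope, 1.16e9, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  noisy <- generate_dilution_series(1.16e9, ods, cv = 0.05, seed = 42)
  nfit <- fit_count_calibration(noisy)
  expect_lt(abs(nfit$slope - 1.16e9) / 1.16e9, 0.05)
  expect_gte(nfit$r2, 0.95)

  flat <- generate_dilution_series(1e9, rep(0.5, 5), cv = 0.05, seed = 1)
  expect_error(fit_count_calibration(flat), class = "magcyto_fit_error")
})
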