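# noise gate, threshold placement and quadrant classification

test_that("log_display floors at 1 and is monotone", {
  expect_identical(log_display(0), 0)
  expect_identical(log_display(1000), 3)
  expect_identical(log_display(c(1, 10, 100)), c(0, 1, 2))
  x <- sort(stats::runif(100, 0, 1e4))
  expect_true(all(diff(log_display(x)) >= 0))
  expect_error(log_display(-1), class = "magcyto_validation_error")
})

test_that("noise_gate separates Syto62-stained cells from debris", {
  ev <- generate_scenario(load_scenario("syto62_stained", 20000, seed = 4))
  expect_identical(nrow(noise_gate(ev, "syto62", cut = 0)), nrow(ev))

  gated <- noise_gate(ev, "syto62", cut = 100)
  frac <- attr(gated, "retained_fraction")
  expect_lt(abs(frac - 0.80), 3 * sqrt(0.8 * 0.2 / 20000) + 0.01)
  expect_gt(mean(gated$true_label == "healthy"), 0.99)

  high <- noise_gate(ev, "syto62", cut = max(ev$FL4_A) + 1)
  expect_identical(nrow(high), 0L)
  expect_s3_class(high, "event_tbl")

  no_fl4 <- event_table(data.frame(FSC_A = 1:5, SSC_A = 1:5))
  expect_error(noise_gate(no_fl4, "syto62", cut = 10),
               class = "magcyto_channel_error")
  expect_identical(nrow(noise_gate(no_fl4, "scatter", cut = 2)), 3L)
})

test_that("thresholds are the nearest-rank percentile of the control", {
  expect_identical(fixed_thresholds()$fl1_cut, 10)
  expect_identical(fixed_thresholds()$fl3_cut, 10)

  # enumerated control: 99.5th nearest-rank percentile of {1..1000} is 995
  ctl <- event_table(data.frame(FSC_A = rep(1, 1000), SSC_A = rep(1, 1000),
                                FL1_A = sample(1:1000), FL3_A = sample(1:1000)))
  thr <- estimate_thresholds(ctl, 99.5)
  expect_identical(thr$fl1_cut, 995)
  expect_identical(thr$provenance$percentile, 99.5)

  small <- constant_control(n = 50)
  expect_error(estimate_thresholds(small), class = "magcyto_sample_size_error")
})

test_that("threshold estimate agrees with a brute-force order-statistic oracle", {
  # oracle: enumerate every rank, pick the first with rank/n >= p/100
  oracle <- function(x, p) {
    s <- sort(x)
    for (i in seq_along(s)) if (i / length(s) >= p / 100) return(s[[i]])
    s[[length(s)]]
  }
  withr::with_seed(99, {
    for (n in c(100, 1234, 10000)) {
      x <- stats::rlnorm(n, 1, 0.8)
      ctl <- event_table(data.frame(FSC_A = x, SSC_A = x, FL1_A = x, FL3_A = x))
      for (p in c(50, 90, 99.5, 100)) {
        expect_identical(estimate_thresholds(ctl, p)$fl1_cut, oracle(x, p))
      }
    }
  })
})

test_that("classify_viability enumerates the quadrant scheme exactly", {
  thr <- fixed_thresholds()  # cuts at (10, 10)
  ev <- event_table(data.frame(
    FSC_A = rep(1, 6), SSC_A = rep(1, 6),
    FL1_A = c(5, 20, 20, 5, 10, 10),
    FL3_A = c(5, 5, 20, 20, 10, 20)))
  res <- classify_viability(ev, thr)
  expect_identical(as.character(res$labels),
                   c("healthy", "injured", "dead", "anomalous",
                     "healthy", "anomalous"))  # boundary counts negative
  expect_equal(res$fractions$fraction, c(1/3, 1/6, 1/6, 1/3), tolerance = 1e-12)
  expect_equal(sum(res$fractions$fraction), 1, tolerance = 1e-9)

  all_zero <- event_table(data.frame(FSC_A = rep(1, 4), SSC_A = rep(1, 4),
                                     FL1_A = rep(0, 4), FL3_A = rep(0, 4)))
  expect_identical(classify_viability(all_zero, thr)$fractions$fraction[[1]], 1)

  empty <- event_table(data.frame(FSC_A = numeric(), SSC_A = numeric(),
                                  FL1_A = numeric(), FL3_A = numeric()))
  expect_warning(res0 <- classify_viability(empty, thr))
  expect_identical(res0$n_events, 0L)
  expect_true(res0$empty)
})

test_that("quadrant fractions are invariant to event order and monotone in cuts", {
  scn <- load_scenario("starving_magnetic", 5000, seed = 21)
  ev <- generate_scenario(scn)
  thr <- estimate_thresholds(
    generate_scenario(load_scenario("unstained_control", 5000, seed = 1)))

  res <- classify_viability(ev, thr)
  shuffled <- event_table(as_tibble(ev)[sample(nrow(ev)), ], event_meta(ev))
  expect_identical(classify_viability(shuffled, thr)$fractions, res$fractions)

  # raising the BOX cut can only grow the healthy+anomalous side
  healthy_at <- function(cut) {
    t2 <- thr; t2$fl1_cut <- cut
    f <- classify_viability(ev, t2)$fractions
    f$fraction[f$state == "healthy"]
  }
  cuts <- sort(c(thr$fl1_cut, quantile(ev$FL1_A, c(0.2, 0.5, 0.8, 0.99))))
  h <- vapply(cuts, healthy_at, numeric(1))
  expect_true(all(diff(h) >= 0))
})

test_that("well-separated scenarios recover generating fractions at depth", {
  # >= 2 log-decades between negative (mu 1.0) and positive (mu 3.2) locations
  n <- 25000
  scn <- load_scenario("starving_magnetic", n, seed = 33)
  ev <- generate_scenario(scn)
  thr <- estimate_thresholds(
    generate_scenario(load_scenario("unstained_control", 25000, seed = 2)))
  res <- classify_viability(ev, thr)
  fr <- vapply(scn$populations, `[[`, numeric(1), "fraction")
  names(fr) <- vapply(scn$populations, `[[`, character(1), "label")
  for (st in names(fr)) {
    got <- res$fractions$fraction[res$fractions$state == st]
    tol <- 3 * sqrt(fr[[st]] * (1 - fr[[st]]) / n)
    # allow the 0.5% dye-negative misclassification rate on top of binomial error
    expect_lt(abs(got - fr[[st]]), tol + 0.015)
  }
})

test_that("scatter_summary reports means, CV and heterogeneity", {
  const <- event_table(data.frame(FSC_A = rep(100, 50), SSC_A = rep(100, 50)))
  s <- scatter_summary(const)
  expect_identical(s$mean, c(100, 100))
  expect_identical(s$cv, c(0, 0))

  # log-normal CV closed form: sqrt(exp((sigma ln10)^2) - 1)
  pop <- population_spec("x", 1, list(FSC_A = c(2, 0.25), SSC_A = c(2, 0.25)))
  ev <- sample_population(pop, 1e5, seed = 6)
  cv_expect <- sqrt(exp((0.25 * log(10))^2) - 1)
  expect_equal(scatter_summary(ev)$cv[[1]], cv_expect, tolerance = 0.02)

  # plate-grown cells: larger and more heterogeneous than liquid-grown
  liquid <- generate_scenario(load_scenario("liquid_grown", 20000, seed = 8))
  plate <- generate_scenario(load_scenario("plate_grown", 20000, seed = 9))
  sl <- scatter_summary(liquid); sp <- scatter_summary(plate)
  expect_gt(sp$mean[[1]], sl$mean[[1]])
  expect_gt(attr(sp, "heterogeneity_index"), attr(sl, "heterogeneity_index"))

  empty <- event_table(data.frame(FSC_A = numeric(), SSC_A = numeric()))
  expect_error(scatter_summary(empty), class = "magcyto_sample_size_error")
})
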