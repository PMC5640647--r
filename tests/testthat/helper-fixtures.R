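# small in-code fixtures shared across test files

simple_events <- function(n = 10, fl = TRUE, seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(FSC_A = stats::runif(n, 50, 200),
                     SSC_A = stats::runif(n, 20, 100))
    if (fl) {
      df$FL1_A <- stats::runif(n, 1, 50)
      df$FL3_A <- stats::runif(n, 1, 50)
      df$FL4_A <- stats::runif(n, 1, 50)
    }
    event_table(df, acquisition_meta(flow_rate = 35, duration = 60,
                                     n_events = n))
  })
}

# control whose FL1/FL3 cuts land at exactly 10 when estimated at any percentile
constant_control <- function(n = 200, value = 10) {
  event_table(data.frame(FSC_A = rep(100, n), SSC_A = rep(50, n),
                         FL1_A = rep(value, n), FL3_A = rep(value, n)))
}

fixed_thresholds <- function(fl1 = 10, fl3 = 10) {
  estimate_thresholds(constant_control(value = fl1), 99.5)
}
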