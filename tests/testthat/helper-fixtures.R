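# Short chains for tests: posterior medians of the models under test are
# stable at this length for the low-dimensional fits exercised here.
quick_mcmc <- function(chains = 2, iter = 1500, burn = 700) {
  mcmc_control(chains = chains, iter = iter, burn = burn)
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# Explicit well-separated baselines used by several TP tests.
test_baselines <- function(lambda = 2, sd = 0.5, n = 10) {
  baseline_spec(
    b1 = list(label = "benthic", mean13C = -16, sd13C = sd,
              mean15N = 5, sd15N = sd, n = n),
    b2 = list(label = "pelagic", mean13C = -24, sd13C = sd,
              mean15N = 4.5, sd15N = sd, n = n),
    lambda = lambda
  )
}

# Consumer data generated exactly at the two-baseline model mean for
# (tp_true, alpha_true), with N(0, sigma) residuals.
tp_model_consumer <- function(n, tp_true, alpha_true, baselines, tdf,
                              sigma = 0.3, seed = 1) {
  lambda <- baselines$lambda
  muN <- alpha_true * baselines$b1$mean15N +
    (1 - alpha_true) * baselines$b2$mean15N +
    tdf$meanDeltaN * (tp_true - lambda)
  muC <- alpha_true * baselines$b1$mean13C +
    (1 - alpha_true) * baselines$b2$mean13C +
    tdf$meanDeltaC * (tp_true - lambda)
  withr::with_seed(seed, tibble::tibble(
    taxon = "consumer",
    d13C = muC + rnorm(n, 0, sigma),
    d15N = muN + rnorm(n, 0, sigma)
  ))
}
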