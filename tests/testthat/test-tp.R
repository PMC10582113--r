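test_that("simulated TDFs have the requested moments", {
  d <- simulate_tdf(tdf_spec(nsim = 1e4), seed = 21)
  expect_lt(abs(mean(d$deltaN) - 3.4), 0.03)
  expect_lt(abs(mean(d$deltaC) - 0.39), 3 * 1.3 / sqrt(1e4))
  d0 <- simulate_tdf(tdf_spec(sdDeltaN = 0, sdDeltaC = 0, nsim = 100),
                     seed = 1)
  expect_true(all(d0$deltaN == 3.4) && all(d0$deltaC == 0.39))
  expect_identical(simulate_tdf(seed = 4), simulate_tdf(seed = 4))
})

test_that("the closed-form trophic position behaves as specified", {
  bl <- test_baselines()
  # consumer exactly one enrichment step above baseline 1
  pe <- tp_point_estimate(c(d13C = -16, d15N = 5 + 3.4), bl, deltaN = 3.4)
  expect_equal(pe$alpha, 1)
  expect_equal(pe$tp, 3)
  # d13C outside the baseline interval clips alpha
  expect_equal(tp_point_estimate(c(-10, 8), bl)$alpha, 1)
  expect_equal(tp_point_estimate(c(-30, 8), bl)$alpha, 0)
  expect_error(tp_point_estimate(c(-20, 8), bl, deltaN = 0),
               class = "isoforecast_domain_error")
})

test_that("the lake apex predator oracle value is reproduced", {
  # hand evaluation from the printed community table: alpha clips to 0,
  # pooled plankton baseline d15N = 4.71, TP = 2 + (12.60 - 4.71)/3.4
  com <- load_fixture("iznik_community")
  bl <- baseline_spec(com)
  pe <- tp_point_estimate(c(d13C = -24.65, d15N = 12.60), bl, deltaN = 3.4)
  expect_equal(pe$alpha, 0)
  expect_equal(pe$tp, 4.3205882, tolerance = 1e-6)
})

test_that("identical baseline carbon is rejected as unidentifiable", {
  expect_error(
    baseline_spec(b1 = list(mean13C = -20, mean15N = 5),
                  b2 = list(mean13C = -20, mean15N = 3)),
    class = "isoforecast_identifiability_error")
})

test_that("the posterior collapses to the closed form when all SDs vanish", {
  bl <- test_baselines(sd = 0)
  tdf0 <- tdf_spec(3.4, 0, 0.39, 0)
  tp_true <- 3.5
  alpha_true <- 0.5
  consumer <- tp_model_consumer(5, tp_true, alpha_true, bl, tdf0,
                                sigma = 0, seed = 1)
  fit <- suppressWarnings(fit_two_baseline_tp(
    consumer, bl, tdf = tdf0, mcmc = quick_mcmc(), seed = 2))
  oracle <- tp_point_estimate(consumer, bl, deltaN = 3.4)
  expect_equal(median(fit$draws$tp), oracle$tp, tolerance = 0.01)
  expect_equal(median(fit$draws$alpha), alpha_true, tolerance = 0.02)
})

test_that("raising consumer d15N never lowers the posterior median TP", {
  bl <- test_baselines()
  base <- tp_model_consumer(10, 3.2, 0.5, bl, tdf_spec(), sigma = 0.4,
                            seed = 3)
  fits <- purrr::map(c(0, 1, 2), function(shift) {
    m <- dplyr::mutate(base, d15N = d15N + shift)
    fit_two_baseline_tp(m, bl, mcmc = quick_mcmc(), seed = 5)
  })
  medians <- purrr::map_dbl(fits, ~ median(.x$draws$tp))
  expect_true(all(diff(medians) > 0))
})

test_that("swapping the baselines maps alpha to 1 - alpha, TP unchanged", {
  bl <- test_baselines()
  bl_swapped <- baseline_spec(b1 = bl$b2, b2 = bl$b1, lambda = bl$lambda)
  consumer <- tp_model_consumer(12, 3.4, 0.3, bl, tdf_spec(), sigma = 0.4,
                                seed = 7)
  mc <- quick_mcmc(2, 4000, 1500)
  f1 <- suppressWarnings(fit_two_baseline_tp(consumer, bl, mcmc = mc,
                                             seed = 9))
  f2 <- suppressWarnings(fit_two_baseline_tp(consumer, bl_swapped,
                                             mcmc = mc, seed = 9))
  expect_equal(mean(f1$draws$alpha), 1 - mean(f2$draws$alpha),
               tolerance = 0.1)
  expect_equal(median(f1$draws$tp), median(f2$draws$tp), tolerance = 0.1)
})

test_that("the TP model recovers a known trophic position", {
  bl <- test_baselines()
  tdf <- tdf_spec()
  consumer <- tp_model_consumer(20, 3.5, 0.5, bl, tdf, sigma = 0.3,
                                seed = 13)
  fit <- fit_two_baseline_tp(consumer, bl, tdf = tdf,
                             mcmc = quick_mcmc(), seed = 17)
  ci <- quantile(fit$draws$tp, c(0.025, 0.975))
  expect_gt(3.5, ci[[1]])
  expect_lt(3.5, ci[[2]])
  expect_equal(median(fit$draws$tp), 3.5, tolerance = 0.35)
})

test_that("fit interface contracts hold", {
  bl <- test_baselines()
  one <- tibble::tibble(d13C = -20, d15N = 9)
  expect_warning(fit_two_baseline_tp(one, bl,
                                     mcmc = quick_mcmc(1, 200, 100),
                                     seed = 1),
                 "single consumer")
  fit <- suppressWarnings(fit_two_baseline_tp(
    one, bl, mcmc = quick_mcmc(2, 300, 100), seed = 1))
  expect_true(all(fit$draws$alpha >= 0 & fit$draws$alpha <= 1))
  expect_true(all(fit$draws$tp >= bl$lambda))
  td <- tidy(fit)
  expect_setequal(td$term, c("tp", "alpha", "sigmaN", "sigmaC"))
  expect_s3_class(glance(fit), "tbl_df")
})
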