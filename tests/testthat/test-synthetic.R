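test_that("generated groups converge to their spec moments", {
  n <- 1e5
  sp <- group_spec("x", n = n, mean13C = -22, mean15N = 10,
                   sd13C = 2, sd15N = 1, rho = 0.5)
  g <- generate_group(sp, seed = 31)
  expect_equal(nrow(g), n)
  expect_lt(abs(mean(g$d15N) - 10), 3 * 1 / sqrt(n))
  expect_lt(abs(mean(g$d13C) + 22), 3 * 2 / sqrt(n))
  expect_lt(abs(sd(g$d15N) - 1), 3 * 1 / sqrt(2 * n))
  expect_lt(abs(cor(g$d13C, g$d15N) - 0.5), 3 * (1 - 0.5^2) / sqrt(n))
})

test_that("zero SDs give a point mass and equal seeds equal draws", {
  sp0 <- group_spec("x", n = 20, mean13C = -20, mean15N = 8)
  g0 <- generate_group(sp0, seed = 1)
  expect_true(all(g0$d13C == -20))
  expect_true(all(g0$d15N == 8))
  sp <- group_spec("x", n = 50, mean13C = -20, mean15N = 8,
                   sd13C = 1, sd15N = 1)
  expect_identical(generate_group(sp, seed = 9), generate_group(sp, seed = 9))
  expect_false(identical(generate_group(sp, seed = 9),
                         generate_group(sp, seed = 10)))
})

test_that("group_spec validates its invariants", {
  expect_error(group_spec("x", n = 0, mean13C = 0, mean15N = 0),
               class = "isoforecast_spec_error")
  expect_error(group_spec("x", n = 5, mean13C = 0, mean15N = 0,
                          sd13C = -1), class = "isoforecast_spec_error")
  expect_error(group_spec("x", n = 5, mean13C = 0, mean15N = 0, rho = 1.2),
               class = "isoforecast_spec_error")
})

test_that("consumer generator follows the forward mixing model", {
  s1 <- group_spec("a", 1, mean13C = -20, mean15N = 0)
  s2 <- group_spec("b", 1, mean13C = -20, mean15N = 10)
  tdf0 <- tdf_spec(0, 0, 0, 0)
  # one source, all noise off: consumers exactly at the source mean
  cs <- consumer_spec(list(s1), 1, tdf = tdf0, n = 5)
  out <- generate_consumer(cs, seed = 2)
  expect_true(all(out$d15N == 0) && all(out$d13C == -20))
  # two sources, even split: mean d15N near 5
  cs2 <- consumer_spec(list(s1, s2), c(0.5, 0.5), tdf = tdf0,
                       resid_sd15N = 1, n = 4000)
  out2 <- generate_consumer(cs2, seed = 3)
  expect_lt(abs(mean(out2$d15N) - 5), 3 * 1 / sqrt(4000))
  # simplex validation
  expect_error(consumer_spec(list(s1, s2), c(0.6, 0.6)),
               class = "isoforecast_spec_error")
})

test_that("consumer draws are most likely under the true parameters", {
  # average log-density under the generating likelihood must beat a
  # perturbed parameter vector
  srcs <- list(
    group_spec("a", 1, mean13C = -26, mean15N = 12, sd13C = .5, sd15N = .5),
    group_spec("b", 1, mean13C = -20, mean15N = 6, sd13C = .5, sd15N = .5),
    group_spec("c", 1, mean13C = -14, mean15N = 2, sd13C = .5, sd15N = .5)
  )
  tdf0 <- tdf_spec(0, 0, 0, 0)
  p_true <- c(0.7, 0.2, 0.1)
  cs <- consumer_spec(srcs, p_true, tdf = tdf0, resid_sd13C = 0.3,
                      resid_sd15N = 0.3, n = 400)
  y <- generate_consumer(cs, seed = 11)
  ll <- function(p) {
    mu13 <- vapply(srcs, `[[`, 0, "mean13C")
    mu15 <- vapply(srcs, `[[`, 0, "mean15N")
    v <- 0.5^2
    m13 <- sum(p * mu13); m15 <- sum(p * mu15)
    s13 <- sqrt(sum(p^2 * v) + 0.3^2); s15 <- sqrt(sum(p^2 * v) + 0.3^2)
    sum(dnorm(y$d13C, m13, s13, log = TRUE)) +
      sum(dnorm(y$d15N, m15, s15, log = TRUE))
  }
  expect_gt(ll(p_true), ll(c(0.5, 0.3, 0.2)))
  expect_gt(ll(p_true), ll(c(0.9, 0.05, 0.05)))
})

test_that("communities assemble with stable per-group seed streams", {
  specs <- list(
    group_spec("a", 10, -24, 4, 1, 1),
    group_spec("b", 10, -18, 6, 1, 1),
    group_spec("c", 10, -21, 10, 1, 1)
  )
  roles <- list(baseline1 = "a", baseline2 = "b")
  com <- generate_community(specs, roles, seed = 5)
  expect_equal(nrow(com$measurements), 30L)
  expect_equal(nrow(com$summaries), 3L)
  # changing one group's n leaves the other groups' draws unchanged
  specs2 <- specs
  specs2[[2]] <- group_spec("b", 25, -18, 6, 1, 1)
  com2 <- generate_community(specs2, roles, seed = 5)
  expect_identical(com$measurements[com$measurements$taxon == "a", ],
                   com2$measurements[com2$measurements$taxon == "a", ])
  # error contracts
  expect_error(generate_community(specs, list(baseline1 = "a"), seed = 1),
               class = "isoforecast_config_error")
  expect_error(generate_community(specs, list(baseline1 = "a",
                                              baseline2 = "zz"), seed = 1),
               class = "isoforecast_config_error")
  specs_dup <- c(specs, list(group_spec("a", 5, -20, 5)))
  expect_error(generate_community(specs_dup, roles, seed = 1),
               class = "isoforecast_validation_error")
})

test_that("the lake-like preset reproduces every fixture group", {
  specs <- iznik_group_specs()
  expect_length(specs, 19L)
  roles <- list(baseline1 = "Detritus",
                baseline2 = c("Phytoplankton", "Zooplankton"))
  com <- generate_community(specs, roles, seed = 8)
  expect_equal(nrow(com$summaries), 19L)
})

test_that("moment-matched pseudo-individuals reproduce the summary exactly", {
  com <- load_fixture("iznik_community")
  ind <- simulate_from_summaries(com, seed = 3, taxa = "Silurus glanis")
  expect_equal(nrow(ind), 10L)
  expect_equal(mean(ind$d15N), 12.60, tolerance = 1e-9)
  expect_equal(sd(ind$d15N), 3.70, tolerance = 1e-9)
  expect_equal(mean(ind$d13C), -24.65, tolerance = 1e-9)
  expect_equal(sd(ind$d13C), 2.35, tolerance = 1e-9)
  # plain draws do not match exactly
  ind2 <- simulate_from_summaries(com, seed = 3, taxa = "Silurus glanis",
                                  exact = FALSE)
  expect_gt(abs(mean(ind2$d15N) - 12.60), 1e-6)
})
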