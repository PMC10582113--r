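tiny_recipient <- function(seed = 3) {
  specs <- list(
    group_spec("detritus", 5, -16, 5, .5, .5, status = "native"),
    group_spec("plankton", 5, -24, 4.5, .5, .5, status = "native"),
    group_spec("prey1", 8, -22, 8, .5, .5, status = "native"),
    group_spec("prey2", 8, -18, 8, .5, .5, status = "native"),
    group_spec("apex", 8, -20, 12, .5, .5, status = "native")
  )
  com <- generate_community(
    specs, list(baseline1 = "detritus", baseline2 = "plankton"), seed)
  com$summaries$is_fish <- com$summaries$taxon %in%
    c("prey1", "prey2", "apex")
  com
}

test_that("superimposition appends donors without touching the recipient", {
  rec <- tiny_recipient()
  donor <- tibble::tibble(taxon = "perch", d13C = rnorm(10, -21),
                          d15N = rnorm(10, 13))
  comb <- superimpose(list(perch = donor), rec, seed = 5)
  expect_equal(nrow(comb$measurements),
               nrow(rec$measurements) + 10L)
  expect_identical(comb$measurements[seq_len(nrow(rec$measurements)), ],
                   rec$measurements)
  expect_true(all(comb$measurements$status[
    comb$measurements$group %in% "perch"] == "hypothetical"))
  expect_identical(attr(comb, "donor_labels"), "perch")
})

test_that("summary donors become deterministic pseudo-individuals", {
  rec <- tiny_recipient()
  don <- perch_donor_groups()
  c1 <- superimpose(don, rec, seed = 7)
  c2 <- superimpose(don, rec, seed = 7)
  expect_identical(c1$measurements, c2$measurements)
  lakes <- c1$measurements[c1$measurements$group %in%
                             "P. fluviatilis (lakes)", ]
  expect_equal(nrow(lakes), 20L)
  # moment-matched around the two site means: pooled mean is exact
  expect_equal(mean(lakes$d15N), (15.8 + 15.2) / 2, tolerance = 1e-9)
  c3 <- superimpose(don, rec, seed = 8)
  expect_false(identical(c1$measurements, c3$measurements))
})

test_that("standardization needs donor baselines and can be a no-op", {
  rec <- tiny_recipient()
  donor <- tibble::tibble(taxon = "perch", d13C = rnorm(5, -21),
                          d15N = rnorm(5, 13))
  expect_error(superimpose(list(perch = donor), rec, standardize = TRUE),
               class = "isoforecast_config_error")
  rb <- isoforecast:::recipient_baseline_means(rec)
  same <- superimpose(
    list(perch = donor), rec, standardize = TRUE,
    donor_baselines = list(perch = list(mean13C = rb[["d13C"]],
                                        mean15N = rb[["d15N"]])),
    seed = 2)
  raw <- superimpose(list(perch = donor), rec, seed = 2)
  expect_equal(same$measurements$d13C, raw$measurements$d13C)
  expect_equal(same$measurements$d15N, raw$measurements$d15N)
})

test_that("prey selection applies the exclusion and size rules", {
  com <- load_fixture("iznik_community")
  prey <- select_prey(com, "Silurus glanis")
  expect_s3_class(prey, "source_set")
  expect_equal(nrow(prey), 11L)
  expect_false("Silurus glanis" %in% prey$label)
  expect_false(any(c("Detritus", "Zooplankton", "Pelophylax ridibundus")
                   %in% prey$label))
  # threshold filter: count derived from the fixture's TL column
  s <- com$summaries
  expected <- sum(s$is_fish & s$taxon != "Silurus glanis" &
                    (is.na(s$mean_TL) | s$mean_TL <= 150))
  prey150 <- select_prey(com, "Silurus glanis", size_threshold = 150)
  expect_equal(nrow(prey150), expected)
  expect_false("Capoeta tinca" %in% prey150$label)
  expect_error(select_prey(com, "Esox lucius"),
               class = "isoforecast_config_error")
  expect_error(select_prey(com, "Silurus glanis",
                           extra_exclusions = setdiff(
                             s$taxon[s$is_fish], "Silurus glanis")),
               class = "isoforecast_validation_error")
})

test_that("the projection report is complete and reproducible", {
  rec <- tiny_recipient()
  don <- list(
    donorA = tibble::tibble(taxon = "donorA", d13C = rnorm(8, -20, .5),
                            d15N = rnorm(8, 12, .5)),
    donorB = tibble::tibble(taxon = "donorB", d13C = rnorm(8, -19, .5),
                            d15N = rnorm(8, 11, .5))
  )
  sc <- projection_scenario(rec, don, apex_label = "apex")
  mc <- quick_mcmc(1, 600, 300)
  rep1 <- run_projection(sc, mcmc = mc, seed = 9, nmc = 400)
  expect_s3_class(rep1, "projection_report")
  # every donor has a TP, a diet and overlap entries vs the apex
  expect_true(all(c("donorA", "donorB") %in% rep1$tp$group))
  expect_setequal(unique(rep1$diet$consumer), c("donorA", "donorB"))
  for (d in c("donorA", "donorB")) {
    expect_true(any(rep1$overlap_direction$group_a == d &
                      rep1$overlap_direction$group_b == "apex"))
    expect_true(any(rep1$overlap_direction$group_a == "apex" &
                      rep1$overlap_direction$group_b == d))
    expect_true(d %in% rep1$overlap_seab$group_a)
  }
  expect_equal(rep1$provenance$seed, 9)
  rep2 <- run_projection(sc, mcmc = mc, seed = 9, nmc = 400)
  expect_equal(rep1$tp, rep2$tp)
  expect_equal(rep1$diet, rep2$diet)
  expect_equal(rep1$overlap_direction, rep2$overlap_direction)
})

test_that("resident inference is unchanged by which donors are present", {
  rec <- tiny_recipient()
  mc <- quick_mcmc(1, 500, 250)
  donA <- list(donorA = tibble::tibble(
    taxon = "donorA", d13C = rnorm(8, -20, .5), d15N = rnorm(8, 12, .5)))
  donAB <- c(donA, list(donorB = tibble::tibble(
    taxon = "donorB", d13C = rnorm(8, -19, .5), d15N = rnorm(8, 11, .5))))
  r1 <- run_projection(projection_scenario(rec, donA, "apex"),
                       mcmc = mc, seed = 13, nmc = 200)
  r2 <- run_projection(projection_scenario(rec, donAB, "apex"),
                       mcmc = mc, seed = 13, nmc = 200)
  resident <- c("prey1", "prey2", "apex")
  expect_equal(r1$tp[r1$tp$group %in% resident, ],
               r2$tp[r2$tp$group %in% resident, ])
})

test_that("identical groups overlap at the niche level with a uniform diet", {
  set.seed(17)
  base <- MASS::mvrnorm(60, c(-20, 8), diag(0.25, 2))
  mk <- function(nm) tibble::tibble(taxon = nm, d13C = base[, 1],
                                    d15N = base[, 2])
  ov <- directional_overlap(mk("a"), mk("b"), alpha = 0.95, nmc = 3000,
                            seed = 18, labels = c("a", "b"))
  expect_lt(abs(ov$prob - 0.95), 0.03)
  src <- source_set(tibble::tibble(
    taxon = c("s1", "s2", "s3"), n = 10,
    mean13C = -20, sd13C = .5, mean15N = 8, sd15N = .5))
  fit <- suppressWarnings(fit_mixing_model(
    tibble::tibble(d13C = -19.8, d15N = 8.1), src,
    tdf = tdf_spec(0, 0, 0, 0), mcmc = quick_mcmc(), seed = 19))
  expect_equal(unname(colMeans(fit$p_draws)), rep(1 / 3, 3),
               tolerance = 0.08)
})

test_that("donor SD sensitivity reports one median per donor and SD", {
  rec <- tiny_recipient()
  don <- perch_donor_groups()
  sc <- projection_scenario(rec, don, apex_label = "apex")
  out <- donor_sd_sensitivity(sc, sds = c(0.5, 1),
                              mcmc = quick_mcmc(1, 400, 200), seed = 21)
  expect_equal(nrow(out), 4L)
  expect_setequal(unique(out$donor_sd), c(0.5, 1))
  expect_true(all(is.finite(out$tp_median)))
})
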