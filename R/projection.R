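#' Donor groups from the packaged perch site table
#'
#' Splits the `perch_sites` fixture into its two donor populations (two
#' natural-lake sites; three reservoir sites) as a named list of summary
#' tibbles ready for [superimpose()].
#'
#' @return Named list of summary tibbles.
#' @export
perch_donor_groups <- function() {
  s <- load_fixture("perch_sites")$summaries
  list(
    `P. fluviatilis (lakes)` = s[s$system == "Lake", ],
    `P. fluviatilis (reservoirs)` = s[s$system == "Reservoir", ]
  )
}

#' Superimpose donor populations into a recipient community
#'
#' Appends donor isotope signatures to the recipient community's biplot
#' without rescaling (the default, "raw" approach: donor values are
#' assumed to be on the same per-mil reference scales). Donors given as
#' summary tables (site means) are expanded into pseudo-individuals drawn
#' around each site mean with an assumed SD. With `standardize = TRUE`
#' donor values are instead shifted by the difference between the
#' recipient's and the donor system's baseline means (requires
#' `donor_baselines`).
#'
#' @param donors Named list of donor tibbles: either individual
#'   measurements (`d13C`, `d15N`) or group summaries (`mean13C`,
#'   `mean15N`, ...). Names become donor group labels.
#' @param recipient A [community()].
#' @param standardize Shift donor values to the recipient baseline frame.
#' @param donor_baselines Named list (per donor) with elements `mean13C`
#'   and `mean15N`: the donor system's baseline means. Only used when
#'   `standardize = TRUE`.
#' @param donor_sd Assumed per-isotope SD (per-mil) for pseudo-individuals
#'   when a donor is given as site means only.
#' @param n_per_site Pseudo-individuals per donor summary row.
#' @param seed Integer seed.
#' @return A [community()] containing the recipient rows unchanged plus
#'   the donor individuals (status `"hypothetical"`, group = donor
#'   label), with attribute `donor_labels`.
#' @export
superimpose <- function(donors, recipient, standardize = FALSE,
                        donor_baselines = NULL, donor_sd = 1,
                        n_per_site = 10, seed = 1) {
  stopifnot(inherits(recipient, "community"))
  if (!is.list(donors) || !length(donors)) {
    abort("donors must be a nonempty named list",
          class = "isoforecast_config_error")
  }
  if (is.null(names(donors)) || any(names(donors) == "")) {
    abort("every donor must be named", class = "isoforecast_config_error")
  }
  if (standardize && is.null(donor_baselines)) {
    abort("standardize = TRUE requires donor_baselines",
          class = "isoforecast_config_error")
  }
  donor_rows <- purrr::imap(donors, function(d, label) {
    d <- tibble::as_tibble(d)
    if (all(c("d13C", "d15N") %in% names(d))) {
      out <- d
      out$taxon <- label
    } else {
      out <- simulate_from_summaries(
        d, seed = child_seed(seed, match(label, names(donors))),
        n_per_group = n_per_site, sd_fill = donor_sd)
      out$taxon <- label
    }
    out$group <- label
    out$status <- "hypothetical"
    if (standardize) {
      db <- donor_baselines[[label]]
      if (is.null(db)) {
        abort(paste0("no donor baseline for ", label),
              class = "isoforecast_config_error")
      }
      rb <- recipient_baseline_means(recipient)
      out$d13C <- out$d13C + (rb["d13C"] - db$mean13C)
      out$d15N <- out$d15N + (rb["d15N"] - db$mean15N)
    }
    normalize_measurements(out)
  })
  donor_m <- dplyr::bind_rows(donor_rows)
  donor_s <- summarize_measurements(donor_m)
  donor_s$is_fish <- TRUE
  combined <- community(
    measurements = dplyr::bind_rows(recipient$measurements, donor_m),
    summaries = dplyr::bind_rows(recipient$summaries, donor_s),
    baselines = recipient$baselines
  )
  attr(combined, "donor_labels") <- names(donors)
  combined
}

recipient_baseline_means <- function(recipient) {
  taxa <- unlist(recipient$baselines)
  s <- dplyr::filter(recipient$summaries, .data$taxon %in% taxa)
  c(d13C = mean(s$mean13C), d15N = mean(s$mean15N))
}

#' Select candidate prey sources for a predator
#'
#' All fish taxa of the community except the resident apex predator,
#' any extra exclusions, and (optionally) taxa whose mean total length
#' exceeds a gape-size threshold. Non-fish groups (frog, invertebrates,
#' producers, detritus) are never prey.
#'
#' @param community A [community()] whose summaries flag fish taxa
#'   (`is_fish`).
#' @param apex_label Taxon label of the resident apex predator.
#' @param extra_exclusions Character vector of additional taxa to drop.
#' @param size_threshold Optional mean total length (mm) above which taxa
#'   are excluded; taxa with unknown TL are kept.
#' @return A [source_set()].
#' @export
select_prey <- function(community, apex_label,
                        extra_exclusions = character(),
                        size_threshold = NULL) {
  stopifnot(inherits(community, "community"))
  s <- community$summaries
  if (!apex_label %in% s$taxon) {
    abort(paste0("apex label not present in community: ", apex_label),
          class = "isoforecast_config_error")
  }
  unknown <- setdiff(extra_exclusions, s$taxon)
  if (length(unknown)) {
    abort(paste0("excluded taxa not present in community: ",
                 paste(unknown, collapse = ", ")),
          class = "isoforecast_config_error")
  }
  prey <- dplyr::filter(
    s, !is.na(.data$is_fish) & .data$is_fish,
    .data$taxon != apex_label,
    !.data$taxon %in% extra_exclusions)
  if (!is.null(size_threshold)) {
    prey <- dplyr::filter(
      prey, is.na(.data$mean_TL) | .data$mean_TL <= size_threshold)
  }
  if (nrow(prey) == 0L) {
    abort("prey selection left no sources",
          class = "isoforecast_validation_error")
  }
  source_set(prey)
}

#' Define an invasion projection scenario
#'
#' @param recipient A [community()] (the invaded system).
#' @param donors Named list of donor tables (see [superimpose()]).
#' @param apex_label Resident apex predator taxon.
#' @param prey_exclusions Extra taxa excluded from the prey set.
#' @param size_threshold Optional mean-TL prey filter (mm).
#' @param baselines A [baseline_spec()]; defaults to the recipient's
#'   baseline roles with lambda 2.
#' @param tdf A [tdf_spec()].
#' @param donor_sd Assumed SD for donor pseudo-individuals (per-mil).
#' @param n_per_site Pseudo-individuals per donor summary row.
#' @return A `projection_scenario` list.
#' @export
projection_scenario <- function(recipient, donors, apex_label,
                                prey_exclusions = character(),
                                size_threshold = NULL, baselines = NULL,
                                tdf = tdf_spec(), donor_sd = 1,
                                n_per_site = 10) {
  stopifnot(inherits(recipient, "community"))
  if (!apex_label %in% recipient$summaries$taxon) {
    abort(paste0("apex label not present in recipient: ", apex_label),
          class = "isoforecast_config_error")
  }
  if (!is.list(donors) || !length(donors)) {
    abort("donors must be a nonempty named list",
          class = "isoforecast_config_error")
  }
  unknown <- setdiff(prey_exclusions, recipient$summaries$taxon)
  if (length(unknown)) {
    abort(paste0("excluded taxa not in recipient: ",
                 paste(unknown, collapse = ", ")),
          class = "isoforecast_config_error")
  }
  baselines <- baselines %||% baseline_spec(recipient)
  structure(
    list(recipient = recipient, donors = donors, apex_label = apex_label,
         prey_exclusions = prey_exclusions,
         size_threshold = size_threshold, baselines = baselines,
         tdf = tdf, donor_sd = donor_sd, n_per_site = n_per_site),
    class = "projection_scenario"
  )
}

#' Run the full invasion projection
#'
#' The end-to-end forecast: donor signatures are superimposed into the
#' recipient biplot; trophic positions are fitted for every resident fish
#' group (from pseudo-individuals matching its summary) and for each
#' donor; a diet mixing model is fitted per donor over the selected prey
#' set (optionally also per donor site); and Bayesian standard ellipse
#' overlap plus directional overlap probabilities are computed between
#' each donor and the resident apex predator. All stages share one seed
#' tree, so the report is fully reproducible from (scenario, seed), and
#' resident-only quantities do not depend on which donors are present.
#'
#' @param scenario A [projection_scenario()].
#' @param mcmc An [mcmc_control()] shared by the TP and mixing fits.
#' @param seed Integer seed.
#' @param overlap_alpha Niche levels for the directional overlap (default
#'   `c(0.95, 1 - exp(-0.5))`, the SEAb-95% and standard-ellipse levels).
#' @param nmc Monte-Carlo steps per directional overlap.
#' @param per_site Also fit a mixing model per donor site.
#' @return A `projection_report` with elements `tp`, `tp_fits`, `diet`,
#'   `diet_fits`, `rank1`, `seab`, `overlap_direction`, `overlap_seab`
#'   and `provenance`.
#' @export
run_projection <- function(scenario, mcmc = mcmc_control(), seed = 1,
                           overlap_alpha = c(0.95, 1 - exp(-0.5)),
                           nmc = 10000, per_site = FALSE) {
  stopifnot(inherits(scenario, "projection_scenario"))
  recipient <- scenario$recipient
  combined <- superimpose(scenario$donors, recipient,
                          donor_sd = scenario$donor_sd,
                          n_per_site = scenario$n_per_site,
                          seed = child_seed(seed, 1))
  donor_labels <- attr(combined, "donor_labels")

  # --- trophic positions -------------------------------------------------
  fish <- dplyr::filter(recipient$summaries,
                        !is.na(.data$is_fish) & .data$is_fish)
  tp_fits <- list()
  for (i in seq_len(nrow(fish))) {
    taxon <- fish$taxon[i]
    ind <- simulate_from_summaries(fish[i, ],
                                   seed = child_seed(seed, 1000 + i))
    tp_fits[[taxon]] <- fit_two_baseline_tp(
      ind, scenario$baselines, tdf = scenario$tdf, mcmc = mcmc,
      seed = child_seed(seed, 2000 + i))
  }
  for (j in seq_along(donor_labels)) {
    label <- donor_labels[j]
    ind <- combined$measurements[combined$measurements$group %in% label, ]
    tp_fits[[label]] <- fit_two_baseline_tp(
      ind, scenario$baselines, tdf = scenario$tdf, mcmc = mcmc,
      seed = child_seed(seed, 3000 + j))
  }
  tp_tbl <- dplyr::bind_rows(purrr::imap(tp_fits, function(f, nm) {
    t <- tidy(f)
    tibble::tibble(group = nm,
                   tp_median = t$estimate[t$term == "tp"],
                   tp_low = t$conf.low[t$term == "tp"],
                   tp_high = t$conf.high[t$term == "tp"],
                   alpha_median = t$estimate[t$term == "alpha"])
  }))

  # --- diet mixing per donor --------------------------------------------
  prey <- select_prey(recipient, scenario$apex_label,
                      scenario$prey_exclusions, scenario$size_threshold)
  diet_fits <- list()
  for (j in seq_along(donor_labels)) {
    label <- donor_labels[j]
    consumer <- combined$measurements[combined$measurements$group %in% label, ]
    diet_fits[[label]] <- fit_mixing_model(
      consumer, prey, tdf = scenario$tdf, mcmc = mcmc,
      seed = child_seed(seed, 4000 + j))
    if (per_site) {
      d <- tibble::as_tibble(scenario$donors[[label]])
      if (!"d13C" %in% names(d) && "group" %in% names(d)) {
        for (site in unique(d$group)) {
          site_ind <- simulate_from_summaries(
            d[d$group == site, ],
            seed = child_seed(seed, 4500 + match(site, unique(d$group))),
            n_per_group = scenario$n_per_site,
            sd_fill = scenario$donor_sd)
          diet_fits[[paste0(label, " @ ", site)]] <- fit_mixing_model(
            site_ind, prey, tdf = scenario$tdf, mcmc = mcmc,
            seed = child_seed(seed, 5000 + match(site, unique(d$group))))
        }
      }
    }
  }
  diet_tbl <- dplyr::bind_rows(purrr::imap(diet_fits, function(f, nm) {
    dplyr::mutate(summarize_diet(f), consumer = nm, .before = 1)
  }))
  rank1_tbl <- dplyr::bind_rows(purrr::imap(diet_fits, function(f, nm) {
    dplyr::mutate(rank_stability(f), consumer = nm, .before = 1)
  }))

  # --- niches and overlap vs the apex ------------------------------------
  apex_row <- recipient$summaries[recipient$summaries$taxon ==
                                    scenario$apex_label, ]
  apex_ind <- simulate_from_summaries(apex_row,
                                      seed = child_seed(seed, 6000))
  niche_groups <- c(stats::setNames(list(apex_ind), scenario$apex_label),
                    purrr::map(stats::setNames(donor_labels, donor_labels),
                               function(lb) {
                                 combined$measurements[
                                   combined$measurements$group %in% lb, ]
                               }))
  seab_fits <- purrr::imap(niche_groups, function(m, nm) {
    bayesian_sea(m, ndraws = min(2000, nmc),
                 seed = child_seed(seed, 7000 + match(nm, names(niche_groups))))
  })
  seab_tbl <- dplyr::bind_rows(purrr::imap(seab_fits, function(f, nm) {
    dplyr::mutate(tidy(f), group = nm, .before = 1)
  }))
  overlap_rows <- list()
  seab_overlap_rows <- list()
  for (j in seq_along(donor_labels)) {
    label <- donor_labels[j]
    for (a in overlap_alpha) {
      overlap_rows[[length(overlap_rows) + 1L]] <- directional_overlap(
        niche_groups[[label]], niche_groups[[scenario$apex_label]],
        alpha = a, nmc = nmc, seed = child_seed(seed, 8000 + 10 * j),
        labels = c(label, scenario$apex_label))
      overlap_rows[[length(overlap_rows) + 1L]] <- directional_overlap(
        niche_groups[[scenario$apex_label]], niche_groups[[label]],
        alpha = a, nmc = nmc, seed = child_seed(seed, 8001 + 10 * j),
        labels = c(scenario$apex_label, label))
    }
    ov <- bayesian_overlap(seab_fits[[label]],
                           seab_fits[[scenario$apex_label]],
                           coverage = 0.95, ndraws = 200,
                           seed = child_seed(seed, 8500 + j))
    seab_overlap_rows[[label]] <- tibble::tibble(
      group_a = label, group_b = scenario$apex_label, coverage = 0.95,
      jaccard_mean = mean(ov$jaccard),
      frac_of_a_mean = mean(ov$frac_of_a),
      frac_of_b_mean = mean(ov$frac_of_b)
    )
  }

  structure(
    list(
      tp = tp_tbl, tp_fits = tp_fits,
      diet = diet_tbl, diet_fits = diet_fits, rank1 = rank1_tbl,
      prey = prey,
      seab = seab_tbl,
      overlap_direction = dplyr::bind_rows(overlap_rows),
      overlap_seab = dplyr::bind_rows(seab_overlap_rows),
      combined = combined,
      provenance = list(
        seed = seed, mcmc = mcmc, donor_sd = scenario$donor_sd,
        n_per_site = scenario$n_per_site,
        apex_label = scenario$apex_label,
        prey_exclusions = scenario$prey_exclusions,
        size_threshold = scenario$size_threshold,
        overlap_alpha = overlap_alpha, nmc = nmc,
        lambda = scenario$baselines$lambda,
        tdf = unclass(scenario$tdf),
        version = as.character(utils::packageVersion("isoforecast"))
      )
    ),
    class = "projection_report"
  )
}

#' @export
print.projection_report <- function(x, ...) {
  cat("<projection_report>\n")
  cat("Trophic positions (posterior medians):\n")
  print(dplyr::arrange(x$tp, dplyr::desc(.data$tp_median)), n = 5)
  cat("Top-ranked prey per donor:\n")
  top <- dplyr::slice_head(dplyr::group_by(x$diet, .data$consumer), n = 2)
  print(top)
  invisible(x)
}

#' Sensitivity of donor trophic position to the assumed donor SD
#'
#' Re-runs the donor TP fits across a grid of assumed pseudo-individual
#' SDs (the one free knob of the raw-superimposition approach) and
#' reports the posterior median TP per donor and SD.
#'
#' @param scenario A [projection_scenario()].
#' @param sds SD grid (per-mil).
#' @param mcmc An [mcmc_control()].
#' @param seed Integer seed.
#' @return Tibble with columns `donor`, `donor_sd`, `tp_median`.
#' @export
donor_sd_sensitivity <- function(scenario, sds = c(0.5, 1, 2),
                                 mcmc = mcmc_control(), seed = 1) {
  stopifnot(inherits(scenario, "projection_scenario"))
  rows <- list()
  for (s in sds) {
    combined <- superimpose(scenario$donors, scenario$recipient,
                            donor_sd = s,
                            n_per_site = scenario$n_per_site,
                            seed = child_seed(seed, 1))
    for (label in attr(combined, "donor_labels")) {
      ind <- combined$measurements[combined$measurements$group %in% label, ]
      fit <- fit_two_baseline_tp(ind, scenario$baselines,
                                 tdf = scenario$tdf, mcmc = mcmc,
                                 seed = child_seed(seed, 9000 +
                                                     round(100 * s)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        donor = label, donor_sd = s, tp_median = median(fit$draws$tp))
    }
  }
  dplyr::bind_rows(rows)
}
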