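#' Specify a synthetic isotope group
#'
#' A bivariate-normal cluster in (d13C, d15N) space emulating one taxon's
#' isotope cloud: means and SDs in per-mil, with optional correlation
#' between the two isotopes. The default `rho = 0` reflects that per-taxon
#' isotope covariances are rarely reported; it is configurable because
#' ellipse orientation depends on it.
#'
#' @param taxon Taxon label.
#' @param n Number of individuals to draw (>= 1).
#' @param mean13C,mean15N Group means (per-mil).
#' @param sd13C,sd15N Group SDs (per-mil, >= 0).
#' @param rho Isotope correlation in `[-1, 1]`.
#' @param status Status label (default `"native"`).
#' @return A `group_spec` list.
#' @export
group_spec <- function(taxon, n, mean13C, mean15N, sd13C = 0, sd15N = 0,
                       rho = 0, status = "native") {
  stopifnot(is.character(taxon), length(taxon) == 1L)
  if (!is_number(n) || n < 1) {
    abort("n must be >= 1", class = "isoforecast_spec_error")
  }
  if (!is_number(sd13C) || !is_number(sd15N) || sd13C < 0 || sd15N < 0) {
    abort("SDs must be finite and >= 0", class = "isoforecast_spec_error")
  }
  if (!is_number(rho) || abs(rho) > 1) {
    abort("rho must lie in [-1, 1]", class = "isoforecast_spec_error")
  }
  structure(list(taxon = taxon, n = as.integer(n), mean13C = mean13C,
                 mean15N = mean15N, sd13C = sd13C, sd15N = sd15N,
                 rho = rho, status = status),
            class = "group_spec")
}

#' Draw one synthetic group
#'
#' `n` bivariate-normal individuals with the spec's moments. Identical
#' seeds give identical draws.
#'
#' @param spec A [group_spec()].
#' @param seed Integer seed.
#' @return Tibble of measurements (see [community()]).
#' @export
generate_group <- function(spec, seed) {
  stopifnot(inherits(spec, "group_spec"))
  Sigma <- matrix(c(spec$sd13C^2,
                    spec$rho * spec$sd13C * spec$sd15N,
                    spec$rho * spec$sd13C * spec$sd15N,
                    spec$sd15N^2), 2, 2)
  xy <- with_seed(seed, MASS::mvrnorm(spec$n,
                                      mu = c(spec$mean13C, spec$mean15N),
                                      Sigma = Sigma))
  xy <- matrix(xy, ncol = 2)
  tibble::tibble(
    taxon = spec$taxon, group = NA_character_, status = spec$status,
    d13C = xy[, 1], d15N = xy[, 2],
    total_length = NA_real_, weight = NA_real_
  )
}

#' Specify a synthetic consumer
#'
#' Forward model of the mixing likelihood: a consumer eating the given
#' sources in fixed proportions, with trophic discrimination applied and
#' an optional residual spread.
#'
#' @param sources List of [group_spec()]s, one per prey source.
#' @param proportions Numeric simplex vector over sources (sums to 1).
#' @param tdf A [tdf_spec()]; its means/SDs enter the consumer mean and
#'   variance.
#' @param resid_sd13C,resid_sd15N Residual SDs (per-mil).
#' @param n Number of consumers.
#' @param taxon Consumer label.
#' @return A `consumer_spec` list.
#' @export
consumer_spec <- function(sources, proportions, tdf = tdf_spec(),
                          resid_sd13C = 0, resid_sd15N = 0, n = 1,
                          taxon = "consumer") {
  stopifnot(is.list(sources), length(sources) >= 1L)
  if (length(proportions) != length(sources)) {
    abort("proportions must have one entry per source",
          class = "isoforecast_spec_error")
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
    abort("proportions must be nonnegative and sum to 1 within 1e-9",
          class = "isoforecast_spec_error")
  }
  if (!is_number(n) || n < 1) {
    abort("n must be >= 1", class = "isoforecast_spec_error")
  }
  structure(list(sources = sources, proportions = proportions, tdf = tdf,
                 resid_sd13C = resid_sd13C, resid_sd15N = resid_sd15N,
                 n = as.integer(n), taxon = taxon),
            class = "consumer_spec")
}

#' Draw synthetic consumers from known diet proportions
#'
#' For each isotope j the consumer value is drawn from
#' \deqn{N\big(\sum_k p_k(\mu_{kj} + \Delta_j),\;
#'   \sqrt{\sum_k p_k^2(\sigma_{kj}^2 + \tau_j^2) + \sigma_{resid,j}^2}\big)}
#' where \eqn{\Delta_j}/\eqn{\tau_j} are the TDF mean/SD for isotope j.
#'
#' @param spec A [consumer_spec()].
#' @param seed Integer seed.
#' @return Tibble of consumer measurements.
#' @export
generate_consumer <- function(spec, seed) {
  stopifnot(inherits(spec, "consumer_spec"))
  p <- spec$proportions
  mu13 <- vapply(spec$sources, `[[`, 0, "mean13C")
  mu15 <- vapply(spec$sources, `[[`, 0, "mean15N")
  sd13 <- vapply(spec$sources, `[[`, 0, "sd13C")
  sd15 <- vapply(spec$sources, `[[`, 0, "sd15N")
  tdf <- spec$tdf
  m13 <- sum(p * (mu13 + tdf$meanDeltaC))
  m15 <- sum(p * (mu15 + tdf$meanDeltaN))
  s13 <- sqrt(sum(p^2 * (sd13^2 + tdf$sdDeltaC^2)) + spec$resid_sd13C^2)
  s15 <- sqrt(sum(p^2 * (sd15^2 + tdf$sdDeltaN^2)) + spec$resid_sd15N^2)
  xy <- with_seed(seed, cbind(rnorm(spec$n, m13, s13),
                              rnorm(spec$n, m15, s15)))
  tibble::tibble(
    taxon = spec$taxon, group = NA_character_, status = "hypothetical",
    d13C = xy[, 1], d15N = xy[, 2],
    total_length = NA_real_, weight = NA_real_
  )
}

#' Assemble a synthetic community
#'
#' Draws every group (each on its own seed stream derived from `seed`, so
#' one group's draws do not change when another group's `n` does) and
#' attaches baseline role labels.
#'
#' @param specs List of [group_spec()]s with unique taxon labels.
#' @param baseline_roles Named list mapping at least two baseline roles to
#'   taxon labels present in `specs`.
#' @param seed Integer seed.
#' @return A [community()].
#' @export
generate_community <- function(specs, baseline_roles, seed) {
  taxa <- vapply(specs, `[[`, "", "taxon")
  if (anyDuplicated(taxa)) {
    abort("duplicate taxon labels in specs",
          class = "isoforecast_validation_error")
  }
  if (length(baseline_roles) < 2L) {
    abort("at least two baseline roles must be assigned",
          class = "isoforecast_config_error")
  }
  missing <- setdiff(unlist(baseline_roles), taxa)
  if (length(missing)) {
    abort(paste0("baseline role label(s) not among spec taxa: ",
                 paste(missing, collapse = ", ")),
          class = "isoforecast_config_error")
  }
  ms <- purrr::imap(specs, function(sp, i) {
    generate_group(sp, seed = child_seed(seed, i))
  })
  community(measurements = dplyr::bind_rows(ms),
            baselines = baseline_roles)
}

#' Group specs mirroring the packaged lake community
#'
#' Builds a list of [group_spec()]s from the `iznik_community` fixture's
#' means and SDs (18 groups). Missing SDs are replaced by `sd_fill`.
#'
#' @param sd_fill SD (per-mil) substituted where the fixture reports none.
#' @param rho Common isotope correlation for all groups.
#' @return List of [group_spec()]s.
#' @export
iznik_group_specs <- function(sd_fill = 1, rho = 0) {
  s <- load_fixture("iznik_community")$summaries
  purrr::pmap(
    list(s$taxon, s$n, s$mean13C, s$sd13C, s$mean15N, s$sd15N, s$status),
    function(taxon, n, m13, sd13, m15, sd15, status) {
      group_spec(taxon = taxon, n = n, mean13C = m13, mean15N = m15,
                 sd13C = ifelse(is.na(sd13), sd_fill, sd13),
                 sd15N = ifelse(is.na(sd15), sd_fill, sd15),
                 rho = rho, status = ifelse(is.na(status), "native", status))
    }
  )
}

#' Simulate pseudo-individuals from group summaries
#'
#' Reconstructs bivariate-normal individuals for each summary row of a
#' community (or summary tibble), using the reported n, means and SDs.
#' With `exact = TRUE` (the default) the draws are affinely rescaled so
#' that their sample mean and SD equal the reported values exactly:
#' a published summary table gives the observed sample moments, so
#' pseudo-data conditioned on them reproduce the table rather than adding
#' a second layer of sampling noise on top of it. Set `exact = FALSE`
#' for plain random draws. Rows with a missing SD use `sd_fill`; rows
#' with missing n use `n_default`.
#'
#' @param x A [community()] or summary tibble.
#' @param seed Integer seed.
#' @param n_per_group Optional common n overriding the per-row n.
#' @param n_default n used where the summary reports none.
#' @param sd_fill SD (per-mil) used where the summary reports none.
#' @param rho Isotope correlation used for all groups.
#' @param taxa Optional character vector restricting which taxa to draw.
#' @param exact Match the reported moments exactly (see above).
#' @return Tibble of simulated measurements.
#' @export
simulate_from_summaries <- function(x, seed, n_per_group = NULL,
                                    n_default = 10, sd_fill = 1, rho = 0,
                                    taxa = NULL, exact = TRUE) {
  s <- if (inherits(x, "community")) x$summaries else normalize_summaries(x)
  if (!is.null(taxa)) s <- dplyr::filter(s, .data$taxon %in% taxa)
  if (nrow(s) == 0L) {
    abort("no summary rows to simulate from",
          class = "isoforecast_validation_error")
  }
  rows <- purrr::map(seq_len(nrow(s)), function(i) {
    r <- s[i, ]
    n <- n_per_group %||% (if (is.na(r$n)) n_default else r$n)
    sp <- group_spec(
      taxon = r$taxon, n = n, mean13C = r$mean13C, mean15N = r$mean15N,
      sd13C = if (is.na(r$sd13C)) sd_fill else r$sd13C,
      sd15N = if (is.na(r$sd15N)) sd_fill else r$sd15N,
      rho = rho,
      status = if (is.na(r$status)) "native" else r$status
    )
    out <- generate_group(sp, seed = child_seed(seed, i))
    if (exact) {
      out[, c("d13C", "d15N")] <- match_moments(
        cbind(out$d13C, out$d15N),
        mu = c(sp$mean13C, sp$mean15N),
        sds = c(sp$sd13C, sp$sd15N), rho = sp$rho)
    }
    out$group <- r$group
    out
  })
  dplyr::bind_rows(rows)
}

# Affinely rescale a two-column sample so its sample mean equals mu and
# its sample covariance equals the target (SDs + correlation). Falls back
# to per-axis scaling when n < 3 and to the mean point when an SD is 0.
match_moments <- function(x, mu, sds, rho = 0) {
  n <- nrow(x)
  if (n == 1L || all(sds == 0)) {
    return(matrix(mu, nrow = n, ncol = 2, byrow = TRUE))
  }
  centered <- sweep(x, 2, colMeans(x))
  if (n == 2L || any(sds == 0)) {
    for (j in 1:2) {
      s <- sd(x[, j])
      centered[, j] <- if (s > 0) centered[, j] * (sds[j] / s) else 0
    }
    return(sweep(centered, 2, mu, `+`))
  }
  S_emp <- cov(x)
  S_tgt <- matrix(c(sds[1]^2, rho * sds[1] * sds[2],
                    rho * sds[1] * sds[2], sds[2]^2), 2, 2)
  A <- t(chol(S_tgt)) %*% solve(t(chol(S_emp)))
  sweep(centered %*% t(A), 2, mu, `+`)
}
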