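#' Trophic discrimination factor specification
#'
#' Per-trophic-step isotopic enrichment between diet and consumer tissue,
#' treated as stochastic: each model iteration draws a fresh
#' \eqn{\Delta}N and \eqn{\Delta}C from these normal distributions.
#' Defaults are the canonical muscle/whole-organism literature values
#' (\eqn{\Delta}N = 3.4 +/- 0.98 per-mil, \eqn{\Delta}C = 0.39 +/- 1.3
#' per-mil per trophic step); both are configurable.
#'
#' @param meanDeltaN,sdDeltaN Nitrogen TDF mean and SD (per-mil/step).
#' @param meanDeltaC,sdDeltaC Carbon TDF mean and SD (per-mil/step).
#' @param nsim Number of draws produced by [simulate_tdf()].
#' @return A `tdf_spec` list.
#' @export
tdf_spec <- function(meanDeltaN = 3.4, sdDeltaN = 0.98,
                     meanDeltaC = 0.39, sdDeltaC = 1.3,
                     nsim = 10000) {
  if (sdDeltaN < 0 || sdDeltaC < 0) {
    abort("TDF SDs must be >= 0", class = "isoforecast_spec_error")
  }
  if (!is_number(nsim) || nsim < 1) {
    abort("nsim must be >= 1", class = "isoforecast_spec_error")
  }
  structure(list(meanDeltaN = meanDeltaN, sdDeltaN = sdDeltaN,
                 meanDeltaC = meanDeltaC, sdDeltaC = sdDeltaC,
                 nsim = as.integer(nsim)),
            class = "tdf_spec")
}

#' Simulate trophic discrimination factors
#'
#' `nsim` normal draws per isotope with the spec's moments, as a tibble
#' with columns `deltaN` and `deltaC`.
#'
#' @param spec A [tdf_spec()].
#' @param seed Integer seed.
#' @return Tibble of TDF draws.
#' @export
simulate_tdf <- function(spec = tdf_spec(), seed = NULL) {
  stopifnot(inherits(spec, "tdf_spec"))
  with_seed(seed, tibble::tibble(
    deltaN = rnorm(spec$nsim, spec$meanDeltaN, spec$sdDeltaN),
    deltaC = rnorm(spec$nsim, spec$meanDeltaC, spec$sdDeltaC)
  ))
}

#' Two-baseline specification
#'
#' Resolves two baseline roles against a community's group summaries.
#' Each baseline may pool several taxa (e.g. phyto- and zooplankton as a
#' single pelagic baseline): pooled means are unweighted averages, pooled
#' SDs root-mean-square, pooled n the total. `lambda` is the trophic
#' level assigned to the baselines (default 2, primary consumers).
#'
#' @param community A [community()], or `NULL` when `b1`/`b2` are given
#'   explicitly as lists.
#' @param b1,b2 Character vectors of taxon labels resolved against the
#'   community (default: its `baseline1`/`baseline2` roles), or lists with
#'   elements `label`, `mean15N`, `sd15N`, `mean13C`, `sd13C`, `n`.
#' @param lambda Baseline trophic level (>= 1).
#' @return A `baseline_spec` list with elements `b1`, `b2`, `lambda`.
#' @export
baseline_spec <- function(community = NULL, b1 = NULL, b2 = NULL,
                          lambda = 2) {
  if (!is_number(lambda) || lambda < 1) {
    abort("lambda must be >= 1", class = "isoforecast_spec_error")
  }
  if (inherits(community, "community")) {
    b1 <- b1 %||% community$baselines$baseline1
    b2 <- b2 %||% community$baselines$baseline2
  }
  if (is.null(b1) || is.null(b2)) {
    abort("both baselines must be given (labels or explicit lists)",
          class = "isoforecast_config_error")
  }
  resolve <- function(b) {
    if (is.list(b)) {
      needed <- c("mean15N", "mean13C")
      if (!all(needed %in% names(b))) {
        abort("explicit baselines need mean15N and mean13C",
              class = "isoforecast_config_error")
      }
      return(list(label = b$label %||% "baseline",
                  mean15N = b$mean15N, sd15N = b$sd15N %||% NA_real_,
                  mean13C = b$mean13C, sd13C = b$sd13C %||% NA_real_,
                  n = b$n %||% NA_real_))
    }
    pool_summaries(community, b)
  }
  out <- structure(list(b1 = resolve(b1), b2 = resolve(b2),
                        lambda = lambda),
                   class = "baseline_spec")
  if (isTRUE(all.equal(out$b1$mean13C, out$b2$mean13C))) {
    abort("baselines have identical mean d13C: alpha is not identifiable",
          class = "isoforecast_identifiability_error")
  }
  out
}

pool_summaries <- function(community, taxa) {
  if (!inherits(community, "community")) {
    abort("a community is required to resolve baseline labels",
          class = "isoforecast_config_error")
  }
  s <- dplyr::filter(community$summaries, .data$taxon %in% taxa)
  if (nrow(s) < length(unique(taxa))) {
    abort(paste0("baseline taxa not found in community: ",
                 paste(setdiff(taxa, s$taxon), collapse = ", ")),
          class = "isoforecast_config_error")
  }
  list(
    label = paste(s$taxon, collapse = " + "),
    mean15N = mean(s$mean15N),
    sd15N = if (all(is.na(s$sd15N))) NA_real_ else rms(s$sd15N[!is.na(s$sd15N)]),
    mean13C = mean(s$mean13C),
    sd13C = if (all(is.na(s$sd13C))) NA_real_ else rms(s$sd13C[!is.na(s$sd13C)]),
    n = sum(s$n, na.rm = TRUE)
  )
}

#' Deterministic two-baseline trophic position
#'
#' Closed-form oracle for the two-baseline model:
#' \deqn{\alpha = (\delta^{13}C_c - \delta^{13}C_{b2}) /
#'   (\delta^{13}C_{b1} - \delta^{13}C_{b2})} clipped to `[0, 1]`, and
#' \deqn{TP = \lambda + (\delta^{15}N_c - (\alpha\,\delta^{15}N_{b1} +
#'   (1-\alpha)\,\delta^{15}N_{b2})) / \Delta N.}
#'
#' @param consumer Either a length-2 numeric `c(d13C, d15N)` or a tibble
#'   of measurements (its means are used).
#' @param baselines A [baseline_spec()].
#' @param deltaN Nitrogen enrichment per trophic step (> 0, per-mil).
#' @param lambda Baseline trophic level; defaults to the spec's.
#' @return One-row tibble with columns `tp` and `alpha`.
#' @export
tp_point_estimate <- function(consumer, baselines, deltaN = 3.4,
                              lambda = NULL) {
  stopifnot(inherits(baselines, "baseline_spec"))
  if (!is_number(deltaN) || deltaN <= 0) {
    abort("deltaN must be > 0", class = "isoforecast_domain_error")
  }
  lambda <- lambda %||% baselines$lambda
  xy <- consumer_means(consumer)
  alpha <- (xy[["d13C"]] - baselines$b2$mean13C) /
    (baselines$b1$mean13C - baselines$b2$mean13C)
  alpha <- min(max(alpha, 0), 1)
  base15N <- alpha * baselines$b1$mean15N +
    (1 - alpha) * baselines$b2$mean15N
  tibble::tibble(tp = lambda + (xy[["d15N"]] - base15N) / deltaN,
                 alpha = alpha)
}

consumer_means <- function(consumer) {
  if (is.numeric(consumer) && length(consumer) == 2L) {
    if (is.null(names(consumer))) names(consumer) <- c("d13C", "d15N")
    return(consumer[c("d13C", "d15N")])
  }
  m <- tibble::as_tibble(consumer)
  c(d13C = mean(m$d13C), d15N = mean(m$d15N))
}

#' MCMC chain configuration
#'
#' @param chains Number of chains.
#' @param iter Post-burn-in iterations kept per chain.
#' @param burn Burn-in (adaptation) iterations per chain.
#' @param thin Thinning interval.
#' @return An `mcmc_control` list.
#' @export
mcmc_control <- function(chains = 4, iter = 10000, burn = 2000, thin = 1) {
  stopifnot(chains >= 1, iter >= 1, burn >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burn = as.integer(burn), thin = as.integer(thin)),
            class = "mcmc_control")
}

#' Fit the Bayesian two-baseline trophic-position model
#'
#' Posterior over trophic position TP, baseline-1 mixing proportion
#' \eqn{\alpha} and per-isotope residual SDs, given individual consumer
#' isotope values and two baselines. Likelihood per consumer i:
#' \deqn{\delta^{15}N_i \sim N(\alpha b1_N + (1-\alpha) b2_N +
#'   \Delta N (TP - \lambda),\ \sigma_N)}
#' \deqn{\delta^{13}C_i \sim N(\alpha b1_C + (1-\alpha) b2_C +
#'   \Delta C (TP - \lambda),\ \sigma_C)}
#' with \eqn{\Delta N, \Delta C} and the four baseline means treated as
#' latent parameters, re-drawn every MCMC iteration under their own
#' priors: the TDF normals, and the baseline sampling distributions
#' (SD/sqrt(n), or SD as-is for n < 3). Baseline and TDF uncertainty
#' thereby propagates into the posterior.
#' Priors: TP ~ Uniform(lambda, 10), alpha ~ Beta(1, 1),
#' sigma ~ half-normal(scale 5 per-mil). Sampling is adaptive random-walk
#' Metropolis-within-Gibbs on transformed parameters, adaptation during
#' burn-in only.
#'
#' @param consumer Tibble of consumer measurements (columns `d13C`,
#'   `d15N`), one row per individual.
#' @param baselines A [baseline_spec()].
#' @param tdf A [tdf_spec()].
#' @param lambda Baseline trophic level; defaults to the spec's.
#' @param mcmc An [mcmc_control()].
#' @param seed Integer seed (one stream per chain).
#' @return A `tp_fit` with `$draws` (tibble: chain, iteration, tp, alpha,
#'   sigmaN, sigmaC) and `$diagnostics` (acceptance rates, split-chain
#'   R-hat; R-hat > 1.1 is flagged, not fatal).
#' @export
fit_two_baseline_tp <- function(consumer, baselines, tdf = tdf_spec(),
                                lambda = NULL, mcmc = mcmc_control(),
                                seed = 1) {
  stopifnot(inherits(baselines, "baseline_spec"),
            inherits(tdf, "tdf_spec"), inherits(mcmc, "mcmc_control"))
  m <- tibble::as_tibble(consumer)
  yC <- m$d13C
  yN <- m$d15N
  nc <- length(yN)
  if (nc < 1) {
    abort("at least one consumer measurement is required",
          class = "isoforecast_validation_error")
  }
  if (nc < 2) {
    warn("fitting a trophic position from a single consumer measurement")
  }
  lambda <- lambda %||% baselines$lambda

  b1 <- baselines$b1
  b2 <- baselines$b2
  se_of <- function(b, which) {
    sd <- b[[paste0("sd", which)]]
    if (is.na(sd)) return(0)
    n <- b$n
    if (is.na(n) || n < 3) sd else sd / sqrt(n)
  }
  se1N <- se_of(b1, "15N"); se2N <- se_of(b2, "15N")
  se1C <- se_of(b1, "13C"); se2C <- se_of(b2, "13C")

  # initial values from the closed-form oracle
  pe <- tp_point_estimate(c(d13C = mean(yC), d15N = mean(yN)), baselines,
                          deltaN = max(tdf$meanDeltaN, 0.1),
                          lambda = lambda)
  tp0 <- min(max(pe$tp, lambda + 0.05), 10 - 0.05)
  a0 <- min(max(pe$alpha, 0.02), 0.98)
  sN0 <- max(if (nc > 1) sd(yN) else 1, 0.2)
  sC0 <- max(if (nc > 1) sd(yC) else 1, 0.2)

  total <- mcmc$burn + mcmc$iter * mcmc$thin
  sigma_min <- 1e-6
  chains <- purrr::map(seq_len(mcmc$chains), function(ch) {
    run_tp_chain(
      yN = yN, yC = yC, lambda = lambda, tdf = tdf,
      b = list(m1N = b1$mean15N, m2N = b2$mean15N,
               m1C = b1$mean13C, m2C = b2$mean13C,
               se1N = se1N, se2N = se2N, se1C = se1C, se2C = se2C),
      init = c((tp0 - lambda) * max(tdf$meanDeltaN, 0.1),
               qlogis(a0), log(sN0), log(sC0)),
      total = total, burn = mcmc$burn, thin = mcmc$thin,
      sigma_min = sigma_min, seed = child_seed(seed, ch), chain_id = ch
    )
  })
  draws <- dplyr::bind_rows(purrr::map(chains, "draws"))
  accept <- colMeans(do.call(rbind, purrr::map(chains, "accept")))
  rhat <- c(tp = split_rhat(draws$tp, draws$chain),
            alpha = split_rhat(draws$alpha, draws$chain))
  if (any(is.finite(rhat) & rhat > 1.1)) {
    warn(paste0("chains may not have converged (split R-hat > 1.1 for ",
                paste(names(rhat)[is.finite(rhat) & rhat > 1.1],
                      collapse = ", "), ")"))
  }
  structure(
    list(draws = draws,
         diagnostics = list(accept = accept, rhat = rhat,
                            converged = all(!is.finite(rhat) | rhat <= 1.1)),
         baselines = baselines, tdf = tdf, lambda = lambda,
         n_consumers = nc, seed = seed, mcmc = mcmc),
    class = "tp_fit"
  )
}

run_tp_chain <- function(yN, yC, lambda, tdf, b, init, total, burn, thin,
                         sigma_min, seed, chain_id) {
  nc <- length(yN)
  # Coordinates: 1 nitrogen enrichment eN = deltaN * (TP - lambda)
  # (directly informed by the likelihood, so the TP / deltaN ridge is
  # traversed efficiently), 2 logit-alpha, 3-4 log-sigmas, 5-6 TDF
  # deltaN/deltaC, 7-10 baseline means. TP = lambda + eN / deltaN.
  # The uniform prior on TP contributes a 1/deltaN Jacobian.
  nuis_mean <- c(tdf$meanDeltaN, tdf$meanDeltaC,
                 b$m1N, b$m2N, b$m1C, b$m2C)
  nuis_sd <- c(tdf$sdDeltaN, tdf$sdDeltaC,
               b$se1N, b$se2N, b$se1C, b$se2C)
  free_nuis <- which(nuis_sd > 0) + 4L
  tp_max <- 10
  loglik <- function(u) {
    a <- plogis(u[2])
    sN <- sigma_min + exp(u[3])
    sC <- sigma_min + exp(u[4])
    tpw <- u[1] / u[5]
    muN <- a * u[7] + (1 - a) * u[8] + u[1]
    muC <- a * u[9] + (1 - a) * u[10] + u[6] * tpw
    -nc * log(sN) - sum((yN - muN)^2) / (2 * sN^2) -
      nc * log(sC) - sum((yC - muC)^2) / (2 * sC^2)
  }
  logprior <- function(u) {
    # support: deltaN > 0 and TP = lambda + eN/deltaN within its prior box
    if (u[5] <= 0) return(-Inf)
    tpw <- u[1] / u[5]
    if (tpw < 0 || tpw > tp_max - lambda) return(-Inf)
    sN <- sigma_min + exp(u[3])
    sC <- sigma_min + exp(u[4])
    lp <- log(plogis(u[2])) + log(1 - plogis(u[2])) -
      (sN^2 + sC^2) / (2 * 25) + u[3] + u[4] - log(u[5])
    for (j in free_nuis) {
      lp <- lp - (u[j] - nuis_mean[j - 4L])^2 / (2 * nuis_sd[j - 4L]^2)
    }
    lp
  }
  with_seed(seed, {
    u <- c(init, nuis_mean)
    coords <- c(1:4, free_nuis)
    scales <- c(rep(0.5, 4), pmax(nuis_sd, 0.01))
    acc_count <- rep(0, 10)
    prop_count <- rep(0, 10)
    kept <- matrix(NA_real_, nrow = (total - burn) %/% thin, ncol = 6)
    k <- 0L
    lp <- loglik(u) + logprior(u)
    for (t in seq_len(total)) {
      for (j in coords) {
        u_new <- u
        u_new[j] <- u[j] + rnorm(1, 0, scales[j])
        lpr_new <- logprior(u_new)
        lp_new <- if (is.finite(lpr_new)) loglik(u_new) + lpr_new else -Inf
        acc <- is.finite(lp_new) && log(runif(1)) < (lp_new - lp)
        if (acc) {
          u <- u_new
          lp <- lp_new
        }
        prop_count[j] <- prop_count[j] + 1
        if (acc) acc_count[j] <- acc_count[j] + 1
        if (t <= burn) {
          gamma <- min(0.1, 5 / sqrt(t + 10))
          scales[j] <- exp(log(scales[j]) +
                             gamma * ((if (acc) 1 else 0) - 0.44))
        }
      }
      if (t > burn && (t - burn) %% thin == 0L) {
        k <- k + 1L
        kept[k, ] <- u[c(1:4, 5, 6)]
      }
    }
    list(
      draws = tibble::tibble(
        chain = chain_id, iteration = seq_len(k),
        tp = lambda + kept[, 1] / kept[, 5],
        alpha = plogis(kept[, 2]),
        sigmaN = sigma_min + exp(kept[, 3]),
        sigmaC = sigma_min + exp(kept[, 4]),
        deltaN = kept[, 5], deltaC = kept[, 6]
      ),
      accept = acc_count[coords] / pmax(prop_count[coords], 1)
    )
  })
}

# Split-chain potential scale reduction factor.
split_rhat <- function(x, chain) {
  halves <- split(x, chain)
  halves <- unlist(lapply(halves, function(v) {
    h <- length(v) %/% 2L
    if (h < 2L) return(list(v))
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  if (m < 2L || n < 2L) return(NA_real_)
  halves <- lapply(halves, function(v) v[seq_len(n)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
posterior_draws.tp_fit <- function(x) {
  as.matrix(x$draws[, c("tp", "alpha", "sigmaN", "sigmaC")])
}

#' @exportS3Method generics::tidy
tidy.tp_fit <- function(x, conf_level = 0.95, ...) {
  draws <- posterior_draws(x)
  lo <- (1 - conf_level) / 2
  tibble::tibble(
    term = colnames(draws),
    estimate = unname(apply(draws, 2, median)),
    mean = unname(colMeans(draws)),
    std.error = unname(apply(draws, 2, sd)),
    conf.low = unname(apply(draws, 2, quantile, probs = lo, names = FALSE)),
    conf.high = unname(apply(draws, 2, quantile, probs = 1 - lo,
                             names = FALSE))
  )
}

#' @exportS3Method generics::glance
glance.tp_fit <- function(x, ...) {
  tibble::tibble(
    n_consumers = x$n_consumers,
    n_draws = nrow(x$draws),
    n_chains = x$mcmc$chains,
    rhat_tp = unname(x$diagnostics$rhat["tp"]),
    rhat_alpha = unname(x$diagnostics$rhat["alpha"]),
    accept_rate = mean(x$diagnostics$accept),
    converged = x$diagnostics$converged
  )
}

#' @export
print.tp_fit <- function(x, ...) {
  cat("<tp_fit>", x$n_consumers, "consumers,", nrow(x$draws),
      "posterior draws\n")
  cat("  posterior median TP:",
      round(median(x$draws$tp), 3),
      " alpha:", round(median(x$draws$alpha), 3), "\n")
  invisible(x)
}
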