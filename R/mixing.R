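#' Candidate prey source set
#'
#' Per-source isotope means, SDs and sample sizes for a mixing model,
#' built from a community's group summaries (or any summary tibble).
#' Missing SDs are treated as 0 (a fixed source signature).
#'
#' @param x A [community()] or summary tibble.
#' @param taxa Optional character vector restricting/ordering the sources.
#' @return A `source_set` tibble with columns `label`, `mean13C`, `sd13C`,
#'   `mean15N`, `sd15N`, `n`.
#' @export
source_set <- function(x, taxa = NULL) {
  s <- if (inherits(x, "community")) x$summaries else normalize_summaries(x)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, s$taxon)
    if (length(missing)) {
      abort(paste0("source taxa not in summaries: ",
                   paste(missing, collapse = ", ")),
            class = "isoforecast_config_error")
    }
    s <- s[match(taxa, s$taxon), ]
  }
  out <- tibble::tibble(
    label = s$taxon,
    mean13C = s$mean13C,
    sd13C = dplyr::coalesce(s$sd13C, 0),
    mean15N = s$mean15N,
    sd15N = dplyr::coalesce(s$sd15N, 0),
    n = s$n
  )
  class(out) <- c("source_set", class(out))
  out
}

#' Fit a Bayesian stable-isotope mixing model
#'
#' Posterior diet proportions of a consumer over K prey sources. For each
#' consumer i and isotope j the likelihood is
#' \deqn{y_{ij} \sim N\Big(\sum_k p_k(\mu_{kj} + \Delta_j),\
#'   \sqrt{\textstyle\sum_k p_k^2(\sigma_{kj}^2 + \tau_j^2) +
#'   \sigma_j^2}\Big)}
#' with the TDF \eqn{(\Delta_j, \tau_j)} applied uniformly to all sources
#' and \eqn{\Delta_j} re-drawn each iteration. The proportion vector is
#' parameterised by independent standard-normal latent variables mapped
#' through softmax (weakly informative, strictly interior to the
#' simplex); residual SDs get half-normal(scale 2 per-mil) priors.
#' Sampling: adaptive Metropolis on the latent vector plus
#' Metropolis-within-Gibbs on the residual SDs.
#'
#' @param consumer Tibble of consumer measurements (`d13C`, `d15N`).
#' @param sources A [source_set()] (K >= 1 sources).
#' @param tdf A [tdf_spec()].
#' @param mcmc An [mcmc_control()].
#' @param seed Integer seed.
#' @param prior_only If `TRUE` the consumer likelihood is disabled and
#'   the prior on the simplex is sampled (useful for prior checks).
#' @return A `diet_fit` with `$p_draws` (draws x K matrix, rows on the
#'   simplex), `$sigma_draws`, `$source_labels` and `$diagnostics`.
#' @export
fit_mixing_model <- function(consumer, sources, tdf = tdf_spec(),
                             mcmc = mcmc_control(), seed = 1,
                             prior_only = FALSE) {
  stopifnot(inherits(tdf, "tdf_spec"), inherits(mcmc, "mcmc_control"))
  if (!inherits(sources, "source_set")) sources <- source_set(sources)
  m <- tibble::as_tibble(consumer)
  yC <- m$d13C
  yN <- m$d15N
  nc <- length(yN)
  if (nc < 1 && !prior_only) {
    abort("at least one consumer measurement is required",
          class = "isoforecast_validation_error")
  }
  K <- nrow(sources)
  labels <- sources$label
  ndraw_total <- mcmc$chains * mcmc$iter

  if (K < 2L) {
    p_draws <- matrix(1, nrow = ndraw_total, ncol = 1,
                      dimnames = list(NULL, labels))
    return(structure(
      list(p_draws = p_draws,
           sigma_draws = tibble::tibble(sigmaN = rep(0, ndraw_total),
                                        sigmaC = rep(0, ndraw_total)),
           source_labels = labels,
           chain = rep(seq_len(mcmc$chains), each = mcmc$iter),
           diagnostics = list(degenerate = TRUE, rhat_max = NA_real_,
                              accept = NA_real_),
           warnings = character(), mcmc = mcmc, seed = seed),
      class = "diet_fit"
    ))
  }

  warnings <- character()
  if (all(abs(sources$mean13C - sources$mean13C[1]) < 1e-12) &&
      all(abs(sources$mean15N - sources$mean15N[1]) < 1e-12)) {
    warnings <- c(warnings,
                  "all sources share identical means: proportions are not identifiable")
    warn(warnings[length(warnings)])
  }

  mu13 <- sources$mean13C
  mu15 <- sources$mean15N
  v13 <- sources$sd13C^2
  v15 <- sources$sd15N^2

  chains <- purrr::map(seq_len(mcmc$chains), function(ch) {
    run_mixing_chain(yN, yC, mu15, mu13, v15, v13, tdf, mcmc,
                     prior_only = prior_only,
                     seed = child_seed(seed, 100 + ch), chain_id = ch)
  })
  p_draws <- do.call(rbind, purrr::map(chains, "p"))
  colnames(p_draws) <- labels
  sigma_draws <- dplyr::bind_rows(purrr::map(chains, "sigma"))
  chain_id <- rep(seq_len(mcmc$chains), each = mcmc$iter)
  rhats <- vapply(seq_len(K), function(k) {
    split_rhat(p_draws[, k], chain_id)
  }, 0)
  structure(
    list(p_draws = p_draws, sigma_draws = sigma_draws,
         source_labels = labels, chain = chain_id,
         diagnostics = list(degenerate = FALSE,
                            rhat_max = suppressWarnings(max(rhats, na.rm = TRUE)),
                            accept = mean(unlist(purrr::map(chains, "accept")))),
         warnings = warnings, mcmc = mcmc, seed = seed),
    class = "diet_fit"
  )
}

run_mixing_chain <- function(yN, yC, mu15, mu13, v15, v13, tdf, mcmc,
                             prior_only, seed, chain_id) {
  K <- length(mu15)
  nc <- length(yN)
  softmax <- function(z) {
    e <- exp(z - max(z))
    e / sum(e)
  }
  loglik <- function(z, sN, sC, dN, dC) {
    if (prior_only || nc == 0L) return(0)
    p <- softmax(z)
    muN <- sum(p * (mu15 + dN))
    muC <- sum(p * (mu13 + dC))
    varN <- sum(p^2 * (v15 + tdf$sdDeltaN^2)) + sN^2
    varC <- sum(p^2 * (v13 + tdf$sdDeltaC^2)) + sC^2
    -0.5 * nc * log(varN) - sum((yN - muN)^2) / (2 * varN) -
      0.5 * nc * log(varC) - sum((yC - muC)^2) / (2 * varC)
  }
  total <- mcmc$burn + mcmc$iter * mcmc$thin
  with_seed(seed, {
    z <- rnorm(K, 0, 0.1)
    lsig <- c(log(1), log(1))
    scale_z <- 0.4
    scale_s <- c(0.5, 0.5)
    acc_z <- 0
    dN <- tdf$meanDeltaN
    dC <- tdf$meanDeltaC
    kp <- matrix(NA_real_, nrow = mcmc$iter, ncol = K)
    ks <- matrix(NA_real_, nrow = mcmc$iter, ncol = 2)
    k <- 0L
    logprior_z <- function(z) -0.5 * sum(z^2)
    logprior_s <- function(ls) {
      s <- exp(ls)
      sum(-s^2 / (2 * 4) + ls)
    }
    for (t in seq_len(total)) {
      dN <- rnorm(1, tdf$meanDeltaN, tdf$sdDeltaN)
      dC <- rnorm(1, tdf$meanDeltaC, tdf$sdDeltaC)
      sN <- exp(lsig[1]); sC <- exp(lsig[2])
      lp <- loglik(z, sN, sC, dN, dC) + logprior_z(z) + logprior_s(lsig)
      # block update of the latent simplex vector
      z_new <- z + rnorm(K, 0, scale_z)
      lp_new <- loglik(z_new, sN, sC, dN, dC) + logprior_z(z_new) +
        logprior_s(lsig)
      acc <- is.finite(lp_new) && log(runif(1)) < (lp_new - lp)
      if (acc) {
        z <- z_new
        lp <- lp_new
      }
      acc_z <- acc_z + acc
      if (t <= burn_of(mcmc)) {
        gamma <- min(0.1, 5 / sqrt(t + 10))
        scale_z <- exp(log(scale_z) + gamma * ((if (acc) 1 else 0) - 0.234))
      }
      # residual SDs, one coordinate at a time
      for (j in 1:2) {
        ls_new <- lsig
        ls_new[j] <- lsig[j] + rnorm(1, 0, scale_s[j])
        lp_new <- loglik(z, exp(ls_new[1]), exp(ls_new[2]), dN, dC) +
          logprior_z(z) + logprior_s(ls_new)
        accs <- is.finite(lp_new) && log(runif(1)) < (lp_new - lp)
        if (accs) {
          lsig <- ls_new
          lp <- lp_new
        }
        if (t <= burn_of(mcmc)) {
          gamma <- min(0.1, 5 / sqrt(t + 10))
          scale_s[j] <- exp(log(scale_s[j]) +
                              gamma * ((if (accs) 1 else 0) - 0.44))
        }
      }
      if (t > mcmc$burn && (t - mcmc$burn) %% mcmc$thin == 0L) {
        k <- k + 1L
        kp[k, ] <- softmax(z)
        ks[k, ] <- exp(lsig)
      }
    }
    list(p = kp, sigma = tibble::tibble(sigmaN = ks[, 1], sigmaC = ks[, 2]),
         accept = acc_z / total)
  })
}

burn_of <- function(mcmc) mcmc$burn

#' Summarise a diet posterior
#'
#' Posterior mean, median and central credible intervals per source, in
#' descending posterior-mean order.
#'
#' @param posterior A `diet_fit`.
#' @param levels Credible levels (e.g. `c(0.5, 0.95)`).
#' @return Tibble with one row per source.
#' @export
summarize_diet <- function(posterior, levels = 0.95) {
  stopifnot(inherits(posterior, "diet_fit"))
  p <- posterior$p_draws
  if (is.null(p) || nrow(p) == 0L) {
    abort("empty posterior", class = "isoforecast_validation_error")
  }
  out <- tibble::tibble(
    source = colnames(p),
    mean = unname(colMeans(p)),
    median = unname(apply(p, 2, median))
  )
  for (lv in levels) {
    lo <- (1 - lv) / 2
    tag <- format(100 * lv, trim = TRUE)
    out[[paste0("lower_", tag)]] <-
      apply(p, 2, quantile, probs = lo, names = FALSE)
    out[[paste0("upper_", tag)]] <-
      apply(p, 2, quantile, probs = 1 - lo, names = FALSE)
  }
  dplyr::arrange(out, dplyr::desc(.data$mean))
}

#' Probability of each source being the top-ranked prey
#'
#' Fraction of posterior draws in which each source has the largest diet
#' proportion; the probabilities sum to 1.
#'
#' @param posterior A `diet_fit`.
#' @return Tibble with columns `source` and `prob_rank1`, descending.
#' @export
rank_stability <- function(posterior) {
  stopifnot(inherits(posterior, "diet_fit"))
  p <- posterior$p_draws
  if (is.null(p) || nrow(p) == 0L) {
    abort("empty posterior", class = "isoforecast_validation_error")
  }
  top <- max.col(p, ties.method = "first")
  counts <- tabulate(top, nbins = ncol(p))
  dplyr::arrange(
    tibble::tibble(source = colnames(p), prob_rank1 = counts / nrow(p)),
    dplyr::desc(.data$prob_rank1))
}

#' @export
posterior_draws.diet_fit <- function(x) {
  cbind(x$p_draws,
        sigmaN = x$sigma_draws$sigmaN,
        sigmaC = x$sigma_draws$sigmaC)
}

#' @exportS3Method generics::tidy
tidy.diet_fit <- function(x, levels = 0.95, ...) {
  summarize_diet(x, levels = levels)
}

#' @exportS3Method generics::glance
glance.diet_fit <- function(x, ...) {
  tibble::tibble(
    n_sources = length(x$source_labels),
    n_draws = nrow(x$p_draws),
    rhat_max = x$diagnostics$rhat_max,
    accept_rate = x$diagnostics$accept,
    degenerate = isTRUE(x$diagnostics$degenerate)
  )
}

#' @export
print.diet_fit <- function(x, ...) {
  cat("<diet_fit>", length(x$source_labels), "sources,",
      nrow(x$p_draws), "posterior draws\n")
  s <- summarize_diet(x)
  top <- utils::head(s, 3)
  cat("  top sources:",
      paste0(top$source, " (", round(top$mean, 2), ")", collapse = ", "),
      "\n")
  invisible(x)
}
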