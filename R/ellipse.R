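#' Maximum-likelihood standard ellipse of an isotope cloud
#'
#' Bivariate mean and sample covariance (n-1 denominator) of a group's
#' (d13C, d15N) values, with the standard ellipse area
#' \eqn{SEA = \pi\sqrt{\det\Sigma}} and its small-sample correction
#' \eqn{SEAc = SEA\,(n-1)/(n-2)}.
#'
#' @param samples Tibble of measurements (`d13C`, `d15N`), n >= 3.
#' @return An `ellipse_niche` with elements `mu`, `Sigma`, `n`, `sea`,
#'   `seac`.
#' @export
ml_ellipse <- function(samples) {
  m <- tibble::as_tibble(samples)
  x <- cbind(m$d13C, m$d15N)
  n <- nrow(x)
  if (n < 3) {
    abort("at least 3 samples are needed for an ellipse",
          class = "isoforecast_insufficient_data_error")
  }
  mu <- colMeans(x)
  Sigma <- cov(x)
  dt <- det(Sigma)
  if (dt <= .Machine$double.eps) {
    warn("degenerate (collinear) samples: ellipse area is 0")
    dt <- max(dt, 0)
  }
  sea <- pi * sqrt(dt)
  structure(
    list(mu = setNames(mu, c("d13C", "d15N")), Sigma = Sigma, n = n,
         sea = sea, seac = sea * (n - 1) / (n - 2)),
    class = "ellipse_niche"
  )
}

#' @export
print.ellipse_niche <- function(x, ...) {
  cat("<ellipse_niche> n =", x$n,
      " SEA =", signif(x$sea, 4),
      " SEAc =", signif(x$seac, 4), "per-mil^2\n")
  invisible(x)
}

# Conjugate normal-inverse-Wishart posterior for a bivariate group.
# Vague proper prior: prior mean = sample mean with weight kappa0 = 0.001,
# inverse-Wishart scale = 1e-3 * I (per-mil^2), df = 3.
niw_posterior <- function(x, kappa0 = 0.001, nu0 = 3,
                          Psi0 = diag(1e-3, 2)) {
  n <- nrow(x)
  xbar <- colMeans(x)
  S <- cov(x) * (n - 1)
  list(m = xbar, kappa = kappa0 + n, nu = nu0 + n, Psi = Psi0 + S)
}

# One draw of (mu, Sigma) from a normal-inverse-Wishart.
rniw <- function(post) {
  W <- rWishart(1, df = post$nu, Sigma = solve(post$Psi))[, , 1]
  Sigma <- solve(W)
  Sigma <- (Sigma + t(Sigma)) / 2
  L <- chol(Sigma / post$kappa)
  mu <- post$m + drop(t(L) %*% rnorm(2))
  list(mu = mu, Sigma = Sigma)
}

#' Bayesian standard ellipse area (SEAb)
#'
#' Draws (mu, Sigma) from the conjugate normal-inverse-Wishart posterior
#' under a vague proper prior (prior mean = sample mean with negligible
#' weight kappa0 = 0.001, inverse-Wishart scale 1e-3 I, df 3) and computes
#' the standard ellipse area per draw. Closed-form posterior: no MCMC.
#'
#' @param samples Tibble of measurements (`d13C`, `d15N`), n >= 3.
#' @param ndraws Number of posterior draws.
#' @param seed Integer seed.
#' @return A `seab` with `$sea_draws`, `$mu_draws` (ndraws x 2) and
#'   `$Sigma_draws` (2 x 2 x ndraws).
#' @export
bayesian_sea <- function(samples, ndraws = 10000, seed = 1) {
  m <- tibble::as_tibble(samples)
  x <- cbind(m$d13C, m$d15N)
  if (nrow(x) < 3) {
    abort("at least 3 samples are needed for SEAb",
          class = "isoforecast_insufficient_data_error")
  }
  post <- niw_posterior(x)
  with_seed(seed, {
    mu_draws <- matrix(NA_real_, ndraws, 2)
    Sigma_draws <- array(NA_real_, c(2, 2, ndraws))
    sea_draws <- numeric(ndraws)
    for (i in seq_len(ndraws)) {
      d <- rniw(post)
      mu_draws[i, ] <- d$mu
      Sigma_draws[, , i] <- d$Sigma
      sea_draws[i] <- pi * sqrt(det(d$Sigma))
    }
    structure(
      list(sea_draws = sea_draws, mu_draws = mu_draws,
           Sigma_draws = Sigma_draws, n = nrow(x), post = post),
      class = "seab"
    )
  })
}

#' @export
print.seab <- function(x, ...) {
  cat("<seab>", length(x$sea_draws), "draws; posterior median SEAb =",
      signif(median(x$sea_draws), 4), "per-mil^2\n")
  invisible(x)
}

#' @export
posterior_draws.seab <- function(x) {
  cbind(sea = x$sea_draws,
        mu_d13C = x$mu_draws[, 1], mu_d15N = x$mu_draws[, 2])
}

#' @exportS3Method generics::tidy
tidy.seab <- function(x, conf_level = 0.95, ...) {
  lo <- (1 - conf_level) / 2
  tibble::tibble(
    term = "sea",
    estimate = median(x$sea_draws),
    mean = mean(x$sea_draws),
    std.error = sd(x$sea_draws),
    conf.low = quantile(x$sea_draws, lo, names = FALSE),
    conf.high = quantile(x$sea_draws, 1 - lo, names = FALSE)
  )
}

#' Coverage-level ellipse boundary
#'
#' Closed polyline of the boundary
#' \eqn{\{x : (x-\mu)^T \Sigma^{-1} (x-\mu) = q\}} with q the chi-square
#' (2 df) quantile at `coverage`. `coverage = 1 - exp(-1/2)` (about
#' 0.3935) gives the c = 1 standard ellipse, the conventional reading of
#' a "40% of central data" ellipse.
#'
#' @param niche An `ellipse_niche`, or a list with `mu` and `Sigma`.
#' @param coverage Probability in (0, 1).
#' @param n_vertices Number of polyline vertices (default 360).
#' @return Tibble of boundary points (`d13C`, `d15N`); the first vertex
#'   is not repeated.
#' @export
ellipse_boundary <- function(niche, coverage = 1 - exp(-0.5),
                             n_vertices = 360) {
  if (!is.list(niche) || is.null(niche$mu) || is.null(niche$Sigma)) {
    abort("niche must carry mu and Sigma", class = "isoforecast_geometry_error")
  }
  if (coverage <= 0 || coverage >= 1) {
    abort("coverage must lie in (0, 1)", class = "isoforecast_geometry_error")
  }
  Sigma <- niche$Sigma
  if (det(Sigma) <= .Machine$double.eps) {
    abort("singular covariance: no ellipse boundary",
          class = "isoforecast_geometry_error")
  }
  q <- qchisq(coverage, df = 2)
  L <- t(chol(Sigma))
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  circ <- rbind(cos(theta), sin(theta)) * sqrt(q)
  pts <- t(L %*% circ + niche$mu)
  tibble::tibble(d13C = pts[, 1], d15N = pts[, 2])
}
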