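# Shoelace area of a polygon given as a two-column matrix (no repeated
# closing vertex). Positive for counter-clockwise orientation.
polygon_area <- function(p) {
  x <- p[, 1]
  y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Sutherland-Hodgman clipping of a convex subject polygon by a convex
# clip polygon; both counter-clockwise, two-column matrices.
clip_convex <- function(subject, clip) {
  out <- subject
  nclip <- nrow(clip)
  for (i in seq_len(nclip)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[i, ]
    b <- clip[if (i == nclip) 1L else i + 1L, ]
    # signed side of each vertex relative to edge a->b (left = inside)
    ex <- b[1] - a[1]
    ey <- b[2] - a[2]
    s <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    inside <- s >= 0
    if (all(inside)) next
    if (!any(inside)) return(out[0, , drop = FALSE])
    n <- nrow(out)
    nxt <- c(seq_len(n)[-1], 1L)
    keep <- vector("list", n)
    for (k in seq_len(n)) {
      p1 <- out[k, ]
      p2 <- out[nxt[k], ]
      in1 <- inside[k]
      in2 <- inside[nxt[k]]
      if (in1 && in2) {
        keep[[k]] <- p2
      } else if (in1 && !in2) {
        t <- s[k] / (s[k] - s[nxt[k]])
        keep[[k]] <- p1 + t * (p2 - p1)
      } else if (!in1 && in2) {
        t <- s[k] / (s[k] - s[nxt[k]])
        keep[[k]] <- rbind(p1 + t * (p2 - p1), p2)
      } else {
        keep[[k]] <- NULL
      }
    }
    out <- do.call(rbind, keep)
  }
  out
}

#' Overlap of two coverage-level ellipses
#'
#' Intersects the two coverage-level ellipse polygons (convex polygon
#' clipping, 360 vertices each by default) and reports the intersection
#' area, the fraction of each ellipse covered, and the Jaccard fraction
#' of the union. All three normalisations are reported explicitly since
#' "percent overlap" is ambiguous without one.
#'
#' @param a,b `ellipse_niche` objects (or lists with `mu`, `Sigma`).
#' @param coverage Ellipse coverage level in (0, 1); `1 - exp(-0.5)`
#'   gives the standard ellipse.
#' @param n_vertices Vertices per ellipse polygon.
#' @param labels Length-2 character labels for the two groups.
#' @return One-row tibble: `group_a`, `group_b`, `coverage`,
#'   `area_a`, `area_b`, `intersection_area`, `frac_of_a`, `frac_of_b`,
#'   `jaccard`.
#' @export
ellipse_overlap <- function(a, b, coverage = 0.95, n_vertices = 360,
                            labels = c("A", "B")) {
  pa <- as.matrix(ellipse_boundary(a, coverage, n_vertices))
  pb <- as.matrix(ellipse_boundary(b, coverage, n_vertices))
  area_a <- polygon_area(pa)
  area_b <- polygon_area(pb)
  inter <- clip_convex(pa, pb)
  inter_area <- if (is.null(inter) || nrow(inter) < 3) 0 else polygon_area(inter)
  inter_area <- min(inter_area, area_a, area_b)
  union_area <- area_a + area_b - inter_area
  tibble::tibble(
    group_a = labels[1], group_b = labels[2], coverage = coverage,
    area_a = area_a, area_b = area_b, intersection_area = inter_area,
    frac_of_a = inter_area / area_a, frac_of_b = inter_area / area_b,
    jaccard = inter_area / union_area
  )
}

#' Posterior overlap of two Bayesian ellipses
#'
#' Pairs posterior draws of the two groups' (mu, Sigma) and computes the
#' coverage-level ellipse overlap for each pair.
#'
#' @param a_draws,b_draws `seab` posteriors (see [bayesian_sea()]).
#' @param coverage Ellipse coverage level.
#' @param ndraws Number of paired draws used (default: all shared draws,
#'   capped at 500).
#' @param seed Integer seed (used to subsample draws when needed).
#' @param n_vertices Vertices per ellipse polygon.
#' @return Tibble of overlap draws (one row per paired draw).
#' @export
bayesian_overlap <- function(a_draws, b_draws, coverage = 0.95,
                             ndraws = NULL, seed = 1, n_vertices = 180) {
  stopifnot(inherits(a_draws, "seab"), inherits(b_draws, "seab"))
  available <- min(length(a_draws$sea_draws), length(b_draws$sea_draws))
  if (available < 1) {
    abort("empty posterior", class = "isoforecast_validation_error")
  }
  ndraws <- min(ndraws %||% min(available, 500L), available)
  idx <- if (ndraws < available) {
    with_seed(seed, sample.int(available, ndraws))
  } else {
    seq_len(available)
  }
  rows <- purrr::map(idx, function(i) {
    ellipse_overlap(
      list(mu = a_draws$mu_draws[i, ], Sigma = a_draws$Sigma_draws[, , i]),
      list(mu = b_draws$mu_draws[i, ], Sigma = b_draws$Sigma_draws[, , i]),
      coverage = coverage, n_vertices = n_vertices
    )
  })
  out <- dplyr::bind_rows(rows)
  out$draw <- idx
  out
}

#' Directional probabilistic niche overlap
#'
#' Monte-Carlo estimate of the probability that a random individual of
#' group A falls inside group B's alpha-level niche region. Each of the
#' `nmc` steps draws (mu, Sigma) for both groups from their conjugate
#' normal-inverse-Wishart posteriors, then one individual from A's
#' posterior predictive at the data level, and tests whether it lies
#' inside B's alpha-level Mahalanobis region. The estimate is
#' directional: swapping A and B generally changes it.
#'
#' @param samples_a,samples_b Tibbles of measurements (`d13C`, `d15N`),
#'   n >= 3 each.
#' @param alpha Niche region level in (0, 1), e.g. 0.95.
#' @param nmc Monte-Carlo steps (default 10000; < 100 warns).
#' @param seed Integer seed.
#' @param labels Length-2 character labels.
#' @return One-row tibble: `group_a`, `group_b`, `alpha`, `prob`,
#'   `mc_se`, `nmc`.
#' @export
directional_overlap <- function(samples_a, samples_b, alpha = 0.95,
                                nmc = 10000, seed = 1,
                                labels = c("A", "B")) {
  xa <- as.matrix(tibble::as_tibble(samples_a)[, c("d13C", "d15N")])
  xb <- as.matrix(tibble::as_tibble(samples_b)[, c("d13C", "d15N")])
  if (nrow(xa) < 3 || nrow(xb) < 3) {
    abort("each group needs at least 3 samples",
          class = "isoforecast_insufficient_data_error")
  }
  if (nmc < 100) warn("nmc < 100 gives an unstable overlap estimate")
  post_a <- niw_posterior(xa)
  post_b <- niw_posterior(xb)
  q <- qchisq(alpha, df = 2)
  hits <- with_seed(seed, {
    vapply(seq_len(nmc), function(i) {
      da <- rniw(post_a)
      db <- rniw(post_b)
      x <- da$mu + drop(t(chol(da$Sigma)) %*% rnorm(2))
      d <- x - db$mu
      md <- drop(t(d) %*% solve(db$Sigma, d))
      as.numeric(md <= q)
    }, 0)
  })
  p <- mean(hits)
  tibble::tibble(group_a = labels[1], group_b = labels[2], alpha = alpha,
                 prob = p, mc_se = sqrt(p * (1 - p) / nmc), nmc = nmc)
}

#' Directional overlap matrix for several groups
#'
#' Runs [directional_overlap()] for every ordered pair of groups and
#' returns the long table plus a wide matrix-shaped tibble (rows =
#' species A, columns = species B; the diagonal is undefined).
#'
#' @param measurements Tibble of measurements with a grouping column.
#' @param group_col Name of the grouping column (default `"taxon"`).
#' @param alpha Niche region level.
#' @param nmc Monte-Carlo steps per pair.
#' @param seed Integer seed.
#' @return List with `long` (tibble of pair rows) and `matrix` (wide
#'   tibble of probabilities).
#' @export
directional_overlap_matrix <- function(measurements, group_col = "taxon",
                                       alpha = 0.95, nmc = 10000,
                                       seed = 1) {
  m <- tibble::as_tibble(measurements)
  groups <- unique(m[[group_col]])
  pairs <- expand.grid(a = groups, b = groups,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  rows <- purrr::pmap(pairs, function(a, b) {
    directional_overlap(
      m[m[[group_col]] == a, ], m[m[[group_col]] == b, ],
      alpha = alpha, nmc = nmc,
      seed = child_seed(seed, match(a, groups) * length(groups) +
                          match(b, groups)),
      labels = c(a, b)
    )
  })
  long <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(
    long[, c("group_a", "group_b", "prob")],
    names_from = "group_b", values_from = "prob")
  list(long = long, matrix = wide)
}
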