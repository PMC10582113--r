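#' Isotope biplot of a community
#'
#' Scatter of group signatures in (d13C, d15N) space, per-mil on both
#' axes. Groups with at least three individual measurements optionally
#' get their coverage-level ellipse; groups known only from summaries are
#' drawn at their means.
#'
#' @param community A [community()].
#' @param ellipses Draw standard ellipses where possible.
#' @param coverage Ellipse coverage level (default: standard ellipse).
#' @return A ggplot object.
#' @export
plot_biplot <- function(community, ellipses = TRUE,
                        coverage = 1 - exp(-0.5)) {
  stopifnot(inherits(community, "community"))
  s <- community$summaries
  m <- community$measurements
  p <- ggplot2::ggplot() +
    ggplot2::labs(
      x = expression(delta^13 * C ~ "(‰)"),
      y = expression(delta^15 * N ~ "(‰)"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (nrow(s)) {
    p <- p + ggplot2::geom_point(
      data = s,
      ggplot2::aes(x = .data$mean13C, y = .data$mean15N,
                   colour = .data$taxon),
      shape = 18, size = 3)
  }
  if (nrow(m)) {
    p <- p + ggplot2::geom_point(
      data = m,
      ggplot2::aes(x = .data$d13C, y = .data$d15N, colour = .data$taxon),
      alpha = 0.6, size = 1.5)
    if (ellipses) {
      paths <- m |>
        dplyr::group_by(.data$taxon) |>
        dplyr::filter(dplyr::n() >= 3) |>
        dplyr::group_modify(function(d, key) {
          b <- tryCatch(ellipse_boundary(ml_ellipse(d), coverage),
                        error = function(e) NULL)
          if (is.null(b)) return(tibble::tibble())
          dplyr::bind_rows(b, b[1, ])
        }) |>
        dplyr::ungroup()
      if (nrow(paths)) {
        p <- p + ggplot2::geom_path(
          data = paths,
          ggplot2::aes(x = .data$d13C, y = .data$d15N,
                       colour = .data$taxon))
      }
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.community <- function(object, ...) plot_biplot(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.tp_fit <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$tp)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = median(object$draws$tp),
                        linetype = 2) +
    ggplot2::labs(x = "Trophic position", y = "Posterior density") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.diet_fit <- function(object, ...) {
  d <- tibble::as_tibble(object$p_draws) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "source",
                        values_to = "p")
  ord <- summarize_diet(object)$source
  d$source <- factor(d$source, levels = rev(ord))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p, y = .data$source)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::labs(x = "Diet proportion", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.seab <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(sea = object$sea_draws),
                  ggplot2::aes(x = .data$sea)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::labs(x = "Standard ellipse area (‰²)",
                  y = "Posterior density") +
    ggplot2::theme_minimal()
}
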