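#' Community isotope datasets
#'
#' A `community` bundles per-individual stable-isotope measurements
#' (`$measurements`), per-group summary statistics (`$summaries`) and a
#' mapping of baseline roles to taxon labels (`$baselines`). Isotope values
#' are \eqn{\delta^{13}}C (vs VPDB) and \eqn{\delta^{15}}N (vs atmospheric
#' N2), both in per-mil.
#'
#' @param measurements Tibble of individual records with columns `taxon`,
#'   `d13C`, `d15N` and optionally `group`, `status`, `total_length` (mm)
#'   and `weight` (g).
#' @param summaries Tibble of per-group statistics with columns `taxon`,
#'   `n`, `mean15N`, `sd15N`, `mean13C`, `sd13C` and optionally `group`,
#'   `status`, `is_fish`, `mean_TL`, `mean_W`. Computed from
#'   `measurements` when omitted.
#' @param baselines Named list mapping baseline roles (e.g. `baseline1`,
#'   `baseline2`) to character vectors of taxon labels.
#'
#' @return An object of class `community`.
#' @export
community <- function(measurements = NULL, summaries = NULL,
                      baselines = list()) {
  measurements <- normalize_measurements(measurements)
  if (is.null(summaries)) {
    summaries <- summarize_measurements(measurements)
  } else {
    summaries <- normalize_summaries(summaries)
  }
  validate_community(measurements, summaries, baselines)
  structure(
    list(measurements = measurements, summaries = summaries,
         baselines = baselines),
    class = "community"
  )
}

#' @export
print.community <- function(x, ...) {
  cat("<community>", nrow(x$measurements), "measurements,",
      nrow(x$summaries), "group summaries\n")
  if (length(x$baselines)) {
    for (role in names(x$baselines)) {
      cat("  ", role, ": ", paste(x$baselines[[role]], collapse = " + "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

status_levels <- function() c("native", "invasive", "translocated",
                              "hypothetical")

empty_measurements <- function() {
  tibble::tibble(
    taxon = character(), group = character(), status = character(),
    d13C = numeric(), d15N = numeric(),
    total_length = numeric(), weight = numeric()
  )
}

normalize_measurements <- function(m) {
  if (is.null(m) || nrow(tibble::as_tibble(m)) == 0L) {
    return(empty_measurements())
  }
  m <- tibble::as_tibble(m)
  for (col in c("group", "status")) {
    if (!col %in% names(m)) m[[col]] <- NA_character_
  }
  for (col in c("total_length", "weight")) {
    if (!col %in% names(m)) m[[col]] <- NA_real_
  }
  required <- c("taxon", "d13C", "d15N")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    abort(paste0("measurements are missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "isoforecast_schema_error")
  }
  check_measurement_values(m)
  m[, c("taxon", "group", "status", "d13C", "d15N", "total_length",
        "weight")]
}

check_measurement_values <- function(m) {
  if (any(!is.finite(m$d13C)) || any(!is.finite(m$d15N))) {
    bad <- which(!is.finite(m$d13C) | !is.finite(m$d15N))
    abort(paste0("non-finite isotope value at row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "isoforecast_parse_error")
  }
  if (any(m$d13C < -40 | m$d13C > 0)) {
    warn("d13C values outside the typical [-40, 0] per-mil range")
  }
  if (any(m$d15N < -10 | m$d15N > 30)) {
    warn("d15N values outside the typical [-10, 30] per-mil range")
  }
  bad_tl <- !is.na(m$total_length) & m$total_length <= 0
  bad_w <- !is.na(m$weight) & m$weight <= 0
  if (any(bad_tl) || any(bad_w)) {
    abort("total_length and weight must be positive when present",
          class = "isoforecast_schema_error")
  }
  invisible(m)
}

normalize_summaries <- function(s) {
  s <- tibble::as_tibble(s)
  required <- c("taxon", "n", "mean15N", "mean13C")
  missing <- setdiff(required, names(s))
  if (length(missing)) {
    abort(paste0("summaries are missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "isoforecast_schema_error")
  }
  for (col in c("sd15N", "sd13C", "mean_TL", "mean_W")) {
    if (!col %in% names(s)) s[[col]] <- NA_real_
  }
  if (!"group" %in% names(s)) s$group <- NA_character_
  if (!"status" %in% names(s)) s$status <- NA_character_
  if (!"is_fish" %in% names(s)) s$is_fish <- NA
  if (any(!is.na(s$n) & s$n < 1)) {
    abort("summary n must be >= 1", class = "isoforecast_schema_error")
  }
  sds <- c(s$sd15N, s$sd13C)
  if (any(!is.na(sds) & sds < 0)) {
    abort("summary SDs must be >= 0", class = "isoforecast_schema_error")
  }
  s
}

validate_community <- function(measurements, summaries, baselines) {
  key <- paste(summaries$taxon, summaries$group, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate taxon/group rows in summaries",
          class = "isoforecast_validation_error")
  }
  if (length(baselines)) {
    known <- unique(c(summaries$taxon, measurements$taxon))
    unknown <- setdiff(unlist(baselines), known)
    if (length(unknown)) {
      abort(paste0("baseline label(s) not present in dataset: ",
                   paste(unknown, collapse = ", ")),
            class = "isoforecast_validation_error")
    }
  }
  invisible(TRUE)
}

#' Per-group summary statistics from individual measurements
#'
#' Means and sample (n-1 denominator) standard deviations of both isotopes
#' per taxon-group, in measurement row order of first appearance.
#'
#' @param measurements Tibble of individual measurements (see [community()]).
#' @return Tibble with one row per taxon-group.
#' @export
summarize_measurements <- function(measurements) {
  m <- normalize_measurements(measurements)
  if (nrow(m) == 0L) {
    return(normalize_summaries(tibble::tibble(
      taxon = character(), group = character(), status = character(),
      n = integer(), mean15N = numeric(), sd15N = numeric(),
      mean13C = numeric(), sd13C = numeric()
    )))
  }
  s <- m |>
    dplyr::group_by(.data$taxon, .data$group) |>
    dplyr::summarise(
      status = .data$status[1],
      n = dplyr::n(),
      mean15N = mean(.data$d15N),
      sd15N = if (dplyr::n() > 1) sd(.data$d15N) else NA_real_,
      mean13C = mean(.data$d13C),
      sd13C = if (dplyr::n() > 1) sd(.data$d13C) else NA_real_,
      mean_TL = mean(.data$total_length),
      mean_W = mean(.data$weight),
      .groups = "drop"
    )
  first_seen <- unique(paste(m$taxon, m$group, sep = "\r"))
  s <- s[order(match(paste(s$taxon, s$group, sep = "\r"), first_seen)), ]
  normalize_summaries(s)
}
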