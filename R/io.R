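#' Read an isotope table from CSV
#'
#' Reads a comma-separated table of per-individual isotope measurements
#' (one row per organism) and returns a [community()] with validated rows
#' and per-taxon-group summaries. Required columns: `taxon`, `delta13C`,
#' `delta15N`; optional: `group`, `status`, `TL`, `W`. Alternative column
#' names are supplied through `schema`. A table that instead carries
#' summary columns (`n`, `mean15N`, ...) is read as group summaries.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping internal names
#'   (`taxon`, `d13C`, `d15N`, `group`, `status`, `total_length`,
#'   `weight`) to column names in the file.
#' @return A [community()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("taxon,delta13C,delta15N",
#'              "roach,-22.9,9.2", "roach,-22.8,9.3", "roach,-23.0,9.1"), f)
#' read_isotope_table(f)
read_isotope_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "isoforecast_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (all(c("n", "mean15N", "mean13C") %in% names(raw))) {
    return(read_summary_table(raw))
  }
  default_schema <- c(taxon = "taxon", d13C = "delta13C", d15N = "delta15N",
                      group = "group", status = "status",
                      total_length = "TL", weight = "W")
  if (!is.null(schema)) default_schema[names(schema)] <- schema
  # tolerate the short isotope column names too
  if (!default_schema[["d13C"]] %in% names(raw) && "d13C" %in% names(raw)) {
    default_schema[["d13C"]] <- "d13C"
  }
  if (!default_schema[["d15N"]] %in% names(raw) && "d15N" %in% names(raw)) {
    default_schema[["d15N"]] <- "d15N"
  }

  required <- c("taxon", "d13C", "d15N")
  for (field in required) {
    col <- default_schema[[field]]
    if (!col %in% names(raw)) {
      abort(paste0("required column missing from ", path, ": ", col),
            class = "isoforecast_schema_error")
    }
  }
  m <- tibble::tibble(taxon = raw[[default_schema[["taxon"]]]])
  for (field in c("d13C", "d15N", "total_length", "weight")) {
    col <- default_schema[[field]]
    if (col %in% names(raw)) {
      m[[field]] <- parse_numeric_column(raw[[col]], col,
                                         required = field %in% required)
    }
  }
  for (field in c("group", "status")) {
    col <- default_schema[[field]]
    if (col %in% names(raw)) m[[field]] <- raw[[col]]
  }
  community(measurements = m)
}

parse_numeric_column <- function(x, name, required = TRUE) {
  # normalise unicode minus signs as printed in typeset tables
  x <- gsub("−|–", "-", x)
  x <- gsub("[    ]", "", x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "NA" & is.na(out))
  if (length(bad)) {
    abort(paste0("non-numeric value in column '", name, "' at row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "isoforecast_parse_error")
  }
  if (required && any(is.na(out))) {
    abort(paste0("missing value in required column '", name, "' at row(s): ",
                 paste(head(which(is.na(out)), 5), collapse = ", ")),
          class = "isoforecast_parse_error")
  }
  out
}

read_summary_table <- function(raw) {
  s <- tibble::as_tibble(raw)
  for (col in c("n", "mean15N", "sd15N", "mean13C", "sd13C",
                "mean_TL", "mean_W")) {
    if (col %in% names(s)) {
      s[[col]] <- parse_numeric_column(s[[col]], col, required = FALSE)
    }
  }
  if ("is_fish" %in% names(s)) s$is_fish <- as.logical(s$is_fish)
  community(summaries = s)
}

#' Load a packaged community fixture
#'
#' Two plain-text fixtures ship with the package: `"iznik_community"`, the
#' 19 group summaries (12 fish species, marsh frog, macrozoobenthos,
#' phytoplankton, macrophytes, algae, detritus, zooplankton) of the Iznik
#' Lake case-study community with baseline roles pre-assigned (detritus as
#' baseline 1; phyto- and zooplankton as baseline 2), and
#' `"perch_sites"`, the five donor *Perca fluviatilis* site means (two
#' natural lakes, three reservoirs; means only, no spread reported).
#'
#' @param name One of `"iznik_community"` or `"perch_sites"`.
#' @return A [community()].
#' @export
load_fixture <- function(name = c("iznik_community", "perch_sites")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("iznik_community", "perch_sites")) {
    abort(paste0("unknown fixture: ", paste(name, collapse = ", "),
                 " (available: iznik_community, perch_sites)"),
          class = "isoforecast_lookup_error")
  }
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "isoforecast", mustWork = TRUE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (name == "iznik_community") {
    com <- read_summary_table(raw)
    com$baselines <- list(baseline1 = "Detritus",
                          baseline2 = c("Phytoplankton", "Zooplankton"))
    validate_community(com$measurements, com$summaries, com$baselines)
    return(com)
  }
  s <- tibble::tibble(
    taxon = "Perca fluviatilis",
    group = raw$site,
    status = raw$status,
    is_fish = TRUE,
    system = raw$system,
    n = NA_real_,
    mean15N = parse_numeric_column(raw$mean15N, "mean15N", FALSE),
    sd15N = NA_real_,
    mean13C = parse_numeric_column(raw$mean13C, "mean13C", FALSE),
    sd13C = NA_real_,
    mean_TL = parse_numeric_column(raw$mean_TL, "mean_TL", FALSE),
    mean_W = parse_numeric_column(raw$mean_W, "mean_W", FALSE)
  )
  community(summaries = s)
}

#' Write a posterior summary table to CSV
#'
#' One row per named quantity with posterior mean, SD, 2.5/50/97.5
#' percentiles and the draw count. Accepts any fitted object with a
#' [posterior_draws()] method, or a plain matrix/data frame of draws
#' (columns = quantities).
#'
#' @param result Fitted posterior object or draw matrix.
#' @param path Output CSV path.
#' @return The summary tibble, invisibly.
#' @export
write_posterior_summary <- function(result, path) {
  draws <- posterior_draws(result)
  draws <- as.matrix(draws)
  if (length(draws) == 0L || nrow(draws) == 0L || ncol(draws) == 0L) {
    abort("empty posterior: nothing to summarise",
          class = "isoforecast_validation_error")
  }
  if (is.null(colnames(draws))) {
    colnames(draws) <- paste0("q", seq_len(ncol(draws)))
  }
  out <- tibble::tibble(
    quantity = colnames(draws),
    mean = unname(colMeans(draws)),
    sd = unname(apply(draws, 2, sd)),
    q2.5 = apply(draws, 2, quantile, probs = 0.025, names = FALSE),
    q50 = apply(draws, 2, quantile, probs = 0.5, names = FALSE),
    q97.5 = apply(draws, 2, quantile, probs = 0.975, names = FALSE),
    n_draws = nrow(draws)
  )
  readr::write_csv(out, path)
  invisible(out)
}

#' Read a posterior summary written by [write_posterior_summary()]
#'
#' @param path CSV path.
#' @return Tibble of posterior summaries.
#' @export
read_posterior_summary <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    quantity = "c", .default = "d"), progress = FALSE)
}

#' Posterior draws of a fitted object
#'
#' Returns the raw posterior draws of a fitted object as a numeric matrix
#' with one column per named quantity.
#'
#' @param x A fitted object (`tp_fit`, `diet_fit`, `seab`) or a matrix /
#'   data frame of draws.
#' @return Numeric matrix of draws.
#' @export
posterior_draws <- function(x) UseMethod("posterior_draws")

#' @export
posterior_draws.default <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L,
                                 dimnames = list(NULL, "value"))
  storage.mode(x) <- "double"
  x
}
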