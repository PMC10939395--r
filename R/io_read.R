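SAMPLE_ID_RE <- "^(.+)_([0-9]{4}-[0-9]{2}-[0-9]{2})_(plus|minus)_([0-9]+)$"

parse_sample_ids <- function(sample_id) {
  m <- stringr::str_match(sample_id, SAMPLE_ID_RE)
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(
      sprintf(
        "sample id(s) not of the form <station>_<YYYY-MM-DD>_<plus|minus>_<replicate>: %s",
        paste(sample_id[bad], collapse = ", ")
      ),
      class = "cmtracer_format_error"
    )
  }
  tibble::tibble(
    sample_id = sample_id,
    station = m[, 2],
    date = m[, 3],
    treatment = m[, 4],
    replicate = as.integer(m[, 5])
  )
}

check_counts <- function(x, what = "count") {
  x <- as.numeric(x)
  if (anyNA(x)) {
    abort(sprintf("missing %s values are not allowed", what),
          class = "cmtracer_value_error")
  }
  if (any(x < 0)) {
    abort(sprintf("negative %s values are not allowed", what),
          class = "cmtracer_value_error")
  }
  if (any(x != trunc(x))) {
    abort(sprintf("non-integer %s values are not allowed", what),
          class = "cmtracer_value_error")
  }
  as.integer(round(x))
}

#' Read an ASV feature table
#'
#' Reads a tab-separated feature table in the common QIIME2-export dialect:
#' ASV ids in the first column, one column per sample, an optional leading
#' `# Constructed from biom file` comment line. Sample identity
#' (station, ISO-8601 date, treatment, replicate) is parsed from column
#' names of the form `WP_2021-03-15_plus_1`, or taken from a sidecar
#' metadata table (columns `sample_id`, `station`, `date`, `treatment`,
#' `replicate`), which wins on conflict.
#'
#' @param path Path to the TSV feature table.
#' @param metadata Optional metadata data frame or path to a TSV/CSV file
#'   with the columns listed above.
#' @param orientation `"asv_rows"` (default) or `"sample_rows"` for the
#'   transposed layout.
#' @return A tibble in long form with columns `station`, `date`,
#'   `treatment` (`"plus"`/`"minus"`), `replicate`, `asv_id`, `count`.
#'   Zero counts are kept explicit for every ASV x sample pair present in
#'   the file; an ASV absent from a sample has implicit count 0.
#' @export
read_feature_table <- function(path, metadata = NULL,
                               orientation = c("asv_rows", "sample_rows")) {
  orientation <- match.arg(orientation)
  lines <- readr::read_lines(path)
  if (length(lines) > 0 && stringr::str_starts(lines[[1]], "# Constructed")) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    abort("empty feature table", class = "cmtracer_format_error")
  }
  tab <- readr::read_tsv(I(lines), col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 2) {
    abort("feature table must have an id column and at least one sample column",
          class = "cmtracer_format_error")
  }
  if (orientation == "sample_rows") {
    ids <- names(tab)[-1]
    samples <- as.character(tab[[1]])
    mat <- t(as.matrix(tab[, -1]))
    tab <- tibble::tibble(asv_id = ids)
    for (j in seq_along(samples)) tab[[samples[j]]] <- mat[, j]
  }
  names(tab)[1] <- "asv_id"
  tab$asv_id <- as.character(tab$asv_id)
  if (anyDuplicated(tab$asv_id) > 0) {
    abort("duplicate ASV ids in feature table", class = "cmtracer_format_error")
  }
  long <- tidyr::pivot_longer(tab, -"asv_id",
                              names_to = "sample_id", values_to = "count")
  long$count <- check_counts(long$count)

  meta <- resolve_sample_metadata(unique(long$sample_id), metadata)
  out <- dplyr::inner_join(meta, long, by = "sample_id")
  dplyr::select(out, "station", "date", "treatment", "replicate",
                "asv_id", "count")
}

resolve_sample_metadata <- function(sample_ids, metadata) {
  if (is.null(metadata)) {
    return(parse_sample_ids(sample_ids))
  }
  if (is.character(metadata) && length(metadata) == 1) {
    delim <- if (grepl("\\.csv$", metadata)) "," else "\t"
    metadata <- readr::read_delim(metadata, delim = delim, progress = FALSE,
                                  show_col_types = FALSE)
  }
  need <- c("sample_id", "station", "date", "treatment", "replicate")
  if (!all(need %in% names(metadata))) {
    abort(sprintf("metadata must have columns: %s", paste(need, collapse = ", ")),
          class = "cmtracer_format_error")
  }
  meta <- tibble::as_tibble(metadata)[, need]
  meta$treatment <- normalize_treatment(meta$treatment)
  meta$replicate <- as.integer(meta$replicate)
  missing <- setdiff(sample_ids, meta$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("sample id(s) absent from metadata: %s",
                  paste(missing, collapse = ", ")),
          class = "cmtracer_format_error")
  }
  meta[match(sample_ids, meta$sample_id), ]
}

normalize_treatment <- function(x) {
  x <- stringr::str_to_lower(as.character(x))
  x[x %in% c("plus", "+brdu", "plus_brdu", "brdu+")] <- "plus"
  x[x %in% c("minus", "-brdu", "minus_brdu", "brdu-")] <- "minus"
  bad <- !(x %in% c("plus", "minus"))
  if (any(bad)) {
    abort(sprintf("unrecognized treatment value(s): %s",
                  paste(unique(x[bad]), collapse = ", ")),
          class = "cmtracer_format_error")
  }
  x
}

#' Read a taxonomy assignment table
#'
#' Reads a two-column tab-separated taxonomy file (`Feature ID`, `Taxon`
#' with a Silva-style semicolon-joined lineage) and annotates each ASV with
#' its genus and excluded-group/plastid flags via [annotate_taxonomy()].
#'
#' @inheritParams annotate_taxonomy
#' @param path Path to the TSV taxonomy file.
#' @return A tibble with columns `asv_id`, `lineage`, `genus`,
#'   `is_excluded_group`, `has_plastid`.
#' @export
read_taxonomy <- function(path, keywords = default_lineage_keywords()) {
  tab <- readr::read_tsv(path, col_types = "cc", progress = FALSE,
                         show_col_types = FALSE)
  if (ncol(tab) < 2) {
    abort("taxonomy file must have two tab-separated columns",
          class = "cmtracer_format_error")
  }
  names(tab)[1:2] <- c("asv_id", "lineage")
  tab$lineage[is.na(tab$lineage)] <- ""
  annotate_taxonomy(tab, keywords = keywords)
}

#' Read a microscopy count table
#'
#' Reads per-sample light-microscopy counts: one row per taxon per
#' station/date, with the cell concentration (cells per ml), a plastid flag
#' and the number of Sedgewick-rafter grids counted for that sample (the
#' counting effort that later becomes the GLM offset).
#'
#' @param path CSV with columns `station`, `date`, `taxon`, `cells_per_ml`,
#'   `has_plastid`, `grids_counted`.
#' @param stations Optional character vector of known station ids; rows with
#'   other stations are an error.
#' @return A tibble with those columns, plus `genus` extracted from the
#'   taxon label.
#' @export
read_microscopy <- function(path, stations = NULL) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    station = "c", date = "c", taxon = "c",
    cells_per_ml = "d", has_plastid = "l", grids_counted = "d"
  ), progress = FALSE, show_col_types = FALSE)
  need <- c("station", "date", "taxon", "cells_per_ml", "has_plastid",
            "grids_counted")
  if (!all(need %in% names(tab))) {
    abort(sprintf("microscopy file must have columns: %s",
                  paste(need, collapse = ", ")),
          class = "cmtracer_format_error")
  }
  check_known_stations(tab$station, stations)
  if (anyNA(tab$cells_per_ml) || any(tab$cells_per_ml < 0)) {
    abort("cells_per_ml must be present and non-negative",
          class = "cmtracer_value_error")
  }
  if (anyNA(tab$grids_counted) || any(tab$grids_counted <= 0) ||
      any(tab$grids_counted != trunc(tab$grids_counted))) {
    abort("grids_counted must be a positive integer",
          class = "cmtracer_value_error")
  }
  tab$grids_counted <- as.integer(tab$grids_counted)
  tab$genus <- extract_genus(tab$taxon)
  tibble::as_tibble(tab)
}

ENV_COVARIATES <- c("temperature", "salinity", "turbidity", "NH3", "NOx",
                    "PO4", "SiO2", "Kd", "chl_a")
ENV_NONNEGATIVE <- c("turbidity", "NH3", "NOx", "PO4", "SiO2", "Kd", "chl_a")

#' Read an environmental covariate table
#'
#' One row per station/date with temperature (deg C), salinity, turbidity
#' (FNU), NH3/NOx/PO4/SiO2 (uM), light attenuation Kd (per m) and
#' chlorophyll a (ug per l). Blank cells become `NA` and are carried
#' through: the statistics stage drops sample dates with any missing value.
#'
#' @param path CSV with columns `station`, `date`, and the covariates above.
#' @inheritParams read_microscopy
#' @return A tibble.
#' @export
read_env_table <- function(path, stations = NULL) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    station = "c", date = "c", .default = "d"
  ), progress = FALSE, show_col_types = FALSE)
  need <- c("station", "date", ENV_COVARIATES)
  if (!all(need %in% names(tab))) {
    abort(sprintf("environment file must have columns: %s",
                  paste(need, collapse = ", ")),
          class = "cmtracer_format_error")
  }
  check_known_stations(tab$station, stations)
  for (v in ENV_NONNEGATIVE) {
    if (any(tab[[v]] < 0, na.rm = TRUE)) {
      abort(sprintf("%s must be non-negative", v),
            class = "cmtracer_value_error")
    }
  }
  tibble::as_tibble(tab)
}

check_known_stations <- function(found, stations) {
  if (is.null(stations)) return(invisible())
  bad <- setdiff(unique(found), stations)
  if (length(bad) > 0) {
    abort(sprintf("unknown station id(s): %s", paste(bad, collapse = ", ")),
          class = "cmtracer_value_error")
  }
  invisible()
}
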