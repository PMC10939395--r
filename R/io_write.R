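#' Write an ASV feature table
#'
#' Writes a long-form count table (as returned by [read_feature_table()] or
#' [simulate_brdu_experiment()]) to a wide TSV feature table, samples as
#' columns named `<station>_<date>_<treatment>_<replicate>`.
#'
#' @param counts Long count tibble with columns `station`, `date`,
#'   `treatment`, `replicate`, `asv_id`, `count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(counts, path) {
  need <- c("station", "date", "treatment", "replicate", "asv_id", "count")
  stopifnot(all(need %in% names(counts)))
  wide <- counts %>%
    dplyr::mutate(sample_id = paste(.data$station, .data$date,
                                    .data$treatment, .data$replicate,
                                    sep = "_")) %>%
    dplyr::select("asv_id", "sample_id", "count") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L) %>%
    dplyr::arrange(.data$asv_id)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Write a taxonomy table
#'
#' @param taxonomy Tibble with columns `asv_id` and `lineage`.
#' @param path Output path (TSV, columns `Feature ID`, `Taxon`).
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(all(c("asv_id", "lineage") %in% names(taxonomy)))
  out <- tibble::tibble(`Feature ID` = taxonomy$asv_id,
                        Taxon = taxonomy$lineage)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a microscopy count table
#'
#' @param microscopy Tibble as returned by [read_microscopy()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_microscopy <- function(microscopy, path) {
  cols <- c("station", "date", "taxon", "cells_per_ml", "has_plastid",
            "grids_counted")
  stopifnot(all(cols %in% names(microscopy)))
  readr::write_csv(microscopy[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write an environmental covariate table
#'
#' @param env Tibble as returned by [read_env_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(env, path) {
  cols <- c("station", "date", ENV_COVARIATES)
  stopifnot(all(cols %in% names(env)))
  readr::write_csv(env[, cols], path, progress = FALSE)
  invisible(path)
}
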