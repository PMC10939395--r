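#' Filter excluded-group and singleton ASVs
#'
#' Drops ASVs assigned to excluded groups (bacteria, metazoans, fungi,
#' macroalgae) and singleton ASVs before any normalization. Singletons are
#' judged per experiment (station x date): either ASVs whose total read
#' count across all of the experiment's samples equals 1 (`"total_one"`,
#' the default) or ASVs present in exactly one sample (`"one_sample"`).
#' ASVs missing from the taxonomy table are retained with a warning and
#' treated as having both flags `FALSE`. Counts of retained ASVs are
#' unchanged; an empty result is returned as an empty tibble, not an error.
#'
#' @param counts Long count tibble (see [read_feature_table()]).
#' @param taxonomy Annotated taxonomy tibble (see [read_taxonomy()]).
#' @param config A [cm_config()] object.
#' @return The filtered long count tibble.
#' @export
filter_asvs <- function(counts, taxonomy, config = cm_config()) {
  uncovered <- setdiff(unique(counts$asv_id), taxonomy$asv_id)
  if (length(uncovered) > 0) {
    warn(sprintf("%d ASV(s) have no taxonomy assignment; retained with flags unset",
                 length(uncovered)))
  }
  excluded <- taxonomy$asv_id[taxonomy$is_excluded_group]
  out <- dplyr::filter(counts, !(.data$asv_id %in% excluded))

  singleton_of <- function(d) {
    totals <- d %>%
      dplyr::group_by(.data$asv_id) %>%
      dplyr::summarise(total = sum(.data$count),
                       n_present = sum(.data$count > 0), .groups = "drop")
    if (config$singleton_rule == "total_one") {
      totals$asv_id[totals$total == 1]
    } else {
      totals$asv_id[totals$n_present == 1]
    }
  }
  out %>%
    dplyr::group_by(.data$station, .data$date) %>%
    dplyr::group_modify(function(d, key) {
      dplyr::filter(d, !(.data$asv_id %in% singleton_of(d)))
    }) %>%
    dplyr::ungroup()
}

#' Convert counts to per-sample relative abundances
#'
#' Each count becomes a percentage of its sample's total tags, so every
#' sample sums to 100 (to numerical tolerance).
#'
#' @inheritParams filter_asvs
#' @return The input tibble with an added `pct` column.
#' @export
to_relative <- function(counts) {
  out <- counts %>%
    dplyr::group_by(.data$station, .data$date, .data$treatment,
                    .data$replicate) %>%
    dplyr::mutate(.total = sum(.data$count)) %>%
    dplyr::ungroup()
  if (any(out$.total == 0)) {
    bad <- out %>%
      dplyr::filter(.data$.total == 0) %>%
      dplyr::distinct(.data$station, .data$date, .data$treatment,
                      .data$replicate) %>%
      dplyr::mutate(id = paste(.data$station, .data$date, .data$treatment,
                               .data$replicate, sep = "_"))
    abort(sprintf("sample(s) with zero total reads: %s",
                  paste(bad$id, collapse = ", ")),
          class = "cmtracer_value_error")
  }
  out %>%
    dplyr::mutate(pct = 100 * .data$count / .data$.total) %>%
    dplyr::select(-".total")
}

#' Average relative abundances over replicates within treatment
#'
#' The ASV universe of an experiment is the union over all of its samples;
#' an ASV absent from a replicate contributes 0% to that replicate before
#' averaging.
#'
#' @param rel Relative abundance tibble from [to_relative()].
#' @return A tibble with columns `station`, `date`, `treatment`, `asv_id`,
#'   `mean_pct`.
#' @export
treatment_means <- function(rel) {
  rel %>%
    dplyr::group_by(.data$station, .data$date) %>%
    dplyr::group_modify(function(d, key) {
      samples <- dplyr::distinct(d, .data$treatment, .data$replicate)
      tidyr::crossing(asv_id = unique(d$asv_id), samples) %>%
        dplyr::left_join(d[, c("asv_id", "treatment", "replicate", "pct")],
                         by = c("asv_id", "treatment", "replicate")) %>%
        dplyr::mutate(pct = dplyr::coalesce(.data$pct, 0)) %>%
        dplyr::group_by(.data$treatment, .data$asv_id) %>%
        dplyr::summarise(mean_pct = mean(.data$pct), .groups = "drop")
    }) %>%
    dplyr::ungroup()
}

#' Subtract -BrdU means from +BrdU means
#'
#' For every ASV in the union universe of an experiment, computes the
#' difference between its mean relative abundance in the +BrdU samples and
#' in the -BrdU samples, in percentage points.
#'
#' @param means Output of [treatment_means()].
#' @return A tibble with columns `station`, `date`, `asv_id`,
#'   `mean_plus_pct`, `mean_minus_pct`, `diff_pct`.
#' @export
differential <- function(means) {
  miss <- means %>%
    dplyr::distinct(.data$station, .data$date, .data$treatment) %>%
    dplyr::count(.data$station, .data$date) %>%
    dplyr::filter(.data$n < 2)
  if (nrow(miss) > 0) {
    abort(sprintf("experiment(s) missing a treatment: %s",
                  paste(paste(miss$station, miss$date, sep = "_"),
                        collapse = ", ")),
          class = "cmtracer_value_error")
  }
  means %>%
    tidyr::pivot_wider(names_from = "treatment", values_from = "mean_pct",
                       values_fill = 0) %>%
    dplyr::rename(mean_plus_pct = "plus", mean_minus_pct = "minus") %>%
    dplyr::mutate(diff_pct = .data$mean_plus_pct - .data$mean_minus_pct) %>%
    dplyr::select("station", "date", "asv_id", "mean_plus_pct",
                  "mean_minus_pct", "diff_pct")
}

#' Call bacterivorous ASVs
#'
#' An ASV is called a bacterivore when its +/- difference is strictly
#' positive and strictly greater than the configured threshold (default
#' 0.1 percentage points of total tags). Both inequalities are strict:
#' a difference of exactly 0 or exactly the threshold is rejected.
#'
#' @param records Differential tibble from [differential()].
#' @param config A [cm_config()] object.
#' @return `records` with a logical `is_bacterivore` column.
#' @export
call_bacterivores <- function(records, config = cm_config()) {
  dplyr::mutate(records,
                is_bacterivore = .data$diff_pct > 0 &
                  .data$diff_pct > config$bacterivore_min_diff_pct)
}

#' Call actively grazing constitutive mixotrophs
#'
#' Bacterivorous ASVs whose lineage is chloroplast-containing are called
#' actively grazing constitutive mixotrophs (CMs).
#'
#' @param records Output of [call_bacterivores()].
#' @param taxonomy Annotated taxonomy tibble.
#' @return `records` with added `genus`, `has_plastid` and logical `is_cm`
#'   columns. The active-CM ASV set of an experiment is
#'   `records$asv_id[records$is_cm]` within that experiment's rows.
#' @export
call_cms <- function(records, taxonomy) {
  records %>%
    dplyr::left_join(
      dplyr::select(taxonomy, "asv_id", "genus", "has_plastid"),
      by = "asv_id"
    ) %>%
    dplyr::mutate(
      has_plastid = dplyr::coalesce(.data$has_plastid, FALSE),
      is_cm = .data$is_bacterivore & .data$has_plastid
    )
}

#' Run the full bacterivore/CM classification
#'
#' Chains the classification stage end to end for every experiment
#' (station x date) in a long count table: excluded-group and singleton
#' filtering, per-sample conversion to percentages, replicate averaging per
#' treatment, +/- subtraction, thresholded bacterivore calls and the
#' plastid restriction that defines actively grazing CMs.
#'
#' With `config$pool_replicates = TRUE` replicate counts are summed per
#' treatment before normalization instead of averaging per-replicate
#' percentages; with `config$normalize_before_filter = TRUE` percentages
#' are computed on the unfiltered table.
#'
#' @inheritParams filter_asvs
#' @return A tibble of class `"cm_classification"`, one row per ASV per
#'   experiment, with columns `station`, `date`, `asv_id`,
#'   `mean_plus_pct`, `mean_minus_pct`, `diff_pct`, `is_bacterivore`,
#'   `genus`, `has_plastid`, `is_cm`.
#' @examples
#' sim <- simulate_brdu_experiment(n_asvs = 50, depth = 2000, seed = 1)
#' cls <- classify_experiments(sim$counts, sim$taxonomy)
#' dplyr::filter(cls, is_cm)
#' @export
classify_experiments <- function(counts, taxonomy, config = cm_config()) {
  if (config$normalize_before_filter) {
    rel <- to_relative(counts)
    kept <- filter_asvs(counts, taxonomy, config)
    rel <- dplyr::semi_join(rel, kept,
                            by = c("station", "date", "asv_id"))
  } else {
    kept <- filter_asvs(counts, taxonomy, config)
    if (nrow(kept) == 0) {
      return(empty_classification())
    }
    if (config$pool_replicates) {
      kept <- kept %>%
        dplyr::group_by(.data$station, .data$date, .data$treatment,
                        .data$asv_id) %>%
        dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
        dplyr::mutate(replicate = 1L)
    }
    rel <- to_relative(kept)
  }
  if (nrow(rel) == 0) {
    return(empty_classification())
  }
  out <- rel %>%
    treatment_means() %>%
    differential() %>%
    call_bacterivores(config) %>%
    call_cms(taxonomy)
  class(out) <- c("cm_classification", class(out))
  out
}

empty_classification <- function() {
  out <- tibble::tibble(
    station = character(), date = character(), asv_id = character(),
    mean_plus_pct = double(), mean_minus_pct = double(),
    diff_pct = double(), is_bacterivore = logical(),
    genus = character(), has_plastid = logical(), is_cm = logical()
  )
  class(out) <- c("cm_classification", class(out))
  out
}

#' Write a classification table
#'
#' @param classification A `"cm_classification"` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  readr::write_tsv(classification, path, progress = FALSE)
  invisible(path)
}

#' Read a classification table written by [write_classification()]
#'
#' @param path TSV path.
#' @return A `"cm_classification"` tibble.
#' @export
read_classification <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    station = "c", date = "c", asv_id = "c", mean_plus_pct = "d",
    mean_minus_pct = "d", diff_pct = "d", is_bacterivore = "l",
    genus = "c", has_plastid = "l", is_cm = "l"
  ), progress = FALSE, show_col_types = FALSE)
  class(out) <- c("cm_classification", class(out))
  out
}
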