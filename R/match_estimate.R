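genus_key <- function(x) stringr::str_to_lower(x)

#' Active CM genera per experiment
#'
#' Collapses the actively grazing CM ASVs of each experiment
#' (station x date) to their set of resolvable genera. ASVs without a
#' resolvable genus can never match a microscopy taxon and are dropped
#' here (they still count as CM ASVs elsewhere).
#'
#' @param classification A `"cm_classification"` tibble.
#' @return A tibble with columns `station`, `date`, `genus`, one row per
#'   genus per experiment.
#' @export
active_genus_table <- function(classification) {
  classification %>%
    dplyr::filter(.data$is_cm, !is.na(.data$genus)) %>%
    dplyr::distinct(.data$station, .data$date, .data$genus)
}

#' Potential CM genera per station
#'
#' A genus is a potential CM at a station if it was called an active CM
#' there on *any* sampling date: the per-station union of the active sets.
#'
#' @param active Output of [active_genus_table()].
#' @return A tibble with columns `station`, `genus`.
#' @export
potential_genus_table <- function(active) {
  dplyr::distinct(active, .data$station, .data$genus)
}

#' Estimate potential and active CM abundance and proportion
#'
#' Joins the amplicon-derived CM calls to microscopy counts on exact
#' (station, date) and, for each microscopy sample, sums the cell
#' concentrations of plastid-bearing taxa whose genus matches the active
#' set (that date) or the potential set (any date at that station).
#' Proportions divide by the sample's total phototroph abundance, the sum
#' over all plastid-bearing taxa. Matching is by normalized genus,
#' case-insensitive; microscopy taxa without a resolvable genus only
#' contribute to the phototroph total. Because the tracer experiments use
#' light microscopy as the quantitative anchor, these abundances represent
#' CM taxa large enough to identify microscopically (roughly >10-15 um).
#'
#' @param classification A `"cm_classification"` tibble.
#' @param microscopy A microscopy tibble (see [read_microscopy()]).
#' @return A tibble of class `"cm_estimates"`, one row per microscopy
#'   sample: `station`, `date`, `total_phototroph_abundance`,
#'   `potential_abundance`, `active_abundance`, `potential_proportion`,
#'   `active_proportion`, `active_genera`, `potential_genera`
#'   (semicolon-collapsed, alphabetical), `grids_counted`.
#' @export
estimate_cms <- function(classification, microscopy) {
  active <- active_genus_table(classification)
  potential <- potential_genus_table(active)
  if (!"genus" %in% names(microscopy)) {
    microscopy$genus <- extract_genus(microscopy$taxon)
  }
  out <- microscopy %>%
    dplyr::group_by(.data$station, .data$date) %>%
    dplyr::group_modify(function(d, key) {
      total <- sum(d$cells_per_ml[d$has_plastid])
      if (total <= 0) {
        abort(sprintf("zero total phototroph abundance at %s %s: proportion undefined",
                      key$station, key$date),
              class = "cmtracer_value_error")
      }
      act <- genus_key(active$genus[active$station == key$station &
                                      active$date == key$date])
      pot <- genus_key(potential$genus[potential$station == key$station])
      gk <- genus_key(d$genus)
      in_act <- d$has_plastid & !is.na(gk) & gk %in% act
      in_pot <- d$has_plastid & !is.na(gk) & gk %in% pot
      tibble::tibble(
        total_phototroph_abundance = total,
        potential_abundance = sum(d$cells_per_ml[in_pot]),
        active_abundance = sum(d$cells_per_ml[in_act]),
        potential_proportion = sum(d$cells_per_ml[in_pot]) / total,
        active_proportion = sum(d$cells_per_ml[in_act]) / total,
        active_genera = paste(sort(unique(d$genus[in_act])), collapse = ";"),
        potential_genera = paste(sort(unique(d$genus[in_pot])), collapse = ";"),
        grids_counted = d$grids_counted[[1]]
      )
    }) %>%
    dplyr::ungroup()
  class(out) <- c("cm_estimates", class(out))
  out
}

#' Two-set partition of ASV (or any) identifier sets
#'
#' @param a,b Character vectors (duplicates ignored).
#' @return A one-row tibble with `unique_a`, `unique_b`, `shared`, `total`;
#'   `unique_a + unique_b + shared == total == |a union b|` always holds.
#' @examples
#' set_partition(c("x", "y", "z"), c("y", "w"))
#' @export
set_partition <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  tibble::tibble(
    unique_a = length(setdiff(a, b)),
    unique_b = length(setdiff(b, a)),
    shared = length(intersect(a, b)),
    total = length(union(a, b))
  )
}

#' Partition CM ASVs between two stations
#'
#' Mirrors the unique-to-A / unique-to-B / shared bookkeeping of a
#' two-station study over all ASVs ever called CM at each station.
#'
#' @param classification A `"cm_classification"` tibble covering exactly
#'   two stations (or use `stations` to pick two).
#' @param stations Optional length-2 character vector selecting and
#'   ordering the stations.
#' @return A one-row tibble: `station_a`, `station_b`, `unique_a`,
#'   `unique_b`, `shared`, `total`.
#' @export
asv_set_partition <- function(classification, stations = NULL) {
  cms <- dplyr::filter(classification, .data$is_cm)
  if (is.null(stations)) stations <- sort(unique(classification$station))
  if (length(stations) != 2) {
    abort("ASV set partition requires exactly two stations",
          class = "cmtracer_value_error")
  }
  a <- unique(cms$asv_id[cms$station == stations[[1]]])
  b <- unique(cms$asv_id[cms$station == stations[[2]]])
  dplyr::bind_cols(
    tibble::tibble(station_a = stations[[1]], station_b = stations[[2]]),
    set_partition(a, b)
  )
}

#' Per-station summary of CM estimates
#'
#' Means, standard errors (sd/sqrt(n) over sampling dates), and min-max
#' ranges of the potential/active abundance and proportion series at each
#' station. With a single date the mean is reported and the SE is `NA`.
#'
#' @param estimates A `"cm_estimates"` tibble.
#' @return A tibble with columns `station`, `metric`, `n`, `mean`, `se`,
#'   `min`, `max`.
#' @export
summarize_stations <- function(estimates) {
  metrics <- c("potential_abundance", "active_abundance",
               "potential_proportion", "active_proportion",
               "total_phototroph_abundance")
  estimates %>%
    tidyr::pivot_longer(dplyr::all_of(metrics),
                        names_to = "metric", values_to = "value") %>%
    dplyr::group_by(.data$station, .data$metric) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      se = ifelse(dplyr::n() > 1, sd(.data$value) / sqrt(dplyr::n()), NA_real_),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    ) %>%
    dplyr::mutate(metric = factor(.data$metric, levels = metrics)) %>%
    dplyr::arrange(.data$station, .data$metric) %>%
    dplyr::mutate(metric = as.character(.data$metric))
}

#' Station summary: estimate statistics plus the ASV set partition
#'
#' @inheritParams asv_set_partition
#' @param estimates A `"cm_estimates"` tibble.
#' @return A list of class `"cm_station_summary"` with elements
#'   `station_stats` (see [summarize_stations()]) and `asv_partition`
#'   (see [asv_set_partition()]).
#' @export
station_summary <- function(estimates, classification, stations = NULL) {
  structure(
    list(
      station_stats = summarize_stations(estimates),
      asv_partition = asv_set_partition(classification, stations)
    ),
    class = "cm_station_summary"
  )
}

#' @export
print.cm_station_summary <- function(x, ...) {
  cat("CM station summary\n\nPer-station statistics:\n")
  print(x$station_stats)
  cat("\nCM ASV partition:\n")
  print(x$asv_partition)
  invisible(x)
}

#' Write a CM estimate table
#'
#' @param estimates A `"cm_estimates"` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  readr::write_csv(estimates, path, progress = FALSE)
  invisible(path)
}

#' Read a CM estimate table written by [write_estimates()]
#'
#' @param path CSV path.
#' @return A `"cm_estimates"` tibble.
#' @export
read_estimates <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    station = "c", date = "c", active_genera = "c", potential_genera = "c",
    grids_counted = "i", .default = "d"
  ), progress = FALSE, show_col_types = FALSE)
  out$active_genera[is.na(out$active_genera)] <- ""
  out$potential_genera[is.na(out$potential_genera)] <- ""
  class(out) <- c("cm_estimates", class(out))
  out
}
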