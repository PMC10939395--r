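# In-code fixture builders shared across test files.

# long count tibble from a named list: counts[["WP_2021-03-15_plus_1"]] = c(asv1 = 5, ...)
make_counts <- function(samples) {
  purrr::imap_dfr(samples, function(v, id) {
    m <- stringr::str_match(id, "^(.+)_([0-9-]+)_(plus|minus)_([0-9]+)$")
    tibble::tibble(
      station = m[, 2], date = m[, 3], treatment = m[, 4],
      replicate = as.integer(m[, 5]),
      asv_id = names(v), count = as.integer(v)
    )
  })
}

make_taxonomy <- function(...) {
  lin <- c(...)
  annotate_taxonomy(tibble::tibble(asv_id = names(lin), lineage = unname(lin)))
}

dino_lineage <- function(genus, sp = "sp.") {
  paste("Eukaryota;Alveolata;Dinoflagellata;Dinophyceae", genus,
        paste(genus, sp), sep = ";")
}

crypto_lineage <- function(genus, sp = "sp.") {
  paste("Eukaryota;Cryptista;Cryptophyceae", genus, paste(genus, sp), sep = ";")
}

ciliate_lineage <- function(genus) {
  paste("Eukaryota;Alveolata;Ciliophora", genus, paste(genus, "sp."), sep = ";")
}

make_microscopy <- function(rows) {
  out <- dplyr::bind_rows(rows)
  out$genus <- extract_genus(out$taxon)
  out
}

mic_row <- function(station, date, taxon, cells, plastid = TRUE, grids = 100L) {
  tibble::tibble(station = station, date = date, taxon = taxon,
                 cells_per_ml = cells, has_plastid = plastid,
                 grids_counted = as.integer(grids))
}

# differential record tibble with given diff values (for threshold tests)
make_records <- function(diff, station = "WP", date = "2021-03-15") {
  tibble::tibble(
    station = station, date = date,
    asv_id = sprintf("asv%03d", seq_along(diff)),
    mean_plus_pct = pmax(diff, 0), mean_minus_pct = pmax(-diff, 0),
    diff_pct = diff
  )
}
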