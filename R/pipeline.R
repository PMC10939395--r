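log_line <- function(path, ..., verbose = FALSE) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 paste0(...))
  cat(msg, "\n", file = path, append = TRUE, sep = "")
  if (verbose) message(msg)
  invisible(msg)
}

run_stage <- function(name, log_path, verbose, expr) {
  log_line(log_path, "stage ", name, ": start", verbose = verbose)
  res <- tryCatch(expr, error = function(e) {
    log_line(log_path, "stage ", name, ": ERROR ", conditionMessage(e),
             verbose = verbose)
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "cmtracer_stage_error", parent = e)
  })
  log_line(log_path, "stage ", name, ": done", verbose = verbose)
  res
}

#' Run the full CM inference pipeline
#'
#' Orchestrates simulate (optional) -> classify -> estimate -> stats on
#' files, with a plain-text provenance log and a JSON run manifest. Each
#' stage reads the previous stage's files, so any stage can be re-run
#' standalone; for a fixed configuration and inputs the outputs are
#' byte-identical across runs.
#'
#' If any of `feature_table`, `taxonomy`, `microscopy` or `env` is `NULL`,
#' a synthetic study is generated first with [simulate_study()] (seeded by
#' `config$random_seed`) and its files are written under
#' `out_dir/inputs/`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [cm_config()] object or path to a YAML config file.
#' @param feature_table,taxonomy,microscopy,env Paths to input files
#'   (see the corresponding readers), or `NULL` to simulate.
#' @param metadata Optional sample metadata path for the feature table.
#' @param sim_args List of arguments for [simulate_study()].
#' @param verbose Echo log lines as messages.
#' @return The run manifest (list of class `"cm_run_manifest"`),
#'   invisibly: config snapshot, input digests, package version, seed,
#'   per-stage output paths and the log path.
#' @export
run_pipeline <- function(out_dir, config = cm_config(),
                         feature_table = NULL, taxonomy = NULL,
                         microscopy = NULL, env = NULL, metadata = NULL,
                         sim_args = list(), verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "cm_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  if (file.exists(log_path)) file.remove(log_path)
  log_line(log_path, "cmtracer pipeline start", verbose = verbose)
  log_line(log_path, sprintf(
    "thresholds: bacterivore_min_diff_pct=%g vif_max=%g signal_alpha=%g station_test_alpha=%g singleton_rule=%s seed=%d",
    config$bacterivore_min_diff_pct, config$vif_max, config$signal_alpha,
    config$station_test_alpha, config$singleton_rule, config$random_seed
  ), verbose = verbose)

  if (is.null(feature_table) || is.null(taxonomy) || is.null(microscopy) ||
      is.null(env)) {
    in_dir <- file.path(out_dir, "inputs")
    run_stage("simulate", log_path, verbose, {
      study <- do.call(simulate_study,
                       c(list(seed = config$random_seed), sim_args))
      write_study(study, in_dir)
    })
    feature_table <- file.path(in_dir, "feature_table.tsv")
    taxonomy <- file.path(in_dir, "taxonomy.tsv")
    microscopy <- file.path(in_dir, "microscopy.csv")
    env <- file.path(in_dir, "environment.csv")
  }
  inputs <- c(feature_table = feature_table, taxonomy = taxonomy,
              microscopy = microscopy, env = env)

  paths <- list(
    classification = file.path(out_dir, "classification.tsv"),
    estimates = file.path(out_dir, "estimates.csv"),
    station_stats = file.path(out_dir, "station_summary.csv"),
    asv_partition = file.path(out_dir, "asv_partition.csv"),
    coefficients = file.path(out_dir, "glm_coefficients.csv"),
    signals = file.path(out_dir, "glm_signals.csv")
  )

  manifest <- structure(
    list(
      package = "cmtracer",
      version = as.character(utils::packageVersion("cmtracer")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = config$random_seed,
      config = unclass(config),
      inputs = as.list(inputs),
      input_md5 = as.list(tools::md5sum(unname(inputs))),
      outputs = paths,
      log = log_path
    ),
    class = "cm_run_manifest"
  )
  # the manifest is on disk before any downstream stage output is final
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  cls <- run_stage("classify", log_path, verbose, {
    counts <- read_feature_table(feature_table, metadata = metadata)
    tax <- read_taxonomy(taxonomy)
    out <- classify_experiments(counts, tax, config)
    write_classification(out, paths$classification)
    out
  })
  est <- run_stage("estimate", log_path, verbose, {
    mic <- read_microscopy(microscopy)
    cls_in <- read_classification(paths$classification)
    out <- estimate_cms(cls_in, mic)
    write_estimates(out, paths$estimates)
    readr::write_csv(summarize_stations(out), paths$station_stats,
                     progress = FALSE)
    if (length(unique(cls_in$station)) == 2) {
      readr::write_csv(asv_set_partition(cls_in), paths$asv_partition,
                       progress = FALSE)
    }
    out
  })
  stats_res <- run_stage("stats", log_path, verbose, {
    env_tab <- read_env_table(env)
    est_in <- read_estimates(paths$estimates)
    ana <- cm_env_glms(est_in, env_tab, config)
    coefs <- purrr::imap_dfr(unclass(ana), function(res, st) {
      dplyr::bind_rows(
        dplyr::mutate(tidy(res$abundance_fit), station = st,
                      response = "abundance", .before = 1),
        dplyr::mutate(tidy(res$proportion_fit), station = st,
                      response = "proportion", .before = 1)
      )
    })
    readr::write_csv(coefs, paths$coefficients, progress = FALSE)
    readr::write_csv(tidy(ana), paths$signals, progress = FALSE)
    ana
  })
  log_line(log_path, "cmtracer pipeline done", verbose = verbose)
  invisible(manifest)
}

#' @export
print.cm_run_manifest <- function(x, ...) {
  cat(sprintf("cmtracer run manifest (v%s, seed %d)\n", x$version, x$seed))
  cat("outputs:\n")
  for (nm in names(x$outputs)) cat(sprintf("  %s: %s\n", nm, x$outputs[[nm]]))
  invisible(x)
}

#' Read a run manifest written by [run_pipeline()]
#'
#' @param path Path to `manifest.json`.
#' @return The manifest list.
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "cm_run_manifest")
}
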