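#' Pipeline configuration
#'
#' Collects the tunable constants of the CM inference pipeline. Defaults are
#' the thresholds used throughout: a bacterivore call requires the +BrdU minus
#' -BrdU mean relative abundance difference to be positive *and* strictly
#' greater than 0.1 percentage points; environmental covariates with a
#' variance inflation factor of 5 or more are pruned; covariates with a
#' two-sided p-value strictly below 0.5 are reported as carrying a signal
#' (a deliberately permissive screen, reported with sign only); station
#' contrasts use a paired two-tailed t-test at 0.05.
#'
#' @param bacterivore_min_diff_pct Minimum +/- difference, in percentage
#'   points of total tags, for a bacterivore call (strict inequality).
#' @param vif_max Covariates with VIF at or above this are removed.
#' @param signal_alpha Two-sided p-value bound (strict) for the sign-only
#'   signal report.
#' @param station_test_alpha Alpha for the paired t-test between stations.
#' @param random_seed Integer seed recorded in run manifests and used by the
#'   simulation stage.
#' @param singleton_rule How a "singleton" ASV is defined when filtering:
#'   `"total_one"` (total read count across the whole experiment equals 1,
#'   the default) or `"one_sample"` (present in exactly one sample).
#' @param normalize_before_filter If `TRUE`, relative abundances are computed
#'   on the unfiltered table (sensitivity analysis); the default computes
#'   them after excluded-group/singleton filtering.
#' @param pool_replicates If `TRUE`, treatment means are computed from pooled
#'   replicate counts instead of per-replicate percentages (the default).
#'
#' @return A list with class `"cm_config"`.
#' @examples
#' cfg <- cm_config(bacterivore_min_diff_pct = 0.2)
#' cfg$vif_max
#' @export
cm_config <- function(bacterivore_min_diff_pct = 0.1,
                      vif_max = 5,
                      signal_alpha = 0.5,
                      station_test_alpha = 0.05,
                      random_seed = 1L,
                      singleton_rule = c("total_one", "one_sample"),
                      normalize_before_filter = FALSE,
                      pool_replicates = FALSE) {
  singleton_rule <- match.arg(singleton_rule)
  stopifnot(
    bacterivore_min_diff_pct > 0,
    vif_max > 0,
    signal_alpha > 0, signal_alpha <= 1,
    station_test_alpha > 0, station_test_alpha <= 1
  )
  structure(
    list(
      bacterivore_min_diff_pct = bacterivore_min_diff_pct,
      vif_max = vif_max,
      signal_alpha = signal_alpha,
      station_test_alpha = station_test_alpha,
      random_seed = as.integer(random_seed),
      singleton_rule = singleton_rule,
      normalize_before_filter = isTRUE(normalize_before_filter),
      pool_replicates = isTRUE(pool_replicates)
    ),
    class = "cm_config"
  )
}

#' @export
print.cm_config <- function(x, ...) {
  cat("<cm_config>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML `key: value` file; keys missing from the file take the
#' [cm_config()] defaults, unknown keys are an error.
#'
#' @param path Path to a YAML configuration file.
#' @return A `"cm_config"` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(cm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")),
          class = "cmtracer_value_error")
  }
  do.call(cm_config, vals)
}

#' Write a pipeline configuration file
#'
#' @param config A `"cm_config"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "cm_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
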