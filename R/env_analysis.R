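#' Cells counted under the microscope for a given effort
#'
#' Converts a concentration (cells per ml) back to the integer number of
#' cells actually counted on `grids` Sedgewick-rafter grids. A standard
#' rafter distributes 1 ml over 1000 grids, so each grid examines
#' `grid_volume_ml = 0.001` ml.
#'
#' @param cells_per_ml Cell concentration.
#' @param grids Number of grids counted.
#' @param grid_volume_ml Volume examined per grid, in ml.
#' @return Integer cell counts.
#' @export
counted_cells <- function(cells_per_ml, grids, grid_volume_ml = 0.001) {
  as.integer(round(cells_per_ml * grids * grid_volume_ml))
}

#' Environmental quasi-GLM analysis of active CM estimates
#'
#' For each station: prunes collinear environmental covariates by iterated
#' VIF, then fits (a) a quasipoisson GLM of the number of active-CM cells
#' counted per sample with `log(grids_counted)` as offset and (b) a
#' quasibinomial GLM of the active-CM proportion of phototrophs, and
#' produces sign-only signal reports at the configured permissive
#' threshold. Rows with any missing covariate are dropped.
#'
#' @param estimates A `"cm_estimates"` tibble.
#' @param env Environmental covariate tibble (see [read_env_table()]).
#' @param config A [cm_config()] object.
#' @param covariates Covariate columns to consider (default: temperature,
#'   salinity, turbidity, NH3, NOx, PO4, SiO2, Kd).
#' @return An object of class `"cm_env_analysis"`: a named list per
#'   station with elements `vif`, `abundance_fit`, `proportion_fit`,
#'   `abundance_signals`, `proportion_signals`. `tidy()` returns the long
#'   sign matrix.
#' @export
cm_env_glms <- function(estimates, env, config = cm_config(),
                        covariates = setdiff(ENV_COVARIATES, "chl_a")) {
  joined <- dplyr::inner_join(tibble::as_tibble(estimates), env,
                              by = c("station", "date"))
  if (nrow(joined) == 0) {
    abort("no (station, date) overlap between estimates and environment data",
          class = "cmtracer_value_error")
  }
  per_station <- lapply(split(joined, joined$station), function(d) {
    d <- d[stats::complete.cases(d[, covariates, drop = FALSE]), , drop = FALSE]
    vr <- vif_prune(d[, covariates, drop = FALSE], config$vif_max)
    covs <- vr$retained
    d$active_cells_counted <- counted_cells(d$active_abundance,
                                            d$grids_counted)
    ab <- fit_quasi_glm(d, "active_cells_counted", covs,
                        family = "quasipoisson",
                        offset_col = "grids_counted")
    pr <- fit_quasi_glm(d, "active_proportion", covs,
                        family = "quasibinomial")
    list(
      vif = vr,
      abundance_fit = ab,
      proportion_fit = pr,
      abundance_signals = signal_report(ab, config$signal_alpha),
      proportion_signals = signal_report(pr, config$signal_alpha)
    )
  })
  structure(per_station, class = "cm_env_analysis")
}

#' @export
print.cm_env_analysis <- function(x, ...) {
  for (st in names(x)) {
    cat(sprintf("== Station %s ==\n", st))
    print(x[[st]]$vif)
    cat("abundance signals:\n")
    print(x[[st]]$abundance_signals)
    cat("proportion signals:\n")
    print(x[[st]]$proportion_signals)
  }
  invisible(x)
}

#' Tidy an environmental analysis into a long sign matrix
#'
#' @param x A `"cm_env_analysis"` object.
#' @param ... Unused.
#' @return A tibble: `station`, `response` (`"abundance"`/`"proportion"`),
#'   `term`, `estimate`, `p_value`, `sign` (blank when no signal or the
#'   covariate was pruned for collinearity).
#' @export
#' @exportS3Method generics::tidy
tidy.cm_env_analysis <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(res, st) {
    dplyr::bind_rows(
      dplyr::mutate(res$abundance_signals, station = st,
                    response = "abundance", .before = 1),
      dplyr::mutate(res$proportion_signals, station = st,
                    response = "proportion", .before = 1)
    )
  })
}
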