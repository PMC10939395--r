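#' Paired two-tailed t-test
#'
#' Paired t statistic `t = mean(d) / (sd(d) / sqrt(n))` on the pairwise
#' differences `d = x - y`, with `n - 1` degrees of freedom and a
#' two-sided p-value. Pairs with a missing value in either member are
#' dropped. A zero-variance difference vector is handled explicitly
#' rather than erroring: identical vectors give `t = 0, p = 1`; a constant
#' nonzero difference is reported as the `p -> 0` limit with a
#' `degenerate` flag.
#'
#' @param x,y Numeric vectors of equal length (>= 2 complete pairs).
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_diff`, `n`,
#'   `degenerate`.
#' @examples
#' paired_t_test(c(1, 2, 3, 4), c(2, 2, 2, 5))
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "cmtracer_value_error")
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2) {
    abort("paired t-test needs at least 2 complete pairs",
          class = "cmtracer_value_error")
  }
  d <- x - y
  # treat numerically constant differences as degenerate (t.test would error)
  if (sd(d) <= 1e-12 * max(abs(d), 1)) {
    md <- mean(d)
    return(tibble::tibble(
      t = if (md == 0) 0 else sign(md) * Inf,
      df = n - 1,
      p_value = if (md == 0) 1 else 0,
      mean_diff = md,
      n = n,
      degenerate = TRUE
    ))
  }
  ht <- t.test(x, y, paired = TRUE, alternative = "two.sided")
  tibble::tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_diff = unname(ht$estimate),
    n = n,
    degenerate = FALSE
  )
}

#' Paired station contrasts of environmental covariates
#'
#' For each environmental covariate, pairs the two stations' values on
#' shared sampling dates and runs a paired two-tailed t-test, flagging
#' covariates whose means differ at `alpha`.
#'
#' @param env Environmental tibble (see [read_env_table()]) covering
#'   exactly two stations (or choose with `stations`).
#' @param stations Optional length-2 character vector ordering the contrast
#'   as station A minus station B.
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble with one row per covariate: `covariate`, `t`, `df`,
#'   `p_value`, `mean_diff`, `n`, `degenerate`, `significant`.
#' @export
compare_station_env <- function(env, stations = NULL,
                                alpha = cm_config()$station_test_alpha) {
  if (is.null(stations)) stations <- sort(unique(env$station))
  if (length(stations) != 2) {
    abort("station comparison requires exactly two stations",
          class = "cmtracer_value_error")
  }
  a <- env[env$station == stations[[1]], ]
  b <- env[env$station == stations[[2]], ]
  dates <- intersect(a$date, b$date)
  a <- a[match(dates, a$date), ]
  b <- b[match(dates, b$date), ]
  purrr::map_dfr(ENV_COVARIATES, function(v) {
    res <- paired_t_test(a[[v]], b[[v]])
    dplyr::bind_cols(tibble::tibble(covariate = v), res)
  }) %>%
    dplyr::mutate(significant = .data$p_value < alpha)
}
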