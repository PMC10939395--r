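#' Fit a quasipoisson or quasibinomial GLM with a counting-effort offset
#'
#' Fits the environmental regression used throughout the pipeline: a
#' quasi-likelihood GLM with canonical link (log for quasipoisson counts,
#' logit for quasibinomial proportions), estimated by iteratively
#' reweighted least squares via [stats::glm()] with a tight convergence
#' tolerance. The dispersion is the Pearson estimate
#' `phi = sum(pearson residuals^2) / (n - p)`; standard errors scale with
#' `sqrt(phi)` and two-sided p-values use the t distribution with `n - p`
#' degrees of freedom (configurable to a normal reference).
#'
#' Rows with a missing value in the response, any covariate or the offset
#' column are dropped before fitting (the number dropped is recorded).
#' The offset enters the linear predictor as `log(exposure)`; for the
#' binomial-link proportion model an offset is unconventional but
#' supported, mirroring the design it implements.
#'
#' @param data Data frame containing response, covariates and offset.
#' @param response Name of the response column (non-negative counts for
#'   quasipoisson; proportions in \[0, 1\] for quasibinomial).
#' @param covariates Character vector of covariate column names.
#' @param family `"quasipoisson"` or `"quasibinomial"`.
#' @param offset_col Optional name of a column holding the exposure on its
#'   natural scale (e.g. grids counted); its log is used as the offset.
#' @param t_reference Use the t distribution with `n - p` df for Wald
#'   p-values (default); `FALSE` uses the standard normal.
#' @return An object of class `"quasi_glm_fit"`; see [tidy.quasi_glm_fit()]
#'   and [glance.quasi_glm_fit()] for tidy accessors.
#' @examples
#' d <- data.frame(y = rpois(50, 5), x = rnorm(50), e = rep(2, 50))
#' fit <- fit_quasi_glm(d, "y", "x", family = "quasipoisson", offset_col = "e")
#' tidy(fit)
#' @export
fit_quasi_glm <- function(data, response, covariates,
                          family = c("quasipoisson", "quasibinomial"),
                          offset_col = NULL, t_reference = TRUE) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  used <- c(response, covariates, offset_col)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("column(s) not in data: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "cmtracer_value_error")
  }
  complete <- stats::complete.cases(data[, used, drop = FALSE])
  n_dropped <- sum(!complete)
  d <- data[complete, , drop = FALSE]
  if (nrow(d) <= length(covariates) + 1) {
    abort("not enough complete observations to fit the model",
          class = "cmtracer_value_error")
  }

  y <- d[[response]]
  if (family == "quasipoisson" && any(y < 0)) {
    abort("quasipoisson response must be non-negative counts",
          class = "cmtracer_value_error")
  }
  if (family == "quasibinomial" && (any(y < 0) || any(y > 1))) {
    abort("quasibinomial response must be proportions in [0, 1]",
          class = "cmtracer_value_error")
  }
  off <- NULL
  if (!is.null(offset_col)) {
    exposure <- d[[offset_col]]
    if (any(!is.finite(exposure)) || any(exposure <= 0)) {
      abort(sprintf("offset column '%s' must be positive and finite", offset_col),
            class = "cmtracer_value_error")
    }
    off <- log(exposure)
  }

  # refuse rank-deficient designs explicitly, naming the aliased column(s)
  mm <- cbind(`(Intercept)` = 1, as.matrix(d[, covariates, drop = FALSE]))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(sprintf("degenerate (rank-deficient) design; aliased column(s): %s",
                  paste(aliased, collapse = ", ")),
          class = "cmtracer_value_error")
  }

  fam <- if (family == "quasipoisson") quasipoisson(link = "log") else
    quasibinomial(link = "logit")
  fml <- if (length(covariates) == 0) {
    stats::as.formula(paste(response, "~ 1"))
  } else {
    stats::reformulate(covariates, response = response)
  }
  fit <- suppressWarnings(stats::glm(
    fml, data = d, family = fam, offset = off,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  if (!fit$converged) {
    warn("quasi-GLM did not converge within 100 IRLS iterations")
  }

  n <- nrow(d)
  p <- length(coef(fit))
  df_resid <- n - p
  dispersion <- sum(stats::residuals(fit, type = "pearson")^2) / df_resid
  est <- coef(fit)
  se <- sqrt(diag(summary(fit)$cov.unscaled) * dispersion)
  stat <- est / se
  p_value <- if (t_reference) 2 * pt(abs(stat), df_resid, lower.tail = FALSE)
             else 2 * stats::pnorm(abs(stat), lower.tail = FALSE)

  structure(
    list(
      fit = fit,
      family = family,
      formula = fml,
      coefficients = tibble::tibble(
        term = names(est),
        estimate = unname(est),
        std_error = unname(se),
        statistic = unname(stat),
        p_value = unname(p_value)
      ),
      dispersion = dispersion,
      n = n,
      n_dropped = n_dropped,
      df_residual = df_resid,
      converged = fit$converged,
      offset_col = offset_col,
      t_reference = t_reference
    ),
    class = "quasi_glm_fit"
  )
}

#' @export
print.quasi_glm_fit <- function(x, ...) {
  cat(sprintf("%s GLM fit (n = %d, dropped %d incomplete; dispersion = %.4g)\n",
              x$family, x$n, x$n_dropped, x$dispersion))
  if (!is.null(x$offset_col)) cat(sprintf("offset: log(%s)\n", x$offset_col))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a quasi-GLM fit
#'
#' @param x A `"quasi_glm_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`.
#' @export
#' @exportS3Method generics::tidy
tidy.quasi_glm_fit <- function(x, ...) {
  x$coefficients
}

#' One-row model summary of a quasi-GLM fit
#'
#' @param x A `"quasi_glm_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `n`, `n_dropped`, `df_residual`,
#'   `dispersion`, `deviance`, `null_deviance`, `converged`.
#' @export
#' @exportS3Method generics::glance
glance.quasi_glm_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n = x$n,
    n_dropped = x$n_dropped,
    df_residual = x$df_residual,
    dispersion = x$dispersion,
    deviance = x$fit$deviance,
    null_deviance = x$fit$null.deviance,
    converged = x$converged
  )
}

#' Sign-only signal report for a quasi-GLM fit
#'
#' Reports, for every non-intercept covariate, whether it carries a signal
#' (two-sided p-value strictly below `alpha`, default 0.5 — a deliberately
#' permissive screen) and its direction. Covariates at or above the
#' threshold get an empty sign, matching a blank cell in a sign matrix.
#'
#' @param fit A `"quasi_glm_fit"` object.
#' @param alpha Strict p-value bound; covariates with `p_value < alpha`
#'   are reported signed (default `cm_config()$signal_alpha`).
#' @return A tibble with columns `term`, `estimate`, `p_value`, `sign`
#'   (`"+"`, `"-"`, or `""`).
#' @export
signal_report <- function(fit, alpha = cm_config()$signal_alpha) {
  stopifnot(inherits(fit, "quasi_glm_fit"))
  fit$coefficients %>%
    dplyr::filter(.data$term != "(Intercept)") %>%
    dplyr::mutate(
      sign = dplyr::if_else(.data$p_value < alpha,
                            dplyr::if_else(.data$estimate > 0, "+", "-"),
                            "")
    ) %>%
    dplyr::select("term", "estimate", "p_value", "sign")
}
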