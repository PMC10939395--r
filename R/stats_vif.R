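as_covariate_matrix <- function(X) {
  X <- as.data.frame(X)
  if (!all(vapply(X, is.numeric, logical(1)))) {
    abort("covariates must all be numeric", class = "cmtracer_value_error")
  }
  as.matrix(X)
}

#' Variance inflation factor of one covariate
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the ordinary
#' least-squares regression (with intercept) of covariate `j` on all the
#' others. A perfectly collinear covariate yields `Inf`, not an error.
#'
#' @param X Data frame or matrix of numeric covariates (at least 2 columns,
#'   more rows than columns, no constant column).
#' @param j Column index or name.
#' @return The VIF value (`>= 1`, possibly `Inf`).
#' @export
vif <- function(X, j) {
  vif_values(X)[[if (is.character(j)) j else colnames(as_covariate_matrix(X))[j]]]
}

#' Variance inflation factors of all covariates
#'
#' @inheritParams vif
#' @return Named numeric vector of VIF values, one per column.
#' @export
vif_values <- function(X) {
  M <- as_covariate_matrix(X)
  p <- ncol(M)
  if (p < 2) {
    abort("VIF needs at least 2 covariates", class = "cmtracer_value_error")
  }
  if (nrow(M) <= p) {
    abort("VIF needs more observations than covariates",
          class = "cmtracer_value_error")
  }
  if (is.null(colnames(M))) colnames(M) <- paste0("x", seq_len(p))
  consts <- apply(M, 2, function(v) var(v) == 0)
  if (any(consts)) {
    abort(sprintf("constant covariate column(s): %s",
                  paste(colnames(M)[consts], collapse = ", ")),
          class = "cmtracer_value_error")
  }
  out <- vapply(seq_len(p), function(j) {
    y <- M[, j]
    Z <- cbind(1, M[, -j, drop = FALSE])
    fit <- lm.fit(Z, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    # numerically exact collinearity: clamp to Inf rather than a huge float
    if (1 - r2 <= .Machine$double.eps) return(Inf)
    1 / (1 - r2)
  }, double(1))
  setNames(out, colnames(M))
}

#' Iterative VIF-based collinearity pruning
#'
#' Repeatedly removes the covariate with the largest VIF at or above
#' `vif_max` (ties broken by column order) and recomputes, until every
#' retained covariate has VIF strictly below the threshold or fewer than
#' two covariates remain.
#'
#' @inheritParams vif
#' @param vif_max Removal threshold (default 5: a covariate with VIF of 5
#'   or greater is removed).
#' @return An object of class `"vif_report"`: a list with `rounds` (tibble
#'   of per-round VIF values: `round`, `covariate`, `vif`), `removed`
#'   (in removal order), `retained`, and `vif_max`. `tidy()` returns the
#'   rounds tibble.
#' @examples
#' X <- data.frame(a = rnorm(30), b = rnorm(30))
#' X$c <- X$a + X$b # exactly collinear
#' vif_prune(X)$removed
#' @export
vif_prune <- function(X, vif_max = 5) {
  M <- as_covariate_matrix(X)
  if (is.null(colnames(M))) colnames(M) <- paste0("x", seq_len(ncol(M)))
  removed <- character(0)
  rounds <- list()
  round_i <- 0L
  while (ncol(M) >= 2) {
    round_i <- round_i + 1L
    v <- vif_values(M)
    rounds[[round_i]] <- tibble::tibble(round = round_i,
                                        covariate = names(v), vif = unname(v))
    if (max(v) < vif_max) break
    worst <- names(v)[which.max(v)]
    removed <- c(removed, worst)
    M <- M[, setdiff(colnames(M), worst), drop = FALSE]
  }
  structure(
    list(
      rounds = dplyr::bind_rows(rounds),
      removed = removed,
      retained = colnames(M),
      vif_max = vif_max
    ),
    class = "vif_report"
  )
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("VIF pruning (threshold %g)\n", x$vif_max))
  cat(sprintf("  removed:  %s\n",
              if (length(x$removed)) paste(x$removed, collapse = ", ") else "(none)"))
  cat(sprintf("  retained: %s\n", paste(x$retained, collapse = ", ")))
  invisible(x)
}

#' @rdname vif_prune
#' @param x A `"vif_report"` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.vif_report <- function(x, ...) {
  x$rounds
}
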