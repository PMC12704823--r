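#' Percent total weight loss
#'
#' `100 * (pre - post) / pre`, the standard 6-month bariatric outcome.
#'
#' @param pre_kg,post_kg Positive weights in kg (vectorized).
#' @return %TWL (positive = weight lost).
#' @examples
#' percent_total_weight_loss(120, 90)  # 25
#' @export
percent_total_weight_loss <- function(pre_kg, post_kg) {
  if (any(pre_kg <= 0) || any(post_kg <= 0)) {
    stop_validation("weights must be strictly positive")
  }
  100 * (pre_kg - post_kg) / pre_kg
}

#' Ordinary least squares with coefficient covariance
#'
#' QR-based least-squares fit returning everything downstream inference
#' needs: coefficients, their covariance `sigma2 * (X'X)^-1`, residual
#' variance and degrees of freedom. Rank deficiency is an error naming the
#' offending column.
#'
#' @param X Full-column-rank design matrix (n x p, n > p), with column names.
#' @param y Outcome vector, length n.
#' @return List of class `coda_lm`: `coefficients`, `cov`, `sigma2`,
#'   `df_residual`, `n`, `rss`, `fitted`, `residuals`, `X`, `y`.
#' @export
fit_linear_model <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_validation("X and y have different lengths")
  if (n <= p) stop_validation("need more observations than coefficients")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop_validation(paste0("design matrix is rank deficient; offending column(s): ",
                           paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  R <- qr.R(qx)
  # (X'X)^-1 = R^-1 R^-T, with pivoting undone
  Rinv <- backsolve(R, diag(p))
  XtXinv <- Rinv %*% t(Rinv)
  piv <- qx$pivot
  XtXinv[piv, piv] <- XtXinv
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  structure(
    list(
      coefficients = beta, cov = sigma2 * XtXinv, xtx_inv = XtXinv,
      sigma2 = sigma2, df_residual = df, n = n, rss = rss,
      fitted = fitted, residuals = res, X = X, y = y
    ),
    class = "coda_lm"
  )
}

ilr_design <- function(cohort, basis) {
  comp <- as.matrix(cohort[, comp_cols()])
  Z <- ilr(comp, basis)
  colnames(Z) <- paste0("ilr", 1:3)
  Z
}

covariate_design <- function(cohort, covariates) {
  if (length(covariates) == 0) {
    return(matrix(nrow = nrow(cohort), ncol = 0))
  }
  f <- stats::reformulate(covariates)
  mm <- model.matrix(f, data = cohort)
  mm[, -1, drop = FALSE]  # drop intercept; reference level = first factor level
}

#' Fit the compositional outcome model
#'
#' Least-squares regression of a continuous outcome on the three ILR
#' coordinates of the time-use composition plus any retained covariates
#' (factors are reference-coded).
#'
#' @param cohort Participant tibble with composition columns `sleep_min`,
#'   `sb_min`, `lpa_min`, `mvpa_min`, the outcome, and covariate columns.
#' @param basis ILR basis (default sleep pivot); fitted values, the F-test
#'   and reallocation estimates are invariant to this choice.
#' @param covariates Character vector of covariate column names.
#' @param outcome Outcome column name (default `"pct_twl"`).
#' @return `coda_fit` object: a [fit_linear_model()] fit plus `basis`,
#'   `ilr_idx` (columns of the ILR block), `covariates`, `outcome`.
#' @export
fit_coda_lm <- function(cohort, basis = pivot_basis(1),
                        covariates = character(), outcome = "pct_twl") {
  Z <- ilr_design(cohort, basis)
  C <- covariate_design(cohort, covariates)
  X <- cbind(`(Intercept)` = 1, Z, C)
  fit <- fit_linear_model(X, cohort[[outcome]])
  fit$basis <- basis
  fit$ilr_idx <- 2:4
  fit$covariates <- covariates
  fit$outcome <- outcome
  class(fit) <- c("coda_fit", class(fit))
  fit
}

#' @export
print.coda_fit <- function(x, ...) {
  cat("Compositional linear model (", x$outcome, " on ILR coordinates",
      if (length(x$covariates)) paste0(" + ", paste(x$covariates, collapse = ", ")),
      ")\n", sep = "")
  cat("n =", x$n, " residual df =", x$df_residual,
      " residual SD =", round(sqrt(x$sigma2), 3), "\n")
  print(round(coef_table(x), 4))
  invisible(x)
}

#' Coefficient table for a fitted model
#'
#' @param fit A `coda_lm`/`coda_fit`.
#' @return Matrix with estimate, SE, t and p per term.
#' @export
coef_table <- function(fit) {
  est <- fit$coefficients
  se <- sqrt(diag(fit$cov))
  t <- est / se
  p <- 2 * pt(abs(t), fit$df_residual, lower.tail = FALSE)
  cbind(estimate = est, se = se, t = t, p = p)
}

#' Overall composition F-test
#'
#' Nested-model F-test of the 3-column ILR block: compares the full model
#' with a reduced model lacking the ILR coordinates,
#' `F = ((RSS_r - RSS_f)/3) / (RSS_f / df_f)` on (3, df_f) degrees of
#' freedom. Identical for all four pivot bases, since their ILR blocks span
#' the same column space.
#'
#' @param full A `coda_fit`.
#' @param reduced Optional fit of the same rows without the ILR block; built
#'   automatically from `full` when omitted.
#' @return List of class `composition_test`: `statistic`, `df1`, `df2`,
#'   `p_value`, `rss_full`, `rss_reduced`.
#' @export
test_composition <- function(full, reduced = NULL) {
  stopifnot(inherits(full, "coda_fit"))
  if (is.null(reduced)) {
    Xr <- full$X[, -full$ilr_idx, drop = FALSE]
    reduced <- fit_linear_model(Xr, full$y)
  }
  if (reduced$n != full$n || !isTRUE(all.equal(reduced$y, full$y))) {
    stop_validation("full and reduced models must use the same observations")
  }
  df1 <- length(full$ilr_idx)
  stat <- ((reduced$rss - full$rss) / df1) / (full$rss / full$df_residual)
  structure(
    list(
      statistic = stat, df1 = df1, df2 = full$df_residual,
      p_value = pf(stat, df1, full$df_residual, lower.tail = FALSE),
      rss_full = full$rss, rss_reduced = reduced$rss
    ),
    class = "composition_test"
  )
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf("Overall time-use composition: F(%d, %d) = %.2f, p = %.3f\n",
              x$df1, x$df2, x$statistic, x$p_value))
  invisible(x)
}

#' Screen candidate covariates
#'
#' Each candidate is tested one at a time and retained when significant at
#' `alpha`. With `method = "with_composition"` (default) the candidate is
#' tested alongside the 3 ILR coordinates via a partial F-test of its block
#' (equal to the squared-t test for single-column candidates); with
#' `method = "alone"` it is tested against an intercept-only model.
#'
#' @param cohort Participant tibble (complete cases on the candidates).
#' @param basis ILR basis used for the composition block.
#' @param candidates Candidate covariate column names.
#' @param alpha Screening level in (0, 1) — boundary values are allowed as
#'   degenerate switches (1 retains all, 0 none).
#' @param method Screening model, see above.
#' @param outcome Outcome column name.
#' @return Tibble: `candidate`, `df`, `statistic` (partial F), `p`,
#'   `retained`. Attribute `retained` holds the retained name set.
#' @export
screen_covariates <- function(cohort, basis = pivot_basis(1),
                              candidates = c("age", "sex", "race", "bmi", "surgery"),
                              alpha = 0.05,
                              method = c("with_composition", "alone"),
                              outcome = "pct_twl") {
  method <- match.arg(method)
  if (alpha < 0 || alpha > 1) stop_validation("alpha must be in [0, 1]")
  cc <- complete.cases(cohort[, c(candidates, outcome, comp_cols())])
  cohort <- cohort[cc, , drop = FALSE]
  y <- cohort[[outcome]]
  Z <- ilr_design(cohort, basis)
  base_X <- if (method == "with_composition") {
    cbind(`(Intercept)` = 1, Z)
  } else {
    matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)"))
  }
  base_fit <- fit_linear_model(base_X, y)
  rows <- lapply(candidates, function(v) {
    C <- covariate_design(cohort, v)
    fit <- fit_linear_model(cbind(base_X, C), y)
    df1 <- ncol(C)
    stat <- ((base_fit$rss - fit$rss) / df1) / (fit$rss / fit$df_residual)
    tibble::tibble(
      candidate = v, df = df1, statistic = stat,
      p = pf(stat, df1, fit$df_residual, lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$retained <- out$p < alpha
  attr(out, "retained") <- out$candidate[out$retained]
  out
}
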