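#' Cohort reference point for reallocation estimates
#'
#' The compositional center (geometric mean composition, equivalently the
#' ILR-inverse of the mean ILR coordinates) plus covariate summaries (means
#' for numeric covariates, observed proportions for factors). Covariate
#' values cancel in reallocation differences; they are carried for
#' completeness and reporting.
#'
#' @param fit A `coda_fit`.
#' @param cohort The participant tibble the model was fitted to.
#' @return List of class `coda_reference`: `composition` (minutes, closed to
#'   1440) and `covariates`.
#' @export
reference_point <- function(fit, cohort) {
  comp <- geometric_mean_composition(as.matrix(cohort[, comp_cols()]), 1440)
  covs <- lapply(
    setNames(fit$covariates, fit$covariates),
    function(v) {
      x <- cohort[[v]]
      if (is.numeric(x)) mean(x) else prop.table(table(x))
    }
  )
  structure(list(composition = comp, covariates = covs),
            class = "coda_reference")
}

#' Estimate the outcome difference for one time reallocation
#'
#' Isotemporal substitution at the reference composition: `delta` minutes are
#' moved from one behavior to another (all others constant), both
#' compositions are mapped to the fit's ILR basis, and the estimated outcome
#' difference is `d' beta_ilr` with `d` the ILR difference vector. Its
#' standard error is `sqrt(d' Sigma_ilr d)` from the coefficient covariance
#' (intercept and covariate terms cancel in the difference), with a
#' t-interval on the fit's residual df. Reallocations that would drive a
#' behavior to zero or below are flagged infeasible and carry no estimate.
#'
#' @param fit A `coda_fit`.
#' @param reference A `coda_reference` or a 4-part composition in minutes.
#' @param from,to Behaviors (index or name), distinct.
#' @param delta Minutes reallocated (may be negative).
#' @param alpha Two-sided CI level is `1 - alpha` (default 95% CI).
#' @return One-row tibble: `from`, `to`, `delta_min`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p`, `feasible`.
#' @export
estimate_reallocation <- function(fit, reference, from, to, delta,
                                  alpha = 0.05) {
  comp <- if (inherits(reference, "coda_reference")) reference$composition else reference
  i <- match_behavior(from); j <- match_behavior(to)
  if (i == j) stop_validation("'from' and 'to' must differ")
  row <- tibble::tibble(
    from = time_use_behaviors[i], to = time_use_behaviors[j],
    delta_min = delta,
    estimate = NA_real_, se = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
    feasible = reallocation_feasible(comp, i, j, delta)
  )
  if (!row$feasible) return(row)
  d <- ilr(reallocate(comp, i, j, delta), fit$basis) - ilr(comp, fit$basis)
  beta <- fit$coefficients[fit$ilr_idx]
  Sig <- fit$cov[fit$ilr_idx, fit$ilr_idx]
  est <- sum(d * beta)
  se <- sqrt(drop(t(d) %*% Sig %*% d))
  tq <- qt(1 - alpha / 2, fit$df_residual)
  row$estimate <- est
  row$se <- se
  row$ci_low <- est - tq * se
  row$ci_high <- est + tq * se
  row$p <- if (se == 0) as.numeric(est != 0) * 0 + (est == 0) else
    2 * pt(abs(est / se), fit$df_residual, lower.tail = FALSE)
  row
}

#' Default reallocation grid
#'
#' @param max_delta Largest reallocation in minutes (default 60).
#' @param step Grid step in minutes (default 15); must divide `max_delta`.
#' @return Sorted vector of non-zero deltas, symmetric about 0.
#' @export
reallocation_grid <- function(max_delta = 60, step = 15) {
  if (max_delta %% step != 0) stop_validation("step must divide max_delta")
  setdiff(seq(-max_delta, max_delta, by = step), 0)
}

#' Build the full reallocation table
#'
#' All 12 ordered behavior pairs crossed with every non-zero delta of the
#' grid (default -60..+60 by 15 min: 96 cells), each with its estimate, 95%
#' CI and feasibility flag. Following the analysis protocol, reallocation
#' estimates are only produced when the overall composition F-test is
#' significant; pass the test result to enforce that gate (`force = TRUE`
#' overrides it, e.g. in simulation studies).
#'
#' @param fit A `coda_fit`.
#' @param reference A `coda_reference` or composition in minutes.
#' @param deltas Non-zero reallocation amounts (default [reallocation_grid()]).
#' @param alpha CI/test level.
#' @param composition_test Optional `composition_test` used as the
#'   significance gate.
#' @param force Build the table even when the gate fails.
#' @return Tibble of [estimate_reallocation()] rows (one per cell).
#' @export
build_reallocation_table <- function(fit, reference,
                                     deltas = reallocation_grid(),
                                     alpha = 0.05,
                                     composition_test = NULL,
                                     force = FALSE) {
  if (!is.null(composition_test) && composition_test$p_value >= alpha && !force) {
    stop_validation(sprintf(
      paste0("overall composition not significant (p = %.3f >= %.2f); ",
             "reallocation estimates gated off (use force = TRUE to override)"),
      composition_test$p_value, alpha
    ), class = "coda24_gate")
  }
  pairs <- expand.grid(from = time_use_behaviors, to = time_use_behaviors,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  cells <- lapply(seq_len(nrow(pairs)), function(k) {
    dplyr::bind_rows(lapply(deltas, function(d) {
      estimate_reallocation(fit, reference, pairs$from[k], pairs$to[k], d, alpha)
    }))
  })
  dplyr::bind_rows(cells)
}

fmt_cell <- function(est, lo, hi, feasible) {
  ifelse(feasible, sprintf("%.2f (%.2f, %.2f)", est, lo, hi), "-")
}

#' Render the reallocation table in wide (publication) layout
#'
#' One 4 x 4 block per positive delta: rows are the behavior time is
#' displaced from, columns the behavior it is reallocated to; cells show
#' `estimate (ci_low, ci_high)`, `NA` on the diagonal and a dash where the
#' reallocation is infeasible.
#'
#' @param tab Output of [build_reallocation_table()].
#' @return Character vector of text lines (also printed invisibly-friendly).
#' @export
format_reallocation_table <- function(tab) {
  lines <- character(0)
  for (d in sort(unique(abs(tab$delta_min)))) {
    sub <- tab[tab$delta_min == d, ]
    m <- matrix("NA", 4, 4, dimnames = list(time_use_behaviors, time_use_behaviors))
    for (k in seq_len(nrow(sub))) {
      m[sub$from[k], sub$to[k]] <-
        fmt_cell(sub$estimate[k], sub$ci_low[k], sub$ci_high[k], sub$feasible[k])
    }
    lines <- c(
      lines,
      sprintf("%d min (displaced row -> increased column)", d),
      utils::capture.output(print(m, quote = FALSE)),
      ""
    )
  }
  lines
}

#' Plot the reallocation grid
#'
#' 4 x 4 panel grid (diagonal blank): x = minutes reallocated, y = estimated
#' outcome difference with its CI; rows are the displaced behavior, columns
#' the increased behavior. Infeasible cells are simply absent from their
#' panel.
#'
#' @param tab Output of [build_reallocation_table()].
#' @return A ggplot object.
#' @export
plot_reallocation_grid <- function(tab) {
  pairs <- expand.grid(from = time_use_behaviors, to = time_use_behaviors,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  have <- unique(paste(tab$from, tab$to))
  missing <- setdiff(paste(pairs$from, pairs$to), have)
  if (nrow(tab) == 0 || length(missing) > 0) {
    stop_validation(paste0("reallocation table incomplete; missing pairs: ",
                           paste(if (nrow(tab) == 0) paste(pairs$from, pairs$to) else missing,
                                 collapse = ", ")))
  }
  dat <- tab[tab$feasible, ]
  dat$from <- factor(dat$from, levels = time_use_behaviors)
  dat$to <- factor(dat$to, levels = time_use_behaviors)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$delta_min, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(from ~ to, drop = FALSE) +
    ggplot2::labs(
      x = "Minutes reallocated",
      y = "Estimated difference in outcome",
      title = "Isotemporal reallocation estimates with 95% CI",
      subtitle = "Row: behavior displaced; column: behavior increased"
    ) +
    ggplot2::theme_bw()
}
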