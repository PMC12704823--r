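fit_fixture <- function(n = 45, seed = 42) {
  ch <- fixture_cohort(n = n, seed = seed)
  fit <- fit_coda_lm(ch, covariates = "surgery")
  list(cohort = ch, fit = fit, ref = reference_point(fit, ch),
       test = test_composition(fit))
}

test_that("reference point is the compositional center with covariate summaries", {
  fx <- fit_fixture()
  comp <- as.matrix(fx$cohort[, c("sleep_min", "sb_min", "lpa_min", "mvpa_min")])
  # identical compositions -> that composition
  same <- fx$cohort
  fixed <- closure(c(450, 580, 368, 42))
  for (j in 1:4) {
    same[[c("sleep_min", "sb_min", "lpa_min", "mvpa_min")[j]]] <- fixed[[j]]
  }
  ref_same <- reference_point(fx$fit, same)
  expect_equal(unname(ref_same$composition), unname(closure(c(450, 580, 368, 42))),
               tolerance = 1e-9)
  # dual route: ilr-inverse of the mean ILR coordinates, any basis
  for (p in c(1, 3)) {
    via <- ilr_inverse(colMeans(ilr(comp, pivot_basis(p))), pivot_basis(p))
    expect_equal(unname(fx$ref$composition), unname(via), tolerance = 1e-9)
  }
  expect_named(fx$ref$covariates, "surgery")
  # large n: reference near the generator's mean composition
  big <- fixture_cohort(n = 4000, seed = 9)
  ref_big <- reference_point(fit_coda_lm(big), big)
  expect_lt(max(abs(ref_big$composition - closure(c(447.3, 583.7, 366.0, 42.6)))),
            5)
})

test_that("zero-minute reallocation has zero estimate and zero-width CI", {
  fx <- fit_fixture()
  est <- estimate_reallocation(fx$fit, fx$ref, "sb", "mvpa", 0)
  expect_equal(est$estimate, 0)
  expect_equal(est$ci_low, 0)
  expect_equal(est$ci_high, 0)
  expect_true(est$feasible)
})

test_that("estimates use the t distribution and nest inside their CI", {
  fx <- fit_fixture()
  est <- estimate_reallocation(fx$fit, fx$ref, "sb", "mvpa", 15)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)
  tq <- qt(0.975, fx$fit$df_residual)
  expect_equal(est$ci_high - est$estimate, tq * est$se, tolerance = 1e-12)
  expect_error(estimate_reallocation(fx$fit, fx$ref, "sb", "sb", 15),
               "must differ")
})

test_that("antisymmetry: estimate(A->B, -d) equals estimate(B->A, +d) exactly", {
  fx <- fit_fixture()
  pairs <- subset(expand.grid(from = time_use_behaviors, to = time_use_behaviors,
                              stringsAsFactors = FALSE), from != to)
  for (k in seq_len(nrow(pairs))) {
    for (d in c(15, 30, 45, 60)) {
      a <- estimate_reallocation(fx$fit, fx$ref, pairs$from[k], pairs$to[k], -d)
      b <- estimate_reallocation(fx$fit, fx$ref, pairs$to[k], pairs$from[k], d)
      expect_identical(a$feasible, b$feasible)
      if (a$feasible) {
        expect_identical(a$estimate, b$estimate)
        expect_identical(a$ci_low, b$ci_low)
        expect_identical(a$ci_high, b$ci_high)
      }
    }
  }
})

test_that("the full table has 96 cells and honors the significance gate", {
  fx <- fit_fixture()
  tab <- build_reallocation_table(fx$fit, fx$ref, composition_test = NULL)
  expect_equal(nrow(tab), 96)
  expect_equal(nrow(unique(tab[, c("from", "to")])), 12)
  expect_setequal(unique(tab$delta_min), setdiff(seq(-60, 60, 15), 0))
  expect_true(all(tab$feasible[abs(tab$delta_min) <= 30]))

  fake_ns <- list(p_value = 0.40)
  class(fake_ns) <- "composition_test"
  expect_error(
    build_reallocation_table(fx$fit, fx$ref, composition_test = fake_ns),
    class = "coda24_gate"
  )
  tab2 <- build_reallocation_table(fx$fit, fx$ref, composition_test = fake_ns,
                                   force = TRUE)
  expect_equal(nrow(tab2), 96)
})

test_that("table estimates are invariant to the pivot basis", {
  ch <- fixture_cohort(n = 45, seed = 61)
  tabs <- lapply(1:4, function(p) {
    fit <- fit_coda_lm(ch, basis = pivot_basis(p), covariates = "surgery")
    build_reallocation_table(fit, reference_point(fit, ch))
  })
  for (p in 2:4) {
    expect_identical(tabs[[1]]$feasible, tabs[[p]]$feasible)
    expect_lt(max(abs(tabs[[1]]$estimate - tabs[[p]]$estimate), na.rm = TRUE),
              1e-9)
    expect_lt(max(abs(tabs[[1]]$ci_low - tabs[[p]]$ci_low), na.rm = TRUE), 1e-9)
  }
})

test_that("reallocation signs follow the generator's MVPA-dominant pattern", {
  # strong positive effect of MVPA relative to the rest: into-MVPA estimates
  # increase with delta, out-of-MVPA estimates are negative and steeper
  ch <- fixture_cohort(n = 400, seed = 71)
  fit <- fit_coda_lm(ch, covariates = "surgery")
  ref <- reference_point(fit, ch)
  into <- vapply(c(15, 30, 45, 60), function(d) {
    estimate_reallocation(fit, ref, "sb", "mvpa", d)$estimate
  }, numeric(1))
  expect_true(all(diff(into) > 0))
  expect_true(all(into > 0))
  out15 <- estimate_reallocation(fit, ref, "mvpa", "sb", 15)$estimate
  expect_lt(out15, 0)
  expect_gt(abs(out15), into[1])  # convexity of log-ratios near small MVPA
})

test_that("the wide rendering shows estimates, NA diagonal, and dashes", {
  fx <- fit_fixture()
  ref45 <- closure(c(447.3, 583.7, 366.0, 42.6))
  tab <- build_reallocation_table(fx$fit, ref45)
  lines <- format_reallocation_table(tab)
  expect_true(any(grepl("^15 min", lines)))
  expect_true(any(grepl("-$", trimws(lines))) || any(grepl(" - ", lines)))
  # blocks for each |delta|
  for (d in c(15, 30, 45, 60)) {
    expect_true(any(grepl(sprintf("^%d min", d), lines)))
  }
})

test_that("the panel plot builds and rejects incomplete tables", {
  fx <- fit_fixture()
  tab <- build_reallocation_table(fx$fit, fx$ref)
  g <- plot_reallocation_grid(tab)
  expect_s3_class(g, "ggplot")
  expect_error(plot_reallocation_grid(tab[0, ]), "missing pairs")
  expect_error(plot_reallocation_grid(tab[tab$from != "mvpa", ]), "mvpa")
})

test_that("null generator yields about nominal per-cell significance", {
  set.seed(515)
  sig <- replicate(120, {
    ch <- simulate_cohort(cohort_sim_config(
      n_participants = 45, beta_ilr = c(0, 0, 0), surgery_effect = 0
    ))
    fit <- fit_coda_lm(ch)
    tab <- build_reallocation_table(fit, reference_point(fit, ch), deltas = 15)
    cells <- tab[tab$feasible, ]
    mean(cells$ci_low > 0 | cells$ci_high < 0)
  })
  expect_gt(mean(sig), 0.01)
  expect_lt(mean(sig), 0.12)
})
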