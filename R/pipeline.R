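#' Build a run configuration
#'
#' Collects everything an end-to-end run needs. Exactly one input mode is
#' used: `simulate` (a [cohort_sim_config()]), `cohort_csv` (participant
#' table with composition, covariates and either `pct_twl` or `pre_kg` +
#' `post_kg`), or `epoch_csv` + `participants_csv` (minute epochs joined to
#' weights/covariates by `id`).
#'
#' @param simulate Optional [cohort_sim_config()].
#' @param cohort_csv,epoch_csv,participants_csv Optional input paths.
#' @param screening_alpha Covariate screening / gate level.
#' @param deltas Reallocation grid (default [reallocation_grid()]).
#' @param kappa Closure constant in minutes.
#' @param zero_minutes Pseudo-minute for zero behaviors (see
#'   [average_composition()]).
#' @param min_wear_hours,min_days Wear-validity thresholds.
#' @param force_reallocation Build the reallocation table even when the
#'   composition F-test is not significant.
#' @param seed RNG seed recorded in outputs (and used for simulation when the
#'   sim config has none).
#' @param outdir Output directory (created if missing); `NULL` for no files.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, cohort_csv = NULL, epoch_csv = NULL,
                       participants_csv = NULL, screening_alpha = 0.05,
                       deltas = reallocation_grid(), kappa = 1440,
                       zero_minutes = 0.5, min_wear_hours = 16, min_days = 4,
                       force_reallocation = FALSE, seed = 1L, outdir = NULL) {
  modes <- c(!is.null(simulate), !is.null(cohort_csv), !is.null(epoch_csv))
  if (sum(modes) != 1) {
    stop_validation("exactly one of simulate / cohort_csv / epoch_csv must be given")
  }
  for (p in c(cohort_csv, epoch_csv, participants_csv)) {
    if (!file.exists(p)) stop_validation(paste0("input path does not exist: ", p))
  }
  structure(
    list(
      simulate = simulate, cohort_csv = cohort_csv, epoch_csv = epoch_csv,
      participants_csv = participants_csv, screening_alpha = screening_alpha,
      deltas = deltas, kappa = kappa, zero_minutes = zero_minutes,
      min_wear_hours = min_wear_hours, min_days = min_days,
      force_reallocation = force_reallocation, seed = as.integer(seed),
      outdir = outdir
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; a `simulate:` section
#' holds [cohort_sim_config()] fields (`ilr_covariance` as a list of 3 rows).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    if (!is.null(s$ilr_covariance)) {
      s$ilr_covariance <- do.call(rbind, s$ilr_covariance)
    }
    sim <- do.call(cohort_sim_config, s)
  }
  args <- y[setdiff(names(y), "simulate")]
  do.call(run_config, c(list(simulate = sim), args))
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "outdir")])
}

write_stamped_csv <- function(x, path, stamp) {
  con <- file(path, "w")
  writeLines(stamp, con)
  close(con)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

assemble_cohort <- function(config) {
  log <- character(0)
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (is.null(sim$seed)) sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
    log <- c(log, sprintf("simulated cohort: n = %d (seed %d)",
                          nrow(cohort), sim$seed))
  } else if (!is.null(config$cohort_csv)) {
    cohort <- readr::read_csv(config$cohort_csv, show_col_types = FALSE,
                              comment = "#")
    log <- c(log, sprintf("read cohort: n = %d", nrow(cohort)))
  } else {
    epochs <- read_epoch_csv(config$epoch_csv)
    tu <- process_epochs(epochs, config$min_wear_hours, config$min_days,
                         config$kappa, config$zero_minutes)
    excl <- attr(tu, "exclusions")
    for (k in seq_len(nrow(excl))) {
      log <- c(log, sprintf("excluded %s: %s", excl$id[k], excl$reason[k]))
    }
    parts <- readr::read_csv(config$participants_csv, show_col_types = FALSE,
                             comment = "#")
    cohort <- dplyr::inner_join(tu[tu$valid, ], parts, by = "id")
    log <- c(log, sprintf("valid participants entering the model: %d",
                          nrow(cohort)))
  }
  for (v in c("surgery", "sex", "race")) {
    if (v %in% names(cohort) && !is.factor(cohort[[v]])) {
      cohort[[v]] <- factor(cohort[[v]])
    }
  }
  if (!"pct_twl" %in% names(cohort)) {
    cohort$pct_twl <- percent_total_weight_loss(cohort$pre_kg, cohort$post_kg)
    log <- c(log, "computed pct_twl from pre/post weights")
  }
  list(cohort = cohort, log = log)
}

#' Run the full analysis pipeline
#'
#' Cohort assembly (simulation, cohort CSV, or epoch processing), covariate
#' screening, the compositional outcome model, the overall-composition
#' F-test, and — when the F-test passes the significance gate (or
#' `force_reallocation`) — the reallocation table and figure. When `outdir`
#' is set, writes the cohort, model summary, F-test report, reallocation CSV
#' and text table, figure, run log, and a machine-readable `summary.json`;
#' every file is stamped with the seed and a config hash, so a rerun with the
#' same config is reproducible.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @return List (invisibly when writing): `cohort`, `screening`, `fit`,
#'   `test`, `reference`, `reallocation` (tibble or `NULL` when gated off),
#'   `gated` (logical), `log`, `seed`, `config_hash`.
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  set.seed(config$seed)

  asm <- assemble_cohort(config)
  cohort <- asm$cohort
  log <- asm$log
  if (nrow(cohort) < 4) {
    stop_validation(sprintf("only %d valid participants; cannot fit the model",
                            nrow(cohort)))
  }

  basis <- pivot_basis(1)
  candidates <- intersect(c("age", "sex", "race", "bmi", "surgery"),
                          names(cohort))
  screening <- screen_covariates(cohort, basis, candidates,
                                 alpha = config$screening_alpha)
  retained <- attr(screening, "retained")
  log <- c(log, paste0("covariates retained: ",
                       if (length(retained)) paste(retained, collapse = ", ")
                       else "(none)"))

  fit <- fit_coda_lm(cohort, basis, covariates = retained)
  test <- test_composition(fit)
  log <- c(log, sprintf("composition F(%d, %d) = %.3f, p = %.4f",
                        test$df1, test$df2, test$statistic, test$p_value))

  reference <- reference_point(fit, cohort)
  gated <- test$p_value >= config$screening_alpha && !config$force_reallocation
  realloc <- NULL
  if (!gated) {
    realloc <- build_reallocation_table(fit, reference, config$deltas,
                                        alpha = 0.05,
                                        composition_test = test,
                                        force = config$force_reallocation)
  } else {
    log <- c(log, "reallocation stage skipped: composition test not significant")
  }

  res <- list(cohort = cohort, screening = screening, fit = fit, test = test,
              reference = reference, reallocation = realloc, gated = gated,
              log = log, seed = config$seed, config_hash = hash)

  if (!is.null(config$outdir)) {
    write_run_outputs(res, config)
    return(invisible(res))
  }
  res
}

write_run_outputs <- function(res, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# coda24 run seed=%d config_hash=%s",
                   res$seed, res$config_hash)
  out <- function(f) file.path(config$outdir, f)

  write_stamped_csv(res$cohort, out("cohort.csv"), stamp)

  ct <- coef_table(res$fit)
  write_stamped_csv(
    tibble::tibble(term = rownames(ct), tibble::as_tibble(ct)),
    out("model_summary.csv"), stamp
  )
  write_stamped_csv(res$screening, out("covariate_screening.csv"), stamp)

  writeLines(c(
    stamp,
    sprintf("Overall time-use composition: F(%d, %d) = %.2f, p = %.3f",
            res$test$df1, res$test$df2, res$test$statistic, res$test$p_value),
    sprintf("Reference composition (min/day): %s",
            paste(sprintf("%s=%.1f", time_use_behaviors,
                          res$reference$composition), collapse = ", "))
  ), out("composition_test.txt"))

  if (!is.null(res$reallocation)) {
    write_stamped_csv(res$reallocation, out("reallocation.csv"), stamp)
    writeLines(c(stamp, format_reallocation_table(res$reallocation)),
               out("reallocation_table.txt"))
    g <- plot_reallocation_grid(res$reallocation)
    ggplot2::ggsave(out("reallocation_grid.png"), g,
                    width = 8, height = 7, dpi = 150)
  }

  summary <- list(
    seed = res$seed, config_hash = res$config_hash,
    n = nrow(res$cohort),
    f_statistic = res$test$statistic, p_value = res$test$p_value,
    retained_covariates = as.list(attr(res$screening, "retained")),
    gated = res$gated,
    reference_composition = as.list(res$reference$composition),
    n_infeasible_cells = if (is.null(res$reallocation)) NA_integer_ else
      sum(!res$reallocation$feasible)
  )
  jsonlite::write_json(summary, out("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(stamp, res$log), out("run.log"))
  message(paste(res$log, collapse = "\n"))
  invisible(config$outdir)
}
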