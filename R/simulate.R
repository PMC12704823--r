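#' Default between-person ILR covariance (sleep-pivot basis)
#'
#' Assumed 3 x 3 covariance of person-level ILR coordinates, obtained by the
#' delta method from typical preoperative bariatric-cohort per-behavior SDs
#' (70.7, 100.9, 75.3, 23.0 min/day) evaluated at the mean composition.
#' Between-person log-ratio covariance is rarely reported, so this default is
#' an explicit assumption; see the methods vignette.
#'
#' @return Symmetric positive-definite 3 x 3 matrix.
#' @export
default_ilr_covariance <- function() {
  matrix(c(
    0.0490, 0.0323, 0.0508,
    0.0323, 0.0755, 0.0719,
    0.0508, 0.0719, 0.1668
  ), 3, 3, byrow = TRUE, dimnames = list(paste0("z", 1:3), paste0("z", 1:3)))
}

#' Default outcome coefficients on ILR coordinates (sleep-pivot basis)
#'
#' Chosen so the analytic reallocation effects of the generator emulate the
#' magnitude and sign pattern reported for preoperative time use and 6-month
#' percent total weight loss: moving time into MVPA is beneficial, out of
#' MVPA strongly detrimental, sleep/SB/LPA exchanges near-null.
#'
#' @return Numeric 3-vector.
#' @export
default_beta_ilr <- function() c(z1 = 1.255, z2 = 0.688, z3 = -5.681)

is_spd <- function(S) {
  is.matrix(S) && nrow(S) == ncol(S) &&
    max(abs(S - t(S))) < 1e-8 &&
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0
}

#' Configuration for the synthetic cohort generator
#'
#' Person-level 4-part daily time-use compositions are drawn logistic-normal:
#' ILR coordinates (sleep-pivot basis) are multivariate normal centred at the
#' ILR image of `closure(mean_minutes)` with covariance `ilr_covariance`, so
#' compositions are automatically positive and closed. The outcome
#' (percent total weight loss, %TWL) is linear in the centred ILR coordinates
#' plus a centred surgery-type term and Gaussian noise:
#' `twl = beta0 + beta_ilr . (z - z_mu) + surgery_effect * (rygb - p_rygb) + eps`,
#' which makes `beta0` the population mean %TWL. Demographic covariates
#' (age, sex, race, BMI) are simulated with zero true effect to exercise
#' covariate screening.
#'
#' @param n_participants Cohort size (default 45).
#' @param mean_minutes Mean minutes/day in sleep, SB, LPA, MVPA (default
#'   447.3, 583.7, 366.0, 42.6; closed to 1440 internally).
#' @param ilr_covariance 3 x 3 positive-definite covariance of ILR
#'   coordinates.
#' @param beta0 Population mean %TWL (default 23.8).
#' @param beta_ilr Outcome coefficients on the 3 sleep-pivot ILR coordinates.
#' @param surgery_effect %TWL difference, Roux-en-Y gastric bypass (RYGB)
#'   minus sleeve gastrectomy (SG); default 5.
#' @param p_rygb Probability of RYGB (default 0.20).
#' @param sigma_eps Residual SD of %TWL (default 5.1).
#' @param seed Optional RNG seed; identical config + seed gives identical
#'   cohorts.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_participants = 45,
                              mean_minutes = c(447.3, 583.7, 366.0, 42.6),
                              ilr_covariance = default_ilr_covariance(),
                              beta0 = 23.8,
                              beta_ilr = default_beta_ilr(),
                              surgery_effect = 5,
                              p_rygb = 0.20,
                              sigma_eps = 5.1,
                              seed = NULL) {
  if (n_participants < 1) stop_validation("n_participants must be >= 1")
  if (length(mean_minutes) != 4 || any(mean_minutes <= 0)) {
    stop_validation("mean_minutes must be 4 strictly positive values")
  }
  if (!is_spd(unname(ilr_covariance))) {
    stop_validation("ilr_covariance must be symmetric positive-definite")
  }
  if (length(beta_ilr) != 3) stop_validation("beta_ilr must have length 3")
  if (sigma_eps < 0) stop_validation("sigma_eps must be >= 0")
  if (p_rygb < 0 || p_rygb > 1) stop_validation("p_rygb must be in [0, 1]")
  structure(
    list(
      n_participants = as.integer(n_participants),
      mean_minutes = as.numeric(mean_minutes),
      ilr_covariance = unname(as.matrix(ilr_covariance)),
      beta0 = beta0,
      beta_ilr = as.numeric(beta_ilr),
      surgery_effect = surgery_effect,
      p_rygb = p_rygb,
      sigma_eps = sigma_eps,
      seed = seed
    ),
    class = "cohort_sim_config"
  )
}

#' Simulate a synthetic cohort
#'
#' Draws one participant table per the generating model in
#' [cohort_sim_config()]: time-use composition (minutes, closed to 1440),
#' surgery type, null-effect demographics, pre/post weights consistent with
#' the simulated %TWL, and the %TWL outcome itself.
#'
#' @param config A [cohort_sim_config()].
#' @return Tibble with one row per participant.
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(n_participants = 20, seed = 1))
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_participants
  basis <- pivot_basis(1)
  z_mu <- ilr(closure(config$mean_minutes), basis)

  # logistic-normal compositions
  L <- chol(config$ilr_covariance)
  Z <- matrix(rnorm(n * 3), n, 3) %*% L
  Z <- sweep(Z, 2, z_mu, "+")
  comp <- ilr_inverse(Z, basis, kappa = 1440)

  rygb <- rbinom(n, 1, config$p_rygb)
  age <- rnorm(n, 45.2, 11.3)
  sex <- factor(ifelse(runif(n) < 0.889, "female", "male"),
                levels = c("female", "male"))
  race <- factor(sample(c("White", "Black", "Other"), n, replace = TRUE,
                        prob = c(0.591, 0.259, 0.15)),
                 levels = c("White", "Black", "Other"))
  bmi <- rnorm(n, 46.4, 7.7)

  eps <- rnorm(n, 0, config$sigma_eps)
  twl <- config$beta0 +
    drop(sweep(Z, 2, z_mu) %*% config$beta_ilr) +
    config$surgery_effect * (rygb - config$p_rygb) +
    eps

  height <- rnorm(n, 1.65, 0.08)
  pre_kg <- bmi * height^2
  post_kg <- pre_kg * (1 - twl / 100)

  tibble::tibble(
    id = sprintf("P%03d", seq_len(n)),
    sleep_min = comp[, 1], sb_min = comp[, 2],
    lpa_min = comp[, 3], mvpa_min = comp[, 4],
    surgery = factor(ifelse(rygb == 1, "RYGB", "SG"),
                     levels = c("SG", "RYGB")),
    age = age, sex = sex, race = race, bmi = bmi,
    pre_kg = pre_kg, post_kg = post_kg,
    pct_twl = twl
  )
}

#' Analytic ground-truth reallocation effect of the generator
#'
#' The %TWL difference implied by the generating coefficients when `delta`
#' minutes are moved from one behavior to another at the generator's
#' population reference composition `closure(mean_minutes)`:
#' `beta_ilr . (z(reallocated) - z(reference))`.
#'
#' @param config A [cohort_sim_config()].
#' @param from,to Behaviors (index or name).
#' @param delta Minutes reallocated (may be negative).
#' @return %TWL difference (scalar).
#' @export
true_reallocation_effect <- function(config, from, to, delta) {
  stopifnot(inherits(config, "cohort_sim_config"))
  basis <- pivot_basis(1)
  ref <- closure(config$mean_minutes)
  new <- reallocate(ref, from, to, delta)  # errors if infeasible
  sum(config$beta_ilr * (ilr(new, basis) - ilr(ref, basis)))
}

#' Configuration for the minute-epoch stream generator
#'
#' Emulates wrist-worn accelerometry worn around the clock: a fixed sleep
#' window per night, wake minutes assigned to SB/LPA/MVPA with probabilities
#' `wake_props` and counts drawn from per-behavior lognormal distributions,
#' and optional non-wear gaps.
#'
#' @param sleep_onset,sleep_offset Clock minutes in 0..1439 (default 23:00 and
#'   07:00, i.e. 1380 and 420); the window may wrap midnight but must have
#'   positive length.
#' @param count_distributions Named list (`sb`, `lpa`, `mvpa`) of
#'   `c(meanlog, sdlog)` lognormal parameters; each must place at least 95%
#'   of its mass inside the behavior's count band.
#' @param wake_props Expected share of wake wear time per awake behavior;
#'   default proportional to typical SB/LPA/MVPA minutes.
#' @param nonwear_gap_rate Expected non-wear hours/day (0..24), realised as
#'   independent per-minute removal during wake.
#' @param n_days Days of wear (default 10).
#' @param seed Optional RNG seed.
#' @return A `minute_sim_config` list.
#' @export
minute_sim_config <- function(sleep_onset = 1380, sleep_offset = 420,
                              count_distributions = list(
                                sb = c(meanlog = log(300), sdlog = 0.8),
                                lpa = c(meanlog = log(3800), sdlog = 0.25),
                                mvpa = c(meanlog = log(13000), sdlog = 0.3)
                              ),
                              wake_props = c(sb = 583.7, lpa = 366.0,
                                             mvpa = 42.6) /
                                (583.7 + 366.0 + 42.6),
                              nonwear_gap_rate = 0,
                              n_days = 10,
                              seed = NULL) {
  if (sleep_onset < 0 || sleep_onset > 1439 ||
      sleep_offset < 0 || sleep_offset > 1439) {
    stop_validation("sleep_onset/offset must be clock minutes in 0..1439")
  }
  if (sleep_onset == sleep_offset) {
    stop_validation("sleep window has zero/overlapping length")
  }
  if (nonwear_gap_rate < 0 || nonwear_gap_rate > 24) {
    stop_validation("nonwear_gap_rate must be in [0, 24] hours/day")
  }
  bands <- list(sb = c(0, 2000), lpa = c(2000, 7500), mvpa = c(7500, Inf))
  for (b in names(bands)) {
    p <- count_distributions[[b]]
    mass <- plnorm(bands[[b]][2], p[["meanlog"]], p[["sdlog"]]) -
      plnorm(bands[[b]][1], p[["meanlog"]], p[["sdlog"]])
    if (mass < 0.95) {
      stop_validation(sprintf(
        "count distribution for %s places only %.1f%% of mass in its band",
        b, 100 * mass
      ))
    }
  }
  if (abs(sum(wake_props) - 1) > 1e-8 || any(wake_props < 0)) {
    stop_validation("wake_props must be non-negative and sum to 1")
  }
  structure(
    list(
      sleep_onset = sleep_onset, sleep_offset = sleep_offset,
      count_distributions = count_distributions,
      wake_props = as.numeric(wake_props),
      nonwear_gap_rate = nonwear_gap_rate,
      n_days = as.integer(n_days), seed = seed
    ),
    class = "minute_sim_config"
  )
}

#' Simulate a minute-epoch accelerometer stream
#'
#' @param config A [minute_sim_config()].
#' @param start_date First calendar day of wear.
#' @return Tibble with `n_days` x 1440 rows: `timestamp` (POSIXct, UTC),
#'   `counts`, `wear`, `sleep`.
#' @export
simulate_minute_stream <- function(config, start_date = as.Date("2020-01-06")) {
  stopifnot(inherits(config, "minute_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  minute <- rep(0:1439, config$n_days)
  day <- rep(seq_len(config$n_days) - 1L, each = 1440L)
  on <- config$sleep_onset; off <- config$sleep_offset
  sleep <- if (on > off) minute >= on | minute < off else minute >= on & minute < off

  n <- length(minute)
  wear <- rep(TRUE, n)
  wake <- !sleep
  p_nw <- min(1, config$nonwear_gap_rate * 60 / max(1, sum(wake) / config$n_days))
  if (p_nw > 0) wear[wake] <- runif(sum(wake)) >= p_nw

  counts <- numeric(n)
  # sleep-period counts: low movement, value irrelevant to classification
  counts[sleep] <- rlnorm(sum(sleep), log(30), 1)
  ww <- wake & wear
  beh <- sample(c("sb", "lpa", "mvpa"), sum(ww), replace = TRUE,
                prob = config$wake_props)
  for (b in c("sb", "lpa", "mvpa")) {
    k <- beh == b
    p <- config$count_distributions[[b]]
    counts[ww][k] <- rlnorm(sum(k), p[["meanlog"]], p[["sdlog"]])
  }
  counts[!wear] <- 0

  tibble::tibble(
    timestamp = as.POSIXct(start_date, tz = "UTC") + (day * 1440 + minute) * 60,
    counts = counts,
    wear = wear,
    sleep = sleep
  )
}
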