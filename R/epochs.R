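#' Classify minute epochs into movement behaviors
#'
#' Applies the wrist vector-magnitude count cut-points: counts < 2000 = SB,
#' 2000–7499 = LPA, >= 7500 counts/min = MVPA. Minutes inside the sleep
#' period (sleep flag set) are labelled sleep regardless of counts, mirroring
#' sleep-period-first accelerometer processing. Non-wear minutes are not
#' classified and return `NA`.
#'
#' @param counts Non-negative vector-magnitude counts per minute.
#' @param sleep Logical: minute falls in the detected sleep period.
#' @param wear Logical: device worn during the minute.
#' @return Factor with levels [time_use_behaviors]; `NA` for non-wear.
#' @examples
#' classify_epoch(c(1999, 2000, 7499, 7500))
#' @export
classify_epoch <- function(counts, sleep = FALSE, wear = TRUE) {
  n <- length(counts)
  sleep <- rep_len(sleep, n)
  wear <- rep_len(wear, n)
  if (any(counts < 0, na.rm = TRUE)) {
    stop_validation("counts must be non-negative")
  }
  lab <- ifelse(counts < 2000, "sb", ifelse(counts < 7500, "lpa", "mvpa"))
  lab[sleep] <- "sleep"
  lab[!wear] <- NA_character_
  factor(lab, levels = time_use_behaviors)
}

epoch_date <- function(timestamp) {
  if (inherits(timestamp, "POSIXt")) as.Date(timestamp, tz = "UTC") else as.Date(timestamp)
}

#' Summarize one day of minute epochs
#'
#' Counts classified worn minutes per behavior and total wear time for a
#' single calendar day.
#'
#' @param epochs Data frame with columns `timestamp`, `counts`, `wear`,
#'   `sleep`, all from one calendar day, at most 1440 rows, no duplicate
#'   timestamps.
#' @return One-row tibble: `date`, minutes per behavior (`sleep_min`,
#'   `sb_min`, `lpa_min`, `mvpa_min`) and `wear_hours`.
#' @export
summarize_day <- function(epochs) {
  dates <- epoch_date(epochs$timestamp)
  if (length(unique(dates)) != 1L) {
    stop_validation("epochs must all fall on one calendar day")
  }
  if (nrow(epochs) > 1440L) stop_validation("more than 1440 epochs in a day")
  if (anyDuplicated(epochs$timestamp)) {
    stop_validation("duplicate epoch timestamps")
  }
  lab <- classify_epoch(epochs$counts, epochs$sleep, epochs$wear)
  mins <- table(lab)
  tibble::tibble(
    date = dates[1],
    sleep_min = as.numeric(mins[["sleep"]]),
    sb_min = as.numeric(mins[["sb"]]),
    lpa_min = as.numeric(mins[["lpa"]]),
    mvpa_min = as.numeric(mins[["mvpa"]]),
    wear_hours = sum(epochs$wear) / 60
  )
}

#' Summarize a multi-day epoch stream into day records
#'
#' @param epochs Epoch data frame spanning one or more calendar days (one
#'   participant).
#' @return Tibble with one row per calendar day (see [summarize_day()]).
#' @export
summarize_days <- function(epochs) {
  d <- epoch_date(epochs$timestamp)
  dplyr::bind_rows(lapply(split(epochs, d), summarize_day))
}

#' Apply wear-time validity rules
#'
#' A day is valid when the device was worn at least `min_wear_hours` (default
#' 16 h); a participant is valid when they contribute at least `min_days`
#' (default 4) valid days.
#'
#' @param days Day records from [summarize_days()].
#' @param min_wear_hours,min_days Validity thresholds.
#' @return List: `valid_days` (tibble subset), `n_valid_days`,
#'   `participant_valid` (logical).
#' @export
filter_valid_days <- function(days, min_wear_hours = 16, min_days = 4) {
  keep <- days$wear_hours >= min_wear_hours
  valid <- days[keep, , drop = FALSE]
  list(
    valid_days = valid,
    n_valid_days = nrow(valid),
    participant_valid = nrow(valid) >= min_days
  )
}

#' Average valid days into a person-level daily composition
#'
#' Arithmetic mean of daily minutes per behavior over the valid days, with
#' person-level zeros replaced by a pseudo-minute (`zero_minutes`, default
#' 0.5 min) so log-ratios exist, then proportional rescaling to `kappa`
#' (1440 min). Rescaling redistributes any non-wear shortfall across
#' behaviors in proportion to observed time.
#'
#' @param valid_days Tibble of valid day records (>= 1 row; the validity rule
#'   itself lives in [filter_valid_days()]).
#' @param kappa Closure constant in minutes.
#' @param zero_minutes Pseudo-minutes imputed for a behavior whose mean is
#'   exactly zero; set to 0 to disable (then a zero mean is an error).
#' @return One-row tibble: behavior minutes closed to `kappa`, `n_valid_days`.
#' @export
average_composition <- function(valid_days, kappa = 1440, zero_minutes = 0.5) {
  if (nrow(valid_days) < 1L) stop_validation("no valid days to average")
  mu <- colMeans(valid_days[, comp_cols(), drop = FALSE])
  z <- mu == 0
  if (any(z) && zero_minutes > 0) {
    mu[z] <- zero_minutes
  }
  if (any(mu == 0)) {
    stop_validation(paste0(
      "behavior mean of exactly 0 (",
      paste(time_use_behaviors[mu == 0], collapse = ", "),
      "); set zero_minutes > 0 to impute a pseudo-minute"
    ))
  }
  out <- tibble::as_tibble(as.list(closure(mu, kappa)))
  names(out) <- comp_cols()
  out$n_valid_days <- nrow(valid_days)
  out
}

#' Process a multi-participant epoch stream into person-level compositions
#'
#' Runs classification, daily summaries, wear-validity filtering and
#' person-level averaging for each participant, and reports exclusions.
#'
#' @param epochs Epoch data frame with an `id` column plus `timestamp`,
#'   `counts`, `wear`, `sleep`.
#' @inheritParams filter_valid_days
#' @inheritParams average_composition
#' @return Tibble with one row per participant: `id`, composition columns,
#'   `n_valid_days`, `valid`. Attribute `exclusions` lists excluded ids and
#'   reasons.
#' @export
process_epochs <- function(epochs, min_wear_hours = 16, min_days = 4,
                           kappa = 1440, zero_minutes = 0.5) {
  per_id <- lapply(split(epochs, epochs$id), function(e) {
    days <- summarize_days(e)
    f <- filter_valid_days(days, min_wear_hours, min_days)
    if (!f$participant_valid) {
      return(tibble::tibble(
        id = e$id[1],
        sleep_min = NA_real_, sb_min = NA_real_,
        lpa_min = NA_real_, mvpa_min = NA_real_,
        n_valid_days = f$n_valid_days, valid = FALSE
      ))
    }
    avg <- average_composition(f$valid_days, kappa, zero_minutes)
    tibble::tibble(id = e$id[1], avg[comp_cols()],
                   n_valid_days = avg$n_valid_days, valid = TRUE)
  })
  out <- dplyr::bind_rows(per_id)
  excl <- out[!out$valid, c("id", "n_valid_days")]
  if (nrow(excl) > 0) {
    excl$reason <- sprintf("only %d valid days (need >= %d)",
                           excl$n_valid_days, min_days)
  } else {
    excl$reason <- character(0)
  }
  attr(out, "exclusions") <- excl
  out
}

#' Read a minute-epoch CSV
#'
#' Expected columns: `id` (optional), `timestamp` (ISO-8601), `counts`,
#' `wear` (0/1), `sleep` (0/1).
#'
#' @param path File path.
#' @return Tibble with `wear`/`sleep` as logical.
#' @export
read_epoch_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  x$wear <- as.logical(x$wear)
  x$sleep <- as.logical(x$sleep)
  x
}

#' Write a minute-epoch CSV
#'
#' @param epochs Epoch tibble.
#' @param path File path.
#' @export
write_epoch_csv <- function(epochs, path) {
  out <- epochs
  out$wear <- as.integer(out$wear)
  out$sleep <- as.integer(out$sleep)
  readr::write_csv(out, path)
  invisible(path)
}
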