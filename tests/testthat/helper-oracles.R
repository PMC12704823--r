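# Independent oracles used to cross-check the implementation. These never
# call the package's own code paths for the quantity under test.

# Pivot-coordinate ILR written directly from the log-ratio formula:
# z_i = sqrt((D-i)/(D-i+1)) * log(x_(i) / geomean(remaining)), with the pivot
# part moved to the front and the rest kept in order.
oracle_ilr <- function(x, pivot = 1) {
  D <- length(x)
  ord <- c(pivot, setdiff(seq_len(D), pivot))
  xs <- x[ord]
  vapply(seq_len(D - 1), function(i) {
    rest <- xs[(i + 1):D]
    sqrt((D - i) / (D - i + 1)) * log(xs[i] / exp(mean(log(rest))))
  }, numeric(1))
}

# Aitchison distance via the centred log-ratio, no ILR involved.
oracle_aitchison <- function(x, y) {
  clr <- function(v) log(v) - mean(log(v))
  sqrt(sum((clr(x) - clr(y))^2))
}

# Normal-equations least squares via an explicit pseudo-inverse.
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  XtX_inv <- solve(XtX)
  beta <- drop(XtX_inv %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  list(beta = beta, cov = sigma2 * XtX_inv, sigma2 = sigma2, df = df,
       rss = sum(res^2))
}

# Brute-force reallocation effect: rebuild the reallocated composition by
# hand and take the outcome difference with the direct ILR formula above.
oracle_reallocation_effect <- function(mean_minutes, beta, from, to, delta) {
  ref <- 1440 * mean_minutes / sum(mean_minutes)
  new <- ref
  new[from] <- new[from] - delta
  new[to] <- new[to] + delta
  sum(beta * (oracle_ilr(new) - oracle_ilr(ref)))
}

random_composition <- function(n = 1, kappa = 1440) {
  x <- matrix(exp(rnorm(n * 4, 0, 1.2)), n, 4)
  x <- kappa * x / rowSums(x)
  if (n == 1) drop(x) else x
}

# small deterministic fixture cohort
fixture_cohort <- function(n = 45, seed = 42, ...) {
  simulate_cohort(cohort_sim_config(n_participants = n, seed = seed, ...))
}

make_epoch_day <- function(date = as.Date("2020-01-06"), counts, sleep = FALSE,
                           wear = TRUE) {
  n <- length(counts)
  tibble::tibble(
    timestamp = as.POSIXct(date, tz = "UTC") + 60 * (seq_len(n) - 1),
    counts = counts,
    wear = rep_len(wear, n),
    sleep = rep_len(sleep, n)
  )
}
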