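#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals (0.5 always moves away
#' from zero), as used when reporting table aggregates; base R's `round()`
#' rounds half to even. A tiny epsilon guards exact .5 cases against binary
#' representation error.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-7) / p
}

#' Percent timing error against a manual reference
#'
#' `E_T = |T_s - T_m| / T_m * 100`, the agreement metric between
#' system-measured and manually stopwatched times (manual reference in the
#' denominator). Scale-invariant: multiplying both times by c > 0 leaves it
#' unchanged.
#'
#' @param t_system system-measured time in s.
#' @param t_manual manually measured reference time in s (> 0).
#' @return percent error.
#' @export
time_error <- function(t_system, t_manual) {
  if (any(t_manual <= 0)) stop("reference time must be positive")
  abs(t_system - t_manual) / t_manual * 100
}

#' Percent hold-time difference, classifier denominator
#'
#' `100 * |ht_c - ht_t| / ht_c` where `ht_c` is the classifier hold time and
#' `ht_t` the instrumented test-rig hold time. Note the denominator is the
#' classifier value (the convention of the packaged hold-time comparison
#' table), unlike [time_error()], which divides by the manual reference;
#' reports label which convention is used.
#'
#' @param ht_classifier classifier hold time in s (> 0).
#' @param ht_test_setup test-rig hold time in s.
#' @param digits decimal places for reporting (NULL for unrounded).
#' @return percent difference.
#' @export
holdtime_difference <- function(ht_classifier, ht_test_setup, digits = 1) {
  if (any(ht_classifier <= 0)) stop("classifier hold time must be positive")
  d <- 100 * abs(ht_classifier - ht_test_setup) / ht_classifier
  if (is.null(digits)) d else round_half_away(d, digits)
}

#' Hold-time agreement summary over comparison sets
#'
#' Per-set accuracy is `100 - holdtime_difference` (difference rounded to
#' one decimal, as reported); the summary is the mean, minimum and maximum
#' accuracy over sets, rounded half away from zero to one decimal.
#'
#' @param ht_classifier numeric vector of classifier hold times.
#' @param ht_test_setup numeric vector of test-rig hold times.
#' @return list with `accuracy` (per set), `mean`, `min`, `max`.
#' @export
accuracy_summary <- function(ht_classifier, ht_test_setup) {
  if (length(ht_classifier) == 0L) stop("empty input")
  acc <- 100 - holdtime_difference(ht_classifier, ht_test_setup)
  list(accuracy = acc,
       mean = round_half_away(mean(acc), 1),
       min = round_half_away(min(acc), 1),
       max = round_half_away(max(acc), 1))
}

#' Column aggregate statistics (table footer convention)
#'
#' Arithmetic mean, extrema and sample standard deviation (n - 1), rounded
#' half away from zero to `digits` decimals (`digits = NULL` for unrounded).
#'
#' @param values numeric column.
#' @param digits decimal places, or NULL.
#' @return list `mean`, `max`, `min`, `sd`.
#' @export
column_stats <- function(values, digits = 1) {
  if (length(values) < 2L) stop("need n >= 2 for the sample sd")
  out <- list(mean = mean(values), max = max(values), min = min(values),
              sd = stats::sd(values))
  if (!is.null(digits)) out <- lapply(out, round_half_away, digits = digits)
  out
}

#' Load a packaged reference table
#'
#' The package ships four healthy-cohort reference tables as plain CSV:
#' `table1` (25 hold-time comparison sets: total time, classifier and
#' test-rig hold times, percent difference), `table4` (20 participants:
#' per-phase total and hold times and hold percentage), `table5` (20
#' participants: per-axis maximum angular velocities per phase, deg/s) and
#' `table6` (20 participants: per-axis mean peak accelerations per phase,
#' m/s^2).
#'
#' @param name one of `"table1"`, `"table4"`, `"table5"`, `"table6"`.
#' @return data.frame.
#' @export
load_fixture <- function(name) {
  if (!name %in% c("table1", "table4", "table5", "table6"))
    stop(sprintf("unknown fixture '%s'", name))
  path <- system.file("extdata", paste0(name, ".csv"), package = "handdex")
  if (path == "") stop("fixture file not installed")
  utils::read.csv(path)
}
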