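# Observer-reliability metrics for repeated similarity measurements: the
# technical error of measurement (TEM), its percentage of the grand mean
# (rTEM), and the coefficient of reliability R (the proportion of
# between-subject variance free of measurement error). Two sessions per
# subject; the multi-observer generalized TEM is out of scope.

check_repeats <- function(data) {
  need <- c("subject_id", "m1", "m2")
  if (!all(need %in% names(data)))
    stop("repeated-measures data needs columns: ", paste(need, collapse = ", "))
  if (nrow(data) < 2L) stop("need at least 2 subjects")
  if (anyNA(data$m1) || anyNA(data$m2)) stop("both measurements must be present per row")
  data
}

#' Technical error of measurement
#'
#' `TEM = sqrt(sum(d_i^2) / (2 n))` with `d_i` the within-subject difference
#' between the two sessions; same units as the measurements.
#'
#' @param data data frame with columns `subject_id`, `m1`, `m2`.
#' @return TEM (non-negative scalar).
#' @export
tem <- function(data) {
  data <- check_repeats(data)
  d <- data$m1 - data$m2
  sqrt(sum(d^2) / (2 * nrow(data)))
}

#' Relative technical error of measurement
#'
#' `rTEM = TEM / grand mean * 100`, the TEM as a percentage of the mean of
#' all `2 n` measurements. Conventional acceptance bounds are < 1.5% for
#' intra-observer and < 2.0% for inter-observer error.
#'
#' @param data data frame with columns `subject_id`, `m1`, `m2`.
#' @return rTEM in percent.
#' @export
rtem <- function(data) {
  data <- check_repeats(data)
  gm <- mean(c(data$m1, data$m2))
  if (gm <= 0) stop("grand mean must be positive")
  tem(data) / gm * 100
}

#' Coefficient of reliability
#'
#' `R = 1 - TEM^2 / s^2`, the proportion of the between-subject variance
#' free of measurement error. By default `s^2` is the sample variance
#' (n - 1 denominator) of all `2 n` pooled measurements; the
#' `"subject_mean"` variant uses the variance of the per-subject session
#' means instead. Values above 0.75 conventionally indicate sufficient
#' precision.
#'
#' @param data data frame with columns `subject_id`, `m1`, `m2`.
#' @param variance `"pooled"` (default) or `"subject_mean"`.
#' @return R (at most 1).
#' @export
coefficient_reliability <- function(data, variance = c("pooled", "subject_mean")) {
  variance <- match.arg(variance)
  data <- check_repeats(data)
  s2 <- switch(variance,
               pooled = stats::var(c(data$m1, data$m2)),
               subject_mean = stats::var((data$m1 + data$m2) / 2))
  if (s2 == 0) stop("zero variance across measurements")
  1 - tem(data)^2 / s2
}

#' Reliability summary with acceptance verdicts
#'
#' Bundles TEM, rTEM and R for a two-session repeated-measures table and
#' reports whether rTEM is inside the conventional bound for the observer
#' design (< 1.5% intra-observer, < 2.0% inter-observer) and whether
#' R > 0.75.
#'
#' @param data data frame with columns `subject_id`, `m1`, `m2`.
#' @param observer `"intra"` or `"inter"` (selects the rTEM bound).
#' @param variance passed to [coefficient_reliability()].
#' @return a `sinus_reliability` list: `tem`, `rtem_percent`, `R`, `n`,
#'   `observer`, `rtem_pass`, `R_pass`.
#' @export
reliability_eval <- function(data, observer = c("intra", "inter"),
                             variance = c("pooled", "subject_mean")) {
  observer <- match.arg(observer)
  data <- check_repeats(data)
  t <- tem(data); rt <- rtem(data)
  R <- coefficient_reliability(data, variance)
  bound <- if (observer == "intra") 1.5 else 2.0
  structure(list(tem = t, rtem_percent = rt, R = R, n = nrow(data),
                 observer = observer, rtem_bound = bound,
                 rtem_pass = rt < bound, R_pass = R > 0.75),
            class = "sinus_reliability")
}

#' @export
print.sinus_reliability <- function(x, ...) {
  cat(sprintf("reliability (n = %d, %s-observer):\n", x$n, x$observer))
  cat(sprintf("  TEM  = %.4f\n  rTEM = %.2f%% (bound %.1f%%: %s)\n  R    = %.3f (bound 0.75: %s)\n",
              x$tem, x$rtem_percent, x$rtem_bound,
              if (x$rtem_pass) "pass" else "FAIL",
              x$R, if (x$R_pass) "pass" else "FAIL"))
  invisible(x)
}
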