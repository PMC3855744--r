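#' Two-phase linear migration rate fit
#'
#' Implements the published regression construction: the early rate is a
#' zero-intercept least-squares slope over points at t <= 2 min augmented
#' with the implicit (0, 0) point (migration is zero at the moment of
#' photoactivation; with only the 2-min frame available this reduces to
#' `steps(2) / 2`, the dashed line of the published figures), and the late
#' rate is the ordinary least-squares slope with free intercept over points
#' at t >= 2 min (the solid line). `window_total` is the number of m-steps
#' migrated over the 18-min window starting at the first frame,
#' `steps(t_first + 18) - steps(t_first)` (interpolated between frames if
#' needed, extrapolated at the late rate beyond the last frame).
#'
#' @param curve a [migration_curve()], or a data.frame with columns
#'   `time` (or `time_min`) and `steps`.
#' @return A `two_phase_fit` with fields `rate_early`, `rate_late`,
#'   `intercept_late`, `n_points` (early/late counts), `window_total`.
#' @export
fit_two_phase <- function(curve) {
  if (inherits(curve, "migration_curve")) {
    t <- curve$times; s <- curve$steps
  } else {
    df <- as.data.frame(curve)
    tc <- intersect(c("time", "time_min", "times"), names(df))[1]
    if (is.na(tc) || !"steps" %in% names(df))
      stop("curve must have time and steps columns", call. = FALSE)
    t <- df[[tc]]; s <- df$steps
  }
  o <- order(t); t <- t[o]; s <- s[o]

  late <- t >= 2
  if (sum(late) < 2)
    stop("need at least 2 points with t >= 2 min for the late-phase fit",
         call. = FALSE)
  early <- t <= 2
  if (any(early)) {
    te <- t[early]; se <- s[early]  # (0, 0) contributes nothing to the sums
    rate_early <- max(0, sum(te * se) / sum(te^2))
    n_early <- sum(early) + 1L
  } else {
    warning("no points at t <= 2 min; early rate unavailable")
    rate_early <- NA_real_
    n_early <- 0L
  }

  tl <- t[late]; sl <- s[late]
  rate_late <- sum((tl - mean(tl)) * (sl - mean(sl))) / sum((tl - mean(tl))^2)
  intercept_late <- mean(sl) - rate_late * mean(tl)
  if (rate_late < 0)
    warning("negative late-phase migration rate (front noise?)")

  t_first <- t[1]
  target <- t_first + 18
  s_target <- if (target <= max(t)) {
    approx(t, s, xout = target)$y
  } else {
    s[length(s)] + rate_late * (target - max(t))
  }
  structure(list(rate_early = rate_early, rate_late = rate_late,
                 intercept_late = intercept_late,
                 n_points = c(early = n_early, late = sum(late)),
                 window_total = s_target - s[1]),
            class = "two_phase_fit")
}

#' @export
print.two_phase_fit <- function(x, ...) {
  cat(sprintf(paste0("<two_phase_fit> early %.3f m-steps/min (dashed), ",
                     "late %.3f m-steps/min (solid), 18-min total %.2f\n"),
              x$rate_early, x$rate_late, x$window_total))
  invisible(x)
}

#' Ratio of two migration rates, rounded as published
#'
#' @param rate_a numerator rate.
#' @param rate_b denominator rate; must be positive.
#' @return `rate_a / rate_b` rounded to one decimal, half away from zero.
#' @export
rate_ratio <- function(rate_a, rate_b) {
  check_scalar(rate_a, "rate_a")
  check_scalar(rate_b, "rate_b")
  if (rate_b <= 0) stop("'rate_b' must be > 0", call. = FALSE)
  round_half_away(rate_a / rate_b, 1)
}

#' Cohort summary of two-phase fits
#'
#' Mean and SEM of the 18-min migration total, mean rates, and an
#' equal-variance two-sample Student's t test of the totals against a
#' reference cohort (the statistic the original study reported as
#' mean +/- S.E.M. with Student's t test).
#'
#' @param fits list of [fit_two_phase()] results for the cohort.
#' @param reference list of fits for the reference cohort.
#' @param condition,ref_name labels carried into the summary.
#' @return A `group_summary` list.
#' @export
group_summary <- function(fits, reference, condition = "group",
                          ref_name = "reference") {
  pull <- function(fl, f) vapply(fl, function(x) x[[f]], numeric(1))
  if (length(fits) < 2 || length(reference) < 2)
    stop("group_summary needs n >= 2 fits in each group", call. = FALSE)
  wt <- pull(fits, "window_total")
  wr <- pull(reference, "window_total")
  degenerate <- sd(wt) == 0 && sd(wr) == 0
  p <- if (degenerate) NA_real_ else
    t.test(wt, wr, var.equal = TRUE)$p.value
  structure(list(condition = condition, reference = ref_name,
                 n = length(wt),
                 mean_total = mean(wt), sem_total = sd(wt) / sqrt(length(wt)),
                 mean_rate_early = mean(pull(fits, "rate_early")),
                 mean_rate_late = mean(pull(fits, "rate_late")),
                 p_value = p, degenerate = degenerate),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(paste0("<group_summary> %s (n=%d): %.2f +/- %.2f m-steps/18 min; ",
                     "rates %.2f / %.3f m-steps/min; p=%.3g vs %s\n"),
              x$condition, x$n, x$mean_total, x$sem_total,
              x$mean_rate_early, x$mean_rate_late, x$p_value, x$reference))
  invisible(x)
}
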