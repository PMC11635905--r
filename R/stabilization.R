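#' Time until 95% of the drop to the lower asymptote is completed
#'
#' For asymptotic and logistic fits, decay is considered stabilized once the
#' fitted value has completed 95% of the total drop from its starting value
#' f(0) to the lower asymptote: f(t*) = f(0) - 0.95 * (f(0) - asymptote).
#' Closed forms: asymptotic t* = ln(20) * exp(-lam); logistic
#' t* = m + s * ln(20 * (1 + exp(-m/s)) - 1). The reported day is the ceiling
#' of t*. Estimates are confined to the observed window: if t* exceeds the
#' last observed occasion the day is `NA` with `within_window = FALSE` (no
#' extrapolation).
#'
#' @param fit A converged `trajectory_fit` of the asymptotic or logistic
#'   family, with a decreasing trajectory.
#' @param from For logistic fits, measure the drop from the fitted value at
#'   t = 0 (`"f0"`, default) or from the upper asymptote U (`"upper"`).
#' @return One-row data frame (a StabilizationEstimate): `method`
#'   `"asymptote95"`, `t_star` (continuous solution), `day` (ceiling, or NA),
#'   `within_window`.
#' @export
time_to_95_asymptote <- function(fit, from = c("f0", "upper")) {
  from <- match.arg(from)
  stopifnot(inherits(fit, "trajectory_fit"), fit$converged)
  if (!fit$family %in% c("asymptotic", "logistic")) {
    stop("asymptote95 is defined for asymptotic/logistic fits only", call. = FALSE)
  }
  if (!check_decreasing(fit)) {
    stop("asymptote95 requires a decreasing fitted trajectory", call. = FALSE)
  }
  th <- fit$theta
  if (fit$family == "asymptotic") {
    t_star <- log(20) * exp(-th[["lam"]])
  } else {
    m <- th[["m"]]; s <- th[["s"]]
    if (from == "f0") {
      t_star <- m + s * log(20 * (1 + exp(-m / s)) - 1)
    } else {
      # drop measured from U: f(t*) = L + 0.05 (U - L)
      t_star <- m + s * log(19)
    }
  }
  t_last <- max(fit$t)
  within <- t_star <= t_last
  data.frame(method = "asymptote95", t_star = as.numeric(t_star),
             day = if (within) ceiling(t_star) else NA_real_,
             within_window = within, stringsAsFactors = FALSE)
}

#' Time until fitted change over a 7-day window falls below a threshold
#'
#' Scans integer occasions t = 0, 1, ... and returns the first t whose
#' 7-day-window endpoints satisfy |f(t + 6) - f(t)| < threshold, with the
#' window fully inside the observed series. Intended for the polynomial
#' families but computable for any fit.
#'
#' @param fit A converged `trajectory_fit`.
#' @param threshold Change threshold (default 0.1; 0.01 is the stricter
#'   alternative).
#' @param window Window length in days (default 7).
#' @return One-row data frame: `method` `"window7"`, `day` (or NA),
#'   `within_window`.
#' @export
time_to_window_stability <- function(fit, threshold = 0.1, window = 7L) {
  stopifnot(inherits(fit, "trajectory_fit"), fit$converged, window >= 2L)
  t_last <- max(fit$t)
  t_max_start <- t_last - (window - 1L)
  if (t_max_start < 0L) {
    return(data.frame(method = "window7", day = NA_real_,
                      within_window = FALSE, stringsAsFactors = FALSE))
  }
  for (t0 in 0:t_max_start) {
    f0 <- evaluate_trajectory(fit$family, fit$theta, t0)
    f1 <- evaluate_trajectory(fit$family, fit$theta, t0 + window - 1L)
    if (abs(f1 - f0) < threshold) {
      return(data.frame(method = "window7", day = as.numeric(t0),
                        within_window = TRUE, stringsAsFactors = FALSE))
    }
  }
  data.frame(method = "window7", day = NA_real_, within_window = FALSE,
             stringsAsFactors = FALSE)
}

#' First occasion the fitted trajectory drops below the scale midpoint
#'
#' A decreasing trajectory crossing the scale midpoint (fitted value below
#' 2.0 on the 0--4 scale) before stabilizing indicates that a substantial
#' change in habit strength occurred.
#'
#' @param fit A converged `trajectory_fit`.
#' @param stabilization_day Optional method-specific stabilization day used
#'   to set `crossed_before_stabilization`.
#' @param midpoint Scale midpoint (default 2).
#' @return One-row data frame: `method` `"midpoint_cross"`, `day` (first
#'   integer occasion with f(t) < midpoint, or NA), `within_window`,
#'   `crossed_before_stabilization`.
#' @export
midpoint_crossing <- function(fit, stabilization_day = NA_real_, midpoint = 2) {
  stopifnot(inherits(fit, "trajectory_fit"), fit$converged)
  tt <- 0:max(fit$t)
  f <- evaluate_trajectory(fit$family, fit$theta, tt)
  hit <- which(f < midpoint)
  day <- if (length(hit)) as.numeric(tt[hit[1L]]) else NA_real_
  data.frame(method = "midpoint_cross", day = day,
             within_window = length(hit) > 0L,
             crossed_before_stabilization =
               !is.na(day) && !is.na(stabilization_day) && day < stabilization_day,
             stringsAsFactors = FALSE)
}

#' Stabilization estimates for one participant's valid best fit
#'
#' Computes the family-appropriate stabilization estimate (asymptote95 for
#' asymptotic/logistic, the 7-day-window criterion for the polynomial
#' families) plus the midpoint crossing, within the observed window only.
#'
#' @param fit Best-family converged `trajectory_fit`.
#' @param threshold Threshold for the 7-day-window criterion.
#' @param window Window length in days.
#' @return Data frame of estimates with `participant_id` and `family`
#'   columns; rows for the applicable method(s) and the midpoint crossing.
#' @export
stabilization_estimates <- function(fit, threshold = 0.1, window = 7L) {
  est <- NULL
  if (fit$family %in% c("asymptotic", "logistic") && check_decreasing(fit)) {
    est <- time_to_95_asymptote(fit)
    est$t_star <- NULL
  } else if (fit$family %in% c("linear", "quadratic", "cubic", "constant")) {
    est <- time_to_window_stability(fit, threshold = threshold, window = window)
  }
  stab_day <- if (!is.null(est)) est$day else NA_real_
  mid <- midpoint_crossing(fit, stabilization_day = stab_day)
  out <- rbind(
    if (!is.null(est)) cbind(est, crossed_before_stabilization = NA),
    mid
  )
  out
}

#' Table-2-shaped summary of stabilization estimates
#'
#' Median (min, max) of the estimated days per method and best-fitting
#' family, restricted to participants whose fitted values were deemed valid
#' and cross the scale midpoint within the observed window.
#'
#' @param estimates Data frame with columns `participant_id`, `family`,
#'   `method`, `day` (stacked per-participant estimates).
#' @param verdicts Verdict table from [classify_cohort]; only
#'   `overall_valid` participants are summarized.
#' @param require_crossing Restrict to participants whose fitted values drop
#'   below the scale midpoint (default TRUE).
#' @return Data frame: `method`, `family`, `n`, `median`, `min`, `max`
#'   (days); strata with no eligible estimate keep `n = 0`.
#' @export
summarize_stabilization <- function(estimates, verdicts,
                                    require_crossing = TRUE) {
  valid_ids <- verdicts$participant_id[verdicts$overall_valid]
  est <- estimates[estimates$participant_id %in% valid_ids, , drop = FALSE]
  if (require_crossing) {
    crossed <- est$participant_id[est$method == "midpoint_cross" & !is.na(est$day)]
    est <- est[est$participant_id %in% crossed, , drop = FALSE]
  }
  methods <- unique(estimates$method)
  fams <- intersect(.families, unique(estimates$family))
  rows <- list()
  for (m in methods) {
    for (fam in fams) {
      d <- est$day[est$method == m & est$family == fam & !is.na(est$day)]
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, family = fam, n = length(d),
        median = if (length(d)) stats::median(d) else NA_real_,
        min = if (length(d)) min(d) else NA_real_,
        max = if (length(d)) max(d) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
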