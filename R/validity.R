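#' Select the best-fitting family by BIC
#'
#' The family with the lowest BIC wins. Ties (within 1e-9) are broken by the
#' smaller number of mean parameters, then by the canonical family order
#' (constant, linear, quadratic, cubic, asymptotic, logistic) -- parsimony
#' first.
#'
#' @param fits Named list of `trajectory_fit` objects for one participant.
#' @return List with `family` (best family name), `bic`, and `margin` (BIC
#'   distance to the runner-up; `Inf` with a single converged fit), or `NULL`
#'   if no fit converged (participant unmodellable).
#' @export
select_best <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged) && is.finite(f$bic), fits)
  if (length(conv) == 0L) return(NULL)
  fam <- vapply(conv, `[[`, character(1), "family")
  bic <- vapply(conv, `[[`, numeric(1), "bic")
  k <- .k_mean[fam]
  ord <- match(fam, .families)
  eligible <- bic <= min(bic) + 1e-9
  pick <- which(eligible)[order(k[eligible], ord[eligible])][1L]
  margin <- if (length(bic) > 1L) sort(bic[-pick])[1L] - bic[pick] else Inf
  list(family = fam[[pick]], bic = bic[[pick]], margin = margin)
}

#' Step 1: is the fitted trajectory decreasing?
#'
#' Compares fitted values (not raw data) at the first and last occasion of
#' the observed window: decreasing iff f(t_first) - f(t_last) > delta.
#' Constant fits are never "decreasing"; they go through the separate
#' stable-habit pathway.
#'
#' @param fit A converged `trajectory_fit`.
#' @param delta Required end-to-end drop (default 0: strict decrease).
#' @return Logical.
#' @export
check_decreasing <- function(fit, delta = 0) {
  stopifnot(inherits(fit, "trajectory_fit"), fit$converged)
  if (fit$family == "constant") return(FALSE)
  f <- evaluate_trajectory(fit$family, fit$theta, range(fit$t))
  (f[1L] - f[2L]) > delta
}

#' Step 2: is model selection stable under leave-one-out deletion?
#'
#' Deletes each observed (non-imputed) occasion in turn, refits all families
#' on the remaining occasions and reselects by BIC. Stability requires the
#' same family to win in every replicate (`rule = "unanimous"`, the default)
#' or in at least 95% of them (`rule = "agree95"`). A replicate in which the
#' refit of the selected family fails counts as unstable.
#'
#' @param series A [diary_series].
#' @param fits Full-data fits from [fit_all_families].
#' @param rule `"unanimous"` or `"agree95"`.
#' @param warm_start Use the full-data estimates (plus the data-driven
#'   default start) to start nonlinear refits (default TRUE); `FALSE` rescans
#'   the full start grid in every replicate.
#' @return Logical.
#' @export
check_loo_stability <- function(series, fits, rule = c("unanimous", "agree95"),
                                warm_start = TRUE) {
  rule <- match.arg(rule)
  best <- select_best(fits)
  if (is.null(best)) return(FALSE)
  usable <- !is.na(series$y)
  drop_idx <- which(usable & !series$imputed)
  t_all <- series$t[usable]
  y_all <- series$y[usable]
  agree <- logical(length(drop_idx))
  for (i in seq_along(drop_idx)) {
    omit <- match(drop_idx[i], which(usable))
    t <- t_all[-omit]; y <- y_all[-omit]
    refits <- lapply(.families, function(fam) {
      starts <- NULL
      if (warm_start && fam %in% c("asymptotic", "logistic") &&
          isTRUE(fits[[fam]]$converged)) {
        starts <- c(list(fits[[fam]]$theta), .default_starts(fam, t, y)[5L])
      }
      fit_trajectory(t, y, fam, starts = starts)
    })
    names(refits) <- .families
    sel <- select_best(refits)
    agree[i] <- !is.null(sel) && identical(sel$family, best$family)
  }
  if (length(agree) == 0L) return(TRUE)
  if (rule == "unanimous") all(agree) else mean(agree) >= 0.95
}

#' Step 3: is the model RMSE acceptably small?
#'
#' @param fit A converged `trajectory_fit`.
#' @param cutoff Inclusive RMSE cut-off (default 0.33).
#' @return Logical: RMSE <= cutoff.
#' @export
check_rmse <- function(fit, cutoff = 0.33) {
  stopifnot(inherits(fit, "trajectory_fit"), fit$converged)
  fit$rmse <= cutoff
}

#' Step 4: are missing gaps short enough?
#'
#' Uses post-imputation missing runs (imputation only fills singletons, so
#' runs of two or more days are unaffected).
#'
#' @param series A [diary_series].
#' @param cutoff Inclusive longest-gap cut-off in days (default 21).
#' @return Logical: longest missing run <= cutoff.
#' @export
check_gaps <- function(series, cutoff = 21L) {
  longest_gap(series) <= cutoff
}

#' Apply the 4-step validity gate to a participant's best fit
#'
#' Combines (1) a decreasing fitted trajectory, (2) leave-one-out selection
#' stability, (3) RMSE <= `rmse_cutoff`, (4) longest missing gap <=
#' `gap_cutoff`. For a best-fitting constant model the trajectory is flat by
#' construction, so overall validity ("habit stable over time") is judged on
#' steps 2--4 only and reported as `stable_habit_valid`.
#'
#' @param series A [diary_series].
#' @param fits Full-data fits from [fit_all_families].
#' @param rmse_cutoff,gap_cutoff Thresholds for steps 3 and 4.
#' @param loo_rule,warm_start Passed to [check_loo_stability].
#' @param loo Logical; skip the (expensive) step-2 refits when `FALSE`
#'   (step 2 is then recorded as `NA` and treated as passing).
#' @return One-row data frame (a ValidityVerdict): participant id, best
#'   family, BIC margin, `step1_decreasing`, `step2_loo_stable`,
#'   `step3_rmse_ok`, `step4_gap_ok`, `overall_valid`, `stable_habit_valid`,
#'   plus the thresholds used.
#' @export
classify_validity <- function(series, fits, rmse_cutoff = 0.33,
                              gap_cutoff = 21L,
                              loo_rule = "unanimous", warm_start = TRUE,
                              loo = TRUE) {
  best <- select_best(fits)
  if (is.null(best)) {
    return(data.frame(participant_id = series$id, group = series$group,
                      best_family = NA_character_, bic_margin = NA_real_,
                      step1_decreasing = NA, step2_loo_stable = NA,
                      step3_rmse_ok = NA, step4_gap_ok = NA,
                      overall_valid = FALSE, stable_habit_valid = FALSE,
                      rmse_cutoff = rmse_cutoff, gap_cutoff = gap_cutoff,
                      stringsAsFactors = FALSE))
  }
  fit <- fits[[best$family]]
  s1 <- check_decreasing(fit)
  s2 <- if (loo) check_loo_stability(series, fits, rule = loo_rule,
                                     warm_start = warm_start) else NA
  s3 <- check_rmse(fit, rmse_cutoff)
  s4 <- check_gaps(series, gap_cutoff)
  gate234 <- isTRUE(s2 %in% c(TRUE, NA)) && s3 && s4
  data.frame(participant_id = series$id, group = series$group,
             best_family = best$family, bic_margin = best$margin,
             step1_decreasing = s1, step2_loo_stable = s2,
             step3_rmse_ok = s3, step4_gap_ok = s4,
             overall_valid = (best$family != "constant") && s1 && gate234,
             stable_habit_valid = (best$family == "constant") && gate234,
             rmse_cutoff = rmse_cutoff, gap_cutoff = gap_cutoff,
             stringsAsFactors = FALSE)
}

#' Validity verdicts for a whole cohort
#'
#' @param series_list List of [diary_series].
#' @param fits_by_participant Matching named list of [fit_all_families]
#'   outputs (computed when missing).
#' @param ... Passed to [classify_validity].
#' @return Data frame of verdicts, one row per participant.
#' @export
classify_cohort <- function(series_list, fits_by_participant = NULL, ...) {
  if (is.null(fits_by_participant)) {
    fits_by_participant <- lapply(series_list, fit_all_families)
  }
  out <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    classify_validity(series_list[[i]], fits_by_participant[[i]], ...)
  }))
  rownames(out) <- NULL
  out
}
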