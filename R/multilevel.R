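#' Rescale time for multilevel modelling
#'
#' Maps occasions 0..t_max affinely onto [0, upper] (default upper 1.72) to
#' improve mixed-model convergence. The map is order-preserving and its
#' inverse is returned, so fitted values are invariant to the choice.
#'
#' @param t Occasion vector.
#' @param t_max Maximum occasion (default `max(t)`).
#' @param upper Upper end of the rescaled range (default 1.72).
#' @return Numeric vector of rescaled times, with attributes `scale`
#'   (= upper / t_max) and `inverse` (function mapping back to days).
#' @export
rescale_time <- function(t, t_max = max(t), upper = 1.72) {
  stopifnot(t_max > 0)
  sc <- upper / t_max
  out <- t * sc
  attr(out, "scale") <- sc
  attr(out, "inverse") <- function(tp) tp / sc
  out
}

#' Variance decomposition of habit strength (constant multilevel model)
#'
#' Fits the random-intercept-only ("constant") mixed model by maximum
#' likelihood and reports the intraclass correlation coefficient
#' ICC = sigma2_between / (sigma2_between + sigma2_within): the share of
#' outcome variance due to stable between-person differences.
#'
#' @param data Long data frame with columns `participant_id` and `y`.
#' @return List of class `multilevel_result`: `model = "constant"`,
#'   `fixed` (intercept estimate with 95% Wald CI), `sigma2_between`,
#'   `sigma2_within`, `icc`, `bic`, `flags` (character; degenerate cases are
#'   flagged rather than hidden).
#' @export
fit_constant_icc <- function(data) {
  stopifnot(all(c("participant_id", "y") %in% names(data)))
  ids <- unique(data$participant_id)
  if (length(ids) < 2L) {
    return(.ml_result("constant", fixed = NULL, s2b = 0, s2w = NA_real_,
                      icc = NA_real_, bic = NA_real_,
                      flags = "needs >= 2 participants"))
  }
  within_var <- tapply(data$y, data$participant_id, stats::var)
  if (all(is.na(within_var) | within_var == 0)) {
    means <- tapply(data$y, data$participant_id, mean)
    if (stats::var(means) == 0) {
      return(.ml_result("constant", fixed = NULL, s2b = 0, s2w = 0,
                        icc = 0, bic = NA_real_,
                        flags = "degenerate: no variance at all (ICC at 0 boundary)"))
    }
    warning("zero within-person variance: ICC = 1", call. = FALSE)
    return(.ml_result("constant", fixed = NULL, s2b = stats::var(means),
                      s2w = 0, icc = 1, bic = NA_real_,
                      flags = "degenerate: zero within-person variance"))
  }
  fit <- lme4::lmer(y ~ 1 + (1 | participant_id), data = data, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2b <- vc$vcov[vc$grp == "participant_id"]
  s2w <- vc$vcov[vc$grp == "Residual"]
  icc <- s2b / (s2b + s2w)
  flags <- character(0)
  if (lme4::isSingular(fit)) flags <- "singular fit (ICC at boundary)"
  .ml_result("constant", fixed = .fixef_table(fit), s2b = s2b, s2w = s2w,
             icc = icc, bic = stats::BIC(fit), flags = flags, fit = fit)
}

.ml_result <- function(model, fixed, s2b, s2w, icc, bic, flags = character(0),
                       fit = NULL, random = NULL) {
  structure(list(model = model, fixed = fixed, sigma2_between = s2b,
                 sigma2_within = s2w, icc = icc, bic = bic,
                 random = random, flags = flags, fit = fit),
            class = "multilevel_result")
}

#' @export
print.multilevel_result <- function(x, ...) {
  cat(sprintf("<multilevel_result> %s model, BIC = %.2f\n", x$model,
              if (is.finite(x$bic)) x$bic else NA))
  if (!is.null(x$icc) && is.finite(x$icc)) cat(sprintf("  ICC = %.3f\n", x$icc))
  if (!is.null(x$fixed)) { cat("  fixed effects:\n"); print(x$fixed) }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

.fixef_table <- function(fit) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  data.frame(term = names(est), estimate = as.numeric(est), se = se,
             ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cubic multilevel growth model with optional group contrast
#'
#' Linear mixed model with a fixed cubic polynomial in rescaled time,
#' person-level random effects added iteratively (intercept up to the full
#' cubic), and optionally a dichotomous focal-group contrast: a main effect
#' of belonging to `focal_group` (vs the average of the other groups) and,
#' if `group_interactions = TRUE`, its interactions with the time terms.
#' Estimated by maximum likelihood so BICs are comparable across
#' fixed-effect structures.
#'
#' @param data Long data frame with `participant_id`, `t` (occasions),
#'   `y`, and `group` when a contrast is requested.
#' @param random One of `"intercept"`, `"linear"`, `"quadratic"`, `"cubic"`:
#'   highest-order time term with a random effect.
#' @param focal_group Optional group label for the dichotomous contrast.
#' @param group_interactions Add focal-group x time interactions.
#' @param upper Upper end of the rescaled time range.
#' @return A `multilevel_result`; `fixed` contains estimates with 95% Wald
#'   CIs, `random` the random-effect variances, and singular fits are
#'   flagged but retained.
#' @export
fit_cubic_mlm <- function(data, random = c("cubic", "intercept", "linear",
                                           "quadratic"),
                          focal_group = NULL, group_interactions = FALSE,
                          upper = 1.72) {
  random <- match.arg(random)
  stopifnot(all(c("participant_id", "t", "y") %in% names(data)))
  d <- data.frame(participant_id = data$participant_id, y = data$y)
  tp <- rescale_time(data$t, t_max = max(data$t), upper = upper)
  d$t1 <- as.numeric(tp); d$t2 <- d$t1^2; d$t3 <- d$t1^3
  fx <- "y ~ t1 + t2 + t3"
  if (!is.null(focal_group)) {
    stopifnot("group" %in% names(data))
    d$g <- as.numeric(data$group == focal_group)
    fx <- paste(fx, "+ g")
    if (group_interactions) fx <- paste(fx, "+ g:t1 + g:t2 + g:t3")
  }
  re <- switch(random,
               intercept = "(1 | participant_id)",
               linear = "(1 + t1 | participant_id)",
               quadratic = "(1 + t1 + t2 | participant_id)",
               cubic = "(1 + t1 + t2 + t3 | participant_id)")
  form <- stats::as.formula(paste(fx, "+", re))
  conv_msgs <- character(0)
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(form, data = d, REML = FALSE,
                                control = lme4::lmerControl(
                                  check.conv.singular = "ignore"))),
    warning = function(w) {
      conv_msgs <<- c(conv_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2w <- vc$vcov[vc$grp == "Residual"]
  flags <- conv_msgs
  if (lme4::isSingular(fit)) flags <- c(flags, "singular random-effects covariance")
  res <- .ml_result(paste0("cubic_mlm_random_", random),
                    fixed = .fixef_table(fit),
                    s2b = sum(vc$vcov[vc$grp != "Residual" & is.na(vc$var2)]),
                    s2w = s2w, icc = NULL, bic = stats::BIC(fit),
                    flags = flags, fit = fit,
                    random = vc)
  res$time_scale <- attr(tp, "scale")
  res$focal_group <- focal_group
  res
}

#' Iterative random-effect ladder for the cubic multilevel model
#'
#' Adds random effects from lower to higher order (intercept, + linear,
#' + quadratic, + cubic) and reports the BIC of each step.
#'
#' @param data As in [fit_cubic_mlm].
#' @param ... Passed to [fit_cubic_mlm].
#' @return List with `results` (the fitted `multilevel_result`s) and
#'   `ladder` (the [compare_models] table).
#' @export
cubic_mlm_ladder <- function(data, ...) {
  specs <- c("intercept", "linear", "quadratic", "cubic")
  results <- lapply(specs, function(r) fit_cubic_mlm(data, random = r, ...))
  names(results) <- specs
  list(results = results, ladder = compare_models(results))
}

#' Two-stage estimator of the asymptotic multilevel model
#'
#' Stage 1 fits the person-specific asymptotic curve (A_i, R0_i, lam_i) by
#' bounded nonlinear least squares; stage 2 combines them: fixed effects are
#' precision-weighted means of the person estimates, and the random-effect
#' covariance is the between-person moment estimator with the average
#' stage-1 sampling covariance subtracted and projected back to positive
#' semi-definiteness. This estimator is deterministic and robust where a
#' full nonlinear mixed model is fragile; a full-likelihood fit can be
#' plugged in via `stage2` later.
#'
#' @param series_list List of [diary_series] (retained participants).
#' @param min_occasions Minimum usable occasions for a stage-1 fit.
#' @param max_failure_rate Abort (non-estimable) if more than this fraction
#'   of stage-1 fits fail (default 0.5).
#' @return A `multilevel_result` with `fixed` (A, R0, lam with approximate
#'   95% CIs), `random` (between-person covariance), `stage1` (per-person
#'   estimates) and diagnostics (`stage1_failure_rate`) in `flags`.
#' @export
fit_asymptotic_mlm <- function(series_list, min_occasions = 8L,
                               max_failure_rate = 0.5) {
  est <- list(); vars <- list(); ids <- character(0)
  n_fail <- 0L
  for (s in series_list) {
    obs <- !is.na(s$y)
    if (sum(obs) < min_occasions) { n_fail <- n_fail + 1L; next }
    fit <- fit_trajectory(s$t[obs], s$y[obs], "asymptotic")
    if (!fit$converged || any(!is.finite(fit$theta))) { n_fail <- n_fail + 1L; next }
    V <- .asym_sampling_cov(fit)
    est[[length(est) + 1L]] <- fit$theta
    vars[[length(vars) + 1L]] <- V
    ids <- c(ids, s$id)
  }
  fail_rate <- n_fail / max(length(series_list), 1L)
  if (fail_rate > max_failure_rate || length(est) < 2L) {
    return(.ml_result("asymptotic_two_stage", fixed = NULL, s2b = NA_real_,
                      s2w = NA_real_, icc = NULL, bic = NA_real_,
                      flags = sprintf("non-estimable: stage-1 failure rate %.2f",
                                      fail_rate)))
  }
  Th <- do.call(rbind, est)                       # N x 3
  Vd <- t(vapply(vars, diag, numeric(3L)))        # N x 3 sampling variances
  W <- 1 / pmax(Vd, 1e-8)
  fixed_est <- colSums(Th * W) / colSums(W)
  S_raw <- stats::cov(Th)
  V_bar <- Reduce(`+`, vars) / length(vars)
  S_b <- .psd_project(S_raw - V_bar)
  N <- nrow(Th)
  se <- sqrt(pmax(diag(S_b) + diag(V_bar), 0) / N)
  fixed <- data.frame(term = c("A", "R0", "lam"),
                      estimate = as.numeric(fixed_est), se = se,
                      ci_lo = fixed_est - 1.96 * se,
                      ci_hi = fixed_est + 1.96 * se,
                      row.names = NULL, stringsAsFactors = FALSE)
  res <- .ml_result("asymptotic_two_stage", fixed = fixed,
                    s2b = sum(diag(S_b)), s2w = NA_real_, icc = NULL,
                    bic = NA_real_,
                    flags = sprintf("stage-1 failure rate %.2f", fail_rate))
  res$random <- S_b
  res$stage1 <- data.frame(participant_id = ids, A = Th[, 1], R0 = Th[, 2],
                           lam = Th[, 3], stringsAsFactors = FALSE)
  res
}

# Gauss-Newton sampling covariance sigma2 * (J'J)^-1 of a stage-1 fit
.asym_sampling_cov <- function(fit) {
  th <- fit$theta; t <- fit$t
  r <- exp(th[["lam"]])
  e <- exp(-r * t)
  J <- cbind(A = 1 - e,
             R0 = e,
             lam = -(th[["R0"]] - th[["A"]]) * t * r * e)
  dof <- max(length(t) - 3L, 1L)
  sigma2 <- fit$sse / dof
  JtJ <- crossprod(J)
  Vi <- tryCatch(sigma2 * solve(JtJ), error = function(e2) {
    sigma2 * MASS_ginv(JtJ)
  })
  (Vi + t(Vi)) / 2
}

# small pseudo-inverse (avoids importing MASS for one call)
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1L]
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# project a symmetric matrix to the nearest positive semi-definite matrix
.psd_project <- function(S) {
  S <- (S + t(S)) / 2
  ei <- eigen(S, symmetric = TRUE)
  d <- pmax(ei$values, 0)
  out <- ei$vectors %*% diag(d, length(d)) %*% t(ei$vectors)
  dimnames(out) <- dimnames(S)
  out
}

#' Compare fitted multilevel models by BIC
#'
#' @param results List of `multilevel_result` objects fitted to the same
#'   data.
#' @return Data frame sorted by BIC (ascending, stable for ties): `model`,
#'   `bic`, `delta_bic`, `flags`.
#' @export
compare_models <- function(results) {
  stopifnot(length(results) >= 1L)
  tab <- data.frame(
    model = vapply(results, `[[`, character(1), "model"),
    bic = vapply(results, function(r) as.numeric(r$bic), numeric(1)),
    flags = vapply(results, function(r) paste(r$flags, collapse = "; "),
                   character(1)),
    stringsAsFactors = FALSE)
  ord <- order(tab$bic, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  tab$delta_bic <- tab$bic - tab$bic[1L]
  rownames(tab) <- NULL
  tab[c("model", "bic", "delta_bic", "flags")]
}

#' Lag-1 autocorrelation of within-person residuals
#'
#' Reported as a diagnostic only; the growth models do not model residual
#' autocorrelation.
#'
#' @param fit A fitted `multilevel_result` carrying its lme4 fit.
#' @param data The data the model was fitted to (with `participant_id`).
#' @return Mean per-person lag-1 residual autocorrelation.
#' @export
residual_lag1 <- function(fit, data) {
  stopifnot(!is.null(fit$fit))
  r <- stats::residuals(fit$fit)
  ac <- tapply(r, data$participant_id, function(x) {
    if (length(x) < 3L) return(NA_real_)
    stats::cor(x[-1L], x[-length(x)])
  })
  mean(ac, na.rm = TRUE)
}
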