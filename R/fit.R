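#' Fit one trajectory family to a person's habit-strength series
#'
#' Polynomial families are solved by exact ordinary least squares. The
#' asymptotic and logistic families are fitted by bounded nonlinear least
#' squares (`nls` with the "port" algorithm, `optim`/L-BFGS-B as a fallback)
#' from a deterministic multi-start grid: level parameters are initialised
#' from the means of the first and last five observed values, shape
#' parameters from a coarse fixed grid, and the start with the lowest SSE
#' wins (ties keep the earliest start). No autoregressive term is included:
#' the fit describes the shape of the trajectory only.
#'
#' @param t Integer vector of occasions (0-based days) with a usable value.
#' @param y Numeric vector of habit-strength scores at `t` (observed or
#'   imputed occasions; missing days are simply absent, never zero-filled).
#' @param family Trajectory family name.
#' @param starts Optional list of numeric start vectors for the nonlinear
#'   families, replacing the default grid (used e.g. for warm-started
#'   leave-one-out refits).
#' @return An object of class `trajectory_fit`: list with `family`, `theta`
#'   (named), `t`, `y`, `fitted` (at `t`), `sse`, `n_obs`, `rmse`, `bic`,
#'   `converged`.
#' @export
fit_trajectory <- function(t, y, family, starts = NULL) {
  .check_family(family)
  keep <- is.finite(y) & is.finite(t)
  t <- as.numeric(t[keep]); y <- as.numeric(y[keep])
  n <- length(y)
  k_mean <- .k_mean[[family]]
  if (n < k_mean + 2L) {
    return(.traj_fit(family, theta = rep(NA_real_, k_mean), t = t, y = y,
                     converged = FALSE))
  }
  ord <- order(t)
  t <- t[ord]; y <- y[ord]

  if (family %in% c("constant", "linear", "quadratic", "cubic")) {
    deg <- k_mean - 1L
    X <- outer(t, 0:deg, `^`)
    beta <- stats::lm.fit(X, y)$coefficients
    beta[is.na(beta)] <- 0
    return(.traj_fit(family, theta = as.numeric(beta), t = t, y = y,
                     converged = TRUE))
  }

  bounds <- .traj_bounds(family)
  if (is.null(starts)) starts <- .default_starts(family, t, y)
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, bounds$lower + 1e-9), bounds$upper - 1e-9)
    fit <- .fit_nls_port(family, t, y, st, bounds)
    if (is.null(fit)) fit <- .fit_lbfgsb(family, t, y, st, bounds)
    if (is.null(fit)) next
    if (is.null(best) || fit$sse < best$sse - 1e-12) best <- fit
  }
  if (is.null(best)) {
    return(.traj_fit(family, theta = rep(NA_real_, k_mean), t = t, y = y,
                     converged = FALSE))
  }
  .traj_fit(family, theta = best$theta, t = t, y = y, converged = TRUE)
}

.traj_fit <- function(family, theta, t, y, converged) {
  names(theta) <- .par_names[[family]]
  n <- length(y)
  if (converged) {
    fitted <- evaluate_trajectory(family, theta, t)
    sse <- sum((y - fitted)^2)
    rmse <- sqrt(sse / n)
    bic <- bic_from_sse(sse, n, .k_mean[[family]])
  } else {
    fitted <- rep(NA_real_, n); sse <- NA_real_; rmse <- NA_real_; bic <- NA_real_
  }
  structure(
    list(family = family, theta = theta, t = t, y = y, fitted = fitted,
         sse = sse, n_obs = n, rmse = rmse, bic = bic, converged = converged),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %s, n = %d, converged = %s\n",
              x$family, x$n_obs, x$converged))
  if (x$converged) {
    cat("  theta:", paste(sprintf("%s = %.4g", names(x$theta), x$theta),
                          collapse = ", "), "\n")
    cat(sprintf("  SSE = %.4g, RMSE = %.4g, BIC = %.4g\n", x$sse, x$rmse, x$bic))
  }
  invisible(x)
}

# deterministic start grid: 9 starts per nonlinear family
.default_starts <- function(family, t, y) {
  head_mean <- mean(utils::head(y, 5L))
  tail_mean <- mean(utils::tail(y, 5L))
  if (family == "asymptotic") {
    rates <- c(0.01, 0.02, 0.04, 0.08, 0.15, 0.3, 0.6, 1, 1.9)
    lapply(log(rates), function(l) c(A = tail_mean, R0 = head_mean, lam = l))
  } else {
    ms <- as.numeric(stats::quantile(t, c(0.25, 0.5, 0.75), names = FALSE))
    ss <- c(2, 8, 25)
    grid <- expand.grid(m = ms, s = ss)
    lapply(seq_len(nrow(grid)), function(i) {
      c(L = tail_mean, U = head_mean, m = grid$m[i], s = grid$s[i])
    })
  }
}

.nls_formula <- function(family) {
  if (family == "asymptotic") {
    y ~ A + (R0 - A) * exp(-exp(lam) * t)
  } else {
    y ~ L + (U - L) / (1 + exp((t - m) / s))
  }
}

.fit_nls_port <- function(family, t, y, start, bounds) {
  fit <- tryCatch(
    stats::nls(.nls_formula(family),
               data = list(t = t, y = y),
               start = as.list(start),
               algorithm = "port",
               lower = bounds$lower, upper = bounds$upper,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(NULL)
  theta <- stats::coef(fit)[.par_names[[family]]]
  sse <- sum((y - evaluate_trajectory(family, theta, t))^2)
  list(theta = as.numeric(theta), sse = sse)
}

.fit_lbfgsb <- function(family, t, y, start, bounds) {
  obj <- function(th) {
    r <- y - evaluate_trajectory(family, th, t)
    sum(r * r)
  }
  res <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = list(maxit = 500, factr = 1e4)),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$value)) return(NULL)
  list(theta = as.numeric(res$par), sse = res$value)
}

#' Gaussian-likelihood BIC from a residual sum of squares
#'
#' BIC = n * log(max(SSE, eps) / n) + k * log(n), with k = `k_mean` + 1 so the
#' error variance is counted as a parameter. The `eps` floor keeps the BIC
#' finite on perfect (noise-free) fits; because every floored fit hits the
#' same floor, selection among them falls back to the parsimony penalty.
#'
#' @param sse Residual sum of squares.
#' @param n Number of occasions that entered the fit (observed + imputed).
#' @param k_mean Number of mean-structure parameters of the family.
#' @param eps Floor on the SSE (default 1e-10).
#' @return The BIC value (lower is better).
#' @export
bic_from_sse <- function(sse, n, k_mean, eps = 1e-10) {
  stopifnot(n > 0)
  k <- k_mean + 1
  n * log(max(sse, eps) / n) + k * log(n)
}

#' Fit all six trajectory families to one diary series
#'
#' Observed and singleton-imputed occasions both enter the fit; occasions in
#' retained missing gaps are skipped.
#'
#' @param series A [diary_series] object.
#' @return Named list of `trajectory_fit` objects, one per family, in the
#'   canonical family order.
#' @export
fit_all_families <- function(series) {
  stopifnot(inherits(series, "diary_series"))
  obs <- !is.na(series$y)
  t <- series$t[obs]
  y <- series$y[obs]
  fits <- lapply(.families, function(f) fit_trajectory(t, y, f))
  names(fits) <- .families
  fits
}

#' Tabulate per-family fits for a cohort
#'
#' @param fits_by_participant Named list (by participant id) of lists of
#'   `trajectory_fit` objects as returned by [fit_all_families].
#' @return Data frame with one row per participant x family: parameters
#'   (par1..par4, NA-padded), SSE, n_obs, RMSE, BIC, convergence flag.
#' @export
fit_table <- function(fits_by_participant) {
  rows <- lapply(names(fits_by_participant), function(id) {
    fits <- fits_by_participant[[id]]
    do.call(rbind, lapply(fits, function(f) {
      th <- rep(NA_real_, 4L)
      th[seq_along(f$theta)] <- f$theta
      data.frame(participant_id = id, family = f$family,
                 par1 = th[1], par2 = th[2], par3 = th[3], par4 = th[4],
                 sse = f$sse, n_obs = f$n_obs, rmse = f$rmse, bic = f$bic,
                 converged = f$converged, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
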