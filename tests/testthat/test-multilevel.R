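sim_random_intercept <- function(n_id = 50L, n_t = 84L, mu = 2, s_b = 1,
                                 s_w = 0.5, seed = 1L) {
  set.seed(seed)
  id <- rep(sprintf("P%03d", seq_len(n_id)), each = n_t)
  u <- rep(rnorm(n_id, 0, s_b), each = n_t)
  data.frame(participant_id = id, t = rep(0:(n_t - 1L), n_id),
             y = mu + u + rnorm(n_id * n_t, 0, s_w),
             group = "SB", stringsAsFactors = FALSE)
}

test_that("ICC estimates the between-person variance share", {
  d <- sim_random_intercept(n_id = 120L, s_b = sqrt(3), s_w = 1, seed = 3L)
  res <- fit_constant_icc(d)
  # one replicate: allow ~3 sampling SDs (SD of ICC-hat ~ 0.024 at 120 ids)
  expect_lt(abs(res$icc - 0.75), 0.08)
  expect_true(is.finite(res$bic))
})

test_that("degenerate variance structures are flagged, not hidden", {
  # identical constant series: no variance at all, ICC at the 0 boundary
  d0 <- data.frame(participant_id = rep(c("a", "b"), each = 10), y = 2)
  r0 <- fit_constant_icc(d0)
  expect_equal(r0$icc, 0)
  expect_match(r0$flags, "boundary")
  # distinct constant series: zero within-person variance, ICC = 1
  d1 <- data.frame(participant_id = rep(c("a", "b"), each = 10),
                   y = rep(c(1, 3), each = 10))
  expect_warning(r1 <- fit_constant_icc(d1), "ICC = 1")
  expect_equal(r1$icc, 1)
  # a single participant duplicated has no between-person variance
  d2 <- data.frame(participant_id = rep(c("a", "b"), each = 10),
                   y = rep(sin(1:10), 2))
  r2 <- fit_constant_icc(d2)
  expect_lt(r2$sigma2_between, 1e-6)
})

test_that("time rescaling is affine and leaves fitted values invariant", {
  t <- 0:83
  tp <- rescale_time(t)
  expect_equal(range(tp), c(0, 1.72))
  expect_equal(attr(tp, "inverse")(as.numeric(tp)), as.numeric(t))
  expect_true(all(diff(as.numeric(tp)) > 0))
  # cubic fixed effects transform exactly under the affine map
  set.seed(9)
  y <- 3 - 0.03 * t + 2e-4 * t^2 + rnorm(84, 0, 0.1)
  raw <- lm(y ~ poly(t, 3, raw = TRUE))
  scl <- lm(y ~ poly(as.numeric(tp), 3, raw = TRUE))
  expect_equal(fitted(raw), fitted(scl), tolerance = 1e-8)
})

test_that("cubic MLM recovers fixed effects and reduces towards pooled OLS", {
  set.seed(11)
  n_id <- 60L; n_t <- 84L
  beta <- c(3, -1.2, 0.5, -0.08)
  id <- rep(seq_len(n_id), each = n_t)
  tp <- rescale_time(rep(0:(n_t - 1L), n_id))
  X <- cbind(1, tp, tp^2, tp^3)
  u <- rep(rnorm(n_id, 0, 0.6), each = n_t)
  d <- data.frame(participant_id = sprintf("P%03d", id),
                  t = rep(0:(n_t - 1L), n_id),
                  y = as.numeric(X %*% beta) + u + rnorm(n_id * n_t, 0, 0.3),
                  group = "SB")
  res <- fit_cubic_mlm(d, random = "intercept")
  est <- res$fixed$estimate
  se <- res$fixed$se
  expect_true(all(abs(est - beta) <= 2 * se))
  # zero noise, no random effects: fixed effects equal pooled OLS
  d0 <- d
  d0$y <- as.numeric(X %*% beta)
  res0 <- fit_cubic_mlm(d0, random = "intercept")
  ols <- lm(y ~ tp + I(tp^2) + I(tp^3), data = transform(d0, tp = as.numeric(tp)))
  expect_equal(res0$fixed$estimate, unname(coef(ols)), tolerance = 1e-4)
})

test_that("random-effect ladder prefers the generating structure by BIC", {
  d <- sim_random_intercept(n_id = 60L, seed = 13L)
  lad <- cubic_mlm_ladder(d)
  expect_equal(lad$ladder$model[1L], "cubic_mlm_random_intercept")
  expect_equal(lad$ladder$delta_bic[1L], 0)
})

test_that("model comparison sorts by BIC with a stable tie order", {
  mk <- function(name, bic) .mk <- structure(list(model = name, bic = bic,
                                                  flags = character(0)),
                                             class = "multilevel_result")
  tab <- compare_models(list(mk("a", 100), mk("b", 90)))
  expect_equal(tab$model, c("b", "a"))
  tie <- compare_models(list(mk("first", 50), mk("second", 50)))
  expect_equal(tie$model, c("first", "second"))
})

test_that("two-stage asymptotic estimator recovers population parameters", {
  set.seed(17)
  n_id <- 40L
  mu <- c(A = 1, R0 = 3.2, lam = log(0.1))
  sl <- lapply(seq_len(n_id), function(i) {
    th <- mu + c(rnorm(1, 0, 0.2), rnorm(1, 0, 0.25), rnorm(1, 0, 0.2))
    y <- evaluate_trajectory("asymptotic", th, 0:83) + rnorm(84, 0, 0.3)
    diary_series(sprintf("P%02d", i), "SB", pmin(pmax(y, 0), 4))
  })
  res <- fit_asymptotic_mlm(sl)
  est <- res$fixed$estimate
  se <- res$fixed$se
  expect_true(all(abs(est - mu) <= 2.5 * se + 0.1))
  expect_true(all(diag(res$random) >= 0))
  # population curve decreases when fixed R0 > fixed A
  pop <- evaluate_trajectory("asymptotic", est, 0:83)
  expect_true(all(diff(pop) < 0))
})

test_that("two-stage estimator is exact on noise-free homogeneous data", {
  mu <- c(A = 0.8, R0 = 3.4, lam = log(0.12))
  sl <- lapply(1:10, function(i) {
    y <- evaluate_trajectory("asymptotic", mu, 0:83)
    diary_series(sprintf("P%02d", i), "SB", y)
  })
  res <- fit_asymptotic_mlm(sl)
  expect_equal(res$fixed$estimate, unname(mu), tolerance = 1e-4)
  expect_lt(sum(diag(res$random)), 1e-6)
})

test_that("excessive stage-1 failures make the model non-estimable", {
  sl <- lapply(1:6, function(i) {
    y <- rep(NA_real_, 84); y[1:4] <- 2    # too few occasions
    diary_series(sprintf("P%02d", i), "SB", y)
  })
  res <- fit_asymptotic_mlm(sl)
  expect_match(res$flags, "non-estimable")
  expect_null(res$fixed)
})

test_that("a simulated group intercept shift is recovered by the contrast", {
  set.seed(19)
  n_per <- 40L; n_t <- 42L
  groups <- rep(c("SB", "US", "AC", "TS"), each = n_per)
  id <- sprintf("P%03d", seq_along(groups))
  rows <- lapply(seq_along(id), function(i) {
    shift <- if (groups[i] == "SB") 0.8 else 0
    u <- rnorm(1, 0, 0.4)
    t <- 0:(n_t - 1L)
    data.frame(participant_id = id[i], group = groups[i], t = t,
               y = 2.5 + shift + u - 0.5 * rescale_time(t, n_t - 1L) +
                 rnorm(n_t, 0, 0.3))
  })
  d <- do.call(rbind, rows)
  res <- fit_cubic_mlm(d, random = "intercept", focal_group = "SB")
  g <- res$fixed[res$fixed$term == "g", ]
  expect_true(abs(g$estimate - 0.8) <= 2 * g$se)
})
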