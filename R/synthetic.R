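#' Configuration for the synthetic diary cohort generator
#'
#' Defaults emulate the structure of a 91-day habit-decay diary study: four
#' behavioural groups of 46/57/52/39 participants (sedentary behaviour,
#' unhealthy snacking, alcohol, smoking), 84 daily occasions of a 0--4 SRBAI
#' score in steps of 0.25, roughly 29% missing values with long gaps biased
#' towards the second half of the series, occasional same-day duplicates and
#' after-midnight responses.
#'
#' @param group_sizes Named integer vector: participants per behavioural
#'   group.
#' @param n_days Number of daily occasions in the decay phase (>= 8).
#' @param family_mix Named probability vector over the six trajectory
#'   families, summing to 1.
#' @param param_priors Per-family list of parameter ranges (each a
#'   length-2 numeric); see [sample_family_params].
#' @param group_intercept_shift Named numeric: additive shift of the level
#'   parameters per group (group differences are simulated in the intercept
#'   only).
#' @param noise_sd_range Range of the residual SD drawn per participant.
#' @param p_isolated_missing Per-day probability of an isolated missing
#'   response.
#' @param gap_spec List describing long missing gaps: `n_prob` (probabilities
#'   of 0..k gap blocks per participant), `min_len` and `geom_mean`
#'   (length = min_len + Geometric with this mean), `late_frac` (probability
#'   a gap starts in the second half of the series). `NULL` disables gaps.
#' @param p_increasing Probability that an asymptotic/logistic participant
#'   has a non-decaying (retained or regained) habit trajectory.
#' @param p_duplicate Per-day probability of a same-day duplicate response.
#' @param p_after_midnight Probability a response is submitted after midnight
#'   (00:00--12:00 the next calendar day).
#' @param start_date Calendar date of study Day 0.
#' @param day_offset Days between `start_date` and the first decay-phase
#'   occasion (default 7).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(SB = 46L, US = 57L, AC = 52L, TS = 39L),
                          n_days = 84L,
                          family_mix = c(constant = 0.07, linear = 0.05,
                                         quadratic = 0.12, cubic = 0.16,
                                         asymptotic = 0.30, logistic = 0.30),
                          param_priors = default_param_priors(),
                          group_intercept_shift = c(SB = 0.4, US = -0.5,
                                                    AC = -0.9, TS = 0.2),
                          noise_sd_range = c(0.15, 0.45),
                          p_isolated_missing = 0.13,
                          gap_spec = list(n_prob = c(0.15, 0.35, 0.30, 0.20),
                                          min_len = 2L, geom_mean = 9,
                                          late_frac = 0.7),
                          p_increasing = 0.05,
                          p_duplicate = 0.02,
                          p_after_midnight = 0.06,
                          start_date = as.Date("2022-09-19"),
                          day_offset = 7L,
                          seed = 1L) {
  cfg <- list(group_sizes = group_sizes, n_days = as.integer(n_days),
              family_mix = family_mix, param_priors = param_priors,
              group_intercept_shift = group_intercept_shift,
              noise_sd_range = noise_sd_range,
              p_isolated_missing = p_isolated_missing, gap_spec = gap_spec,
              p_increasing = p_increasing, p_duplicate = p_duplicate,
              p_after_midnight = p_after_midnight,
              start_date = as.Date(start_date),
              day_offset = as.integer(day_offset), seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

.cfg_fail <- function(field, why) {
  stop(sprintf("invalid cohort_config field '%s': %s", field, why), call. = FALSE)
}

#' @rdname cohort_config
#' @param config A `cohort_config` to validate.
#' @export
validate_cohort_config <- function(config) {
  with(config, {
    if (length(group_sizes) < 1L || any(group_sizes < 0) ||
        is.null(names(group_sizes)) || anyDuplicated(names(group_sizes)))
      .cfg_fail("group_sizes", "must be a named vector of non-negative counts")
    if (n_days < 8L) .cfg_fail("n_days", "must be >= 8")
    if (abs(sum(family_mix) - 1) > 1e-8 || any(family_mix < 0))
      .cfg_fail("family_mix", "probabilities must be >= 0 and sum to 1")
    if (!all(names(family_mix) %in% .families))
      .cfg_fail("family_mix", "unknown family name")
    for (p in c("p_isolated_missing", "p_increasing", "p_duplicate",
                "p_after_midnight")) {
      v <- get(p)
      if (v < 0 || v > 1) .cfg_fail(p, "must be a probability in [0, 1]")
    }
    if (length(noise_sd_range) != 2L || any(noise_sd_range < 0) ||
        noise_sd_range[1] > noise_sd_range[2])
      .cfg_fail("noise_sd_range", "must be an increasing non-negative range")
    if (!is.null(gap_spec)) {
      if (abs(sum(gap_spec$n_prob) - 1) > 1e-8 || any(gap_spec$n_prob < 0))
        .cfg_fail("gap_spec", "n_prob must be a probability vector")
      if (gap_spec$late_frac < 0 || gap_spec$late_frac > 1)
        .cfg_fail("gap_spec", "late_frac must be in [0, 1]")
      if (gap_spec$min_len < 2L)
        .cfg_fail("gap_spec", "min_len must be >= 2 (gaps are non-singleton)")
    }
  })
  config
}

#' Default per-family parameter priors
#'
#' Ranges keep the latent curve representable on the 0--4 response scale:
#' levels between roughly 0 and 4, decay rates between 0.03 and 0.4 per day,
#' logistic midpoints inside the observation window.
#'
#' @return Named list of per-family parameter ranges.
#' @export
default_param_priors <- function() {
  list(
    constant   = list(b0 = c(1.5, 3.8)),
    linear     = list(b0 = c(2.5, 4), b1 = c(-0.03, -0.005)),
    quadratic  = list(b0 = c(2.5, 4), b1 = c(-0.08, -0.02),
                      b2 = c(2e-4, 8e-4)),
    cubic      = list(b0 = c(2.5, 4), b1 = c(-0.10, -0.05),
                      b2 = c(8e-4, 1.8e-3), b3 = c(-1e-5, -4e-6)),
    asymptotic = list(A = c(0, 1.8), R0 = c(2.5, 4),
                      lam = c(log(0.03), log(0.4))),
    logistic   = list(L = c(0, 1.8), U = c(2.5, 4), m = c(5, 50), s = c(1, 8))
  )
}

#' Draw trajectory parameters from a family's prior
#'
#' Parameters are drawn uniformly within the prior ranges. For the asymptotic
#' and logistic families the level priors are constructed so that the initial
#' value exceeds the lower asymptote (a decaying habit); with
#' `increasing = TRUE` the two levels are swapped, producing a non-decaying
#' (retained/regained strength) trajectory.
#'
#' @param family Family name.
#' @param priors Prior list as in [default_param_priors].
#' @param increasing Logical; swap the levels of asymptotic/logistic draws.
#' @return Named numeric parameter vector (order as in
#'   [evaluate_trajectory]).
#' @export
sample_family_params <- function(family, priors = default_param_priors(),
                                 increasing = FALSE) {
  .check_family(family)
  pr <- priors[[family]]
  if (is.null(pr)) stop("no prior for family ", family, call. = FALSE)
  theta <- vapply(pr, function(rng) stats::runif(1, rng[1], rng[2]), numeric(1))
  if (increasing && family == "asymptotic") theta[c("A", "R0")] <- theta[c("R0", "A")]
  if (increasing && family == "logistic") theta[c("L", "U")] <- theta[c("U", "L")]
  theta[.par_names[[family]]]
}

# closed-form asymptote95 stabilization day of a noiseless decaying truth
.true_stab_day <- function(family, theta) {
  if (family == "asymptotic" && theta[["R0"]] > theta[["A"]]) {
    return(ceiling(log(20) * exp(-theta[["lam"]])))
  }
  if (family == "logistic" && theta[["U"]] > theta[["L"]]) {
    m <- theta[["m"]]; s <- theta[["s"]]
    return(ceiling(m + s * log(20 * (1 + exp(-m / s)) - 1)))
  }
  NA_real_
}

# split an SRBAI score (multiple of 0.25) into four integer 0-4 items
.score_to_items <- function(score) {
  s <- as.integer(round(score * 4))
  base <- s %/% 4L
  extra <- s %% 4L
  items <- rep(base, 4L)
  if (extra > 0L) items[seq_len(extra)] <- items[seq_len(extra)] + 1L
  items
}

#' Simulate a synthetic diary cohort
#'
#' Draws, per participant: a trajectory family from `family_mix`, parameters
#' from the family prior (group differences applied to the level parameters
#' only), a residual SD; evaluates the latent curve on the daily grid, adds
#' Gaussian noise, rounds to the nearest 0.25 and clamps to [0, 4] (an
#' average of four integer items); then removes days via isolated missingness
#' and long gap blocks, injects same-day duplicates and after-midnight
#' timestamps, and decomposes each score into four integer items.
#'
#' @param config A [cohort_config].
#' @return List with `responses` (long raw table: `participant_id`, `group`,
#'   `timestamp` ISO-8601, `item_1`..`item_4`) and `truth` (per participant:
#'   family, parameters `par1`..`par4`, `noise_sd`, `increasing`, and
#'   `stab_day`, the closed-form asymptote95 stabilization day where
#'   defined).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  set.seed(config$seed)
  n_days <- config$n_days
  tgrid <- 0:(n_days - 1L)
  half <- n_days %/% 2L

  resp_rows <- list(); truth_rows <- list(); ridx <- 0L
  pid <- 0L
  for (g in names(config$group_sizes)) {
    shift <- config$group_intercept_shift[g]
    if (is.na(shift) || is.null(shift)) shift <- 0
    for (j in seq_len(config$group_sizes[[g]])) {
      pid <- pid + 1L
      id <- sprintf("P%03d", pid)
      family <- sample(names(config$family_mix), 1L, prob = config$family_mix)
      increasing <- family %in% c("asymptotic", "logistic") &&
        stats::runif(1) < config$p_increasing
      theta <- sample_family_params(family, config$param_priors, increasing)
      # group differences enter through the level parameters only
      lev <- switch(family, asymptotic = c("A", "R0"), logistic = c("L", "U"), "b0")
      theta[lev] <- pmin(pmax(theta[lev] + shift, 0), 4)
      noise_sd <- stats::runif(1, config$noise_sd_range[1], config$noise_sd_range[2])

      latent <- evaluate_trajectory(family, theta, tgrid)
      y <- latent + stats::rnorm(n_days, 0, noise_sd)
      y <- pmin(pmax(round(y * 4) / 4, 0), 4)

      miss <- stats::runif(n_days) < config$p_isolated_missing
      gs <- config$gap_spec
      if (!is.null(gs)) {
        n_gaps <- sample(seq_along(gs$n_prob) - 1L, 1L, prob = gs$n_prob)
        for (k in seq_len(n_gaps)) {
          len <- gs$min_len + stats::rgeom(1L, 1 / (gs$geom_mean + 1))
          late <- stats::runif(1) < gs$late_frac
          lo <- if (late) half else 0L
          hi <- if (late) n_days - len else max(half - len, 0L)
          if (hi < lo) hi <- lo
          start <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          miss[seq.int(start + 1L, min(start + len, n_days))] <- TRUE
        }
      }

      obs_t <- tgrid[!miss]
      if (length(obs_t)) {
        dup <- stats::runif(length(obs_t)) < config$p_duplicate
        tt <- c(obs_t, obs_t[dup])
        yv <- y[obs_t + 1L]
        if (any(dup)) {
          extra <- latent[obs_t[dup] + 1L] + stats::rnorm(sum(dup), 0, noise_sd)
          yv <- c(yv, pmin(pmax(round(extra * 4) / 4, 0), 4))
        }
        after_mid <- stats::runif(length(tt)) < config$p_after_midnight
        date <- config$start_date + config$day_offset + tt + after_mid
        secs <- ifelse(after_mid,
                       stats::runif(length(tt), 0, 12 * 3600 - 1),
                       stats::runif(length(tt), 18 * 3600, 24 * 3600 - 1))
        ts <- sprintf("%sT%02d:%02d:%02d", format(date),
                      floor(secs / 3600) %% 24, floor(secs / 60) %% 60,
                      floor(secs) %% 60)
        s4 <- as.integer(round(yv * 4))
        base <- s4 %/% 4L; extra_n <- s4 %% 4L
        items <- outer(rep(1, length(s4)), 1:4)
        items <- base + (items <= extra_n)
        ridx <- ridx + 1L
        resp_rows[[ridx]] <- data.frame(
          participant_id = id, group = g, timestamp = ts,
          item_1 = items[, 1], item_2 = items[, 2], item_3 = items[, 3],
          item_4 = items[, 4], stringsAsFactors = FALSE)
      }

      th <- rep(NA_real_, 4L); th[seq_along(theta)] <- theta
      truth_rows[[pid]] <- data.frame(
        participant_id = id, group = g, family = family,
        par1 = th[1], par2 = th[2], par3 = th[3], par4 = th[4],
        noise_sd = noise_sd, increasing = increasing,
        stab_day = .true_stab_day(family, theta), stringsAsFactors = FALSE)
    }
  }
  responses <- do.call(rbind, resp_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(responses) <- rownames(truth) <- NULL
  list(responses = responses, truth = truth)
}
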