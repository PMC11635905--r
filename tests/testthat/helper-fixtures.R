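# shared fixtures, built in code at test time

all_families <- c("constant", "linear", "quadratic", "cubic",
                  "asymptotic", "logistic")

# interior-of-bounds truths used across recovery tests
family_truths <- list(
  constant   = c(b0 = 2.5),
  linear     = c(b0 = 3.2, b1 = -0.02),
  quadratic  = c(b0 = 3.5, b1 = -0.05, b2 = 4e-4),
  cubic      = c(b0 = 3.5, b1 = -0.08, b2 = 1.4e-3, b3 = -8e-6),
  asymptotic = c(A = 0.5, R0 = 3.5, lam = log(0.08)),
  logistic   = c(L = 1, U = 3, m = 20, s = 5)
)

# noise-free series on the full grid from a family truth
noiseless_series <- function(family, theta = family_truths[[family]],
                             n_days = 84L, id = "S1", group = "SB") {
  y <- evaluate_trajectory(family, theta, 0:(n_days - 1L))
  diary_series(id, group, pmin(pmax(y, 0), 4), n_days = n_days)
}

# fit all six families to a plain (t, y) pair
fit_six <- function(t, y) {
  fits <- lapply(all_families, function(f) fit_trajectory(t, y, f))
  names(fits) <- all_families
  fits
}

# linear decay, a long missing gap, and an outlier after the gap whose
# removal flips BIC selection back to linear
outlier_gap_series <- function(gap_len = 21L, outlier = 1.2) {
  y <- rep(NA_real_, 84L)
  obs1 <- 0:40
  obs2 <- (41L + gap_len):83L
  y[obs1 + 1L] <- 3 - 0.02 * obs1
  y[obs2 + 1L] <- 3 - 0.02 * obs2
  y[84L] <- y[84L] + outlier
  diary_series("OUT1", "SB", y)
}

# minimal raw-response table for preprocessing tests
raw_response <- function(participant_id, timestamp, items, group = "SB") {
  data.frame(participant_id = participant_id, group = group,
             timestamp = timestamp,
             item_1 = items[1], item_2 = items[2], item_3 = items[3],
             item_4 = items[4], stringsAsFactors = FALSE)
}

# a quiet cohort config for deterministic small simulations
quiet_config <- function(...) {
  defaults <- list(group_sizes = c(SB = 4L, US = 4L, AC = 4L, TS = 4L),
                   noise_sd_range = c(0.2, 0.2), p_increasing = 0,
                   p_duplicate = 0, p_after_midnight = 0,
                   p_isolated_missing = 0, gap_spec = NULL, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}
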