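test_that("after-midnight responses are recoded to the previous day", {
  r <- rbind(raw_response("P1", "2022-10-08T03:00:00", c(2, 2, 2, 2)),
             raw_response("P1", "2022-10-08T12:00:00", c(2, 2, 2, 2)),
             raw_response("P1", "2022-10-08T23:59:00", c(2, 2, 2, 2)))
  out <- recode_after_midnight(r)
  expect_equal(out$date, as.Date(c("2022-10-07", "2022-10-08", "2022-10-08")))
  expect_error(recode_after_midnight(raw_response("P1", "not-a-time", c(1, 1, 1, 1))),
               "unparseable")
})

test_that("SRBAI scoring averages four integer items and rejects partial rows", {
  expect_equal(score_srbai(matrix(c(0, 1, 2, 3), 1)), 1.5)
  expect_equal(score_srbai(matrix(c(4, 4, 4, 4), 1)), 4)
  expect_equal(score_srbai(matrix(c(2, 3, 2, 3), 1)), 2.5)
  expect_warning(s <- score_srbai(matrix(c(2, NA, 2, 2), 1)), "rejected")
  expect_true(is.na(s))
})

test_that("same-day duplicates are removed by averaging", {
  d <- data.frame(participant_id = c("P1", "P1", "P2", "P3", "P3", "P3"),
                  t = c(3L, 3L, 3L, 5L, 5L, 5L),
                  srbai = c(2, 3, 1.5, 1, 1, 4))
  out <- collapse_duplicates(d)
  expect_equal(out$srbai[out$participant_id == "P1"], 2.5)
  expect_equal(out$srbai[out$participant_id == "P2"], 1.5)  # identity
  expect_equal(out$srbai[out$participant_id == "P3"], 2)    # mean of 1,1,4
})

test_that("only interior singleton gaps are imputed, by neighbour mean", {
  y <- rep(2, 12)
  y[c(1, 6, 9, 10)] <- NA          # edge, singleton, run of two
  y[5] <- 3; y[7] <- 2             # neighbours of the singleton at t=5
  s <- impute_isolated(diary_series("P1", "SB", y))
  expect_equal(s$y[6], 2.5)                  # neighbour-mean oracle
  expect_true(s$imputed[6])
  expect_true(all(is.na(s$y[c(1, 9, 10)])))  # edge and run stay missing
  expect_equal(sum(s$imputed), 1L)
})

test_that("imputation never alters observed values and is idempotent", {
  set.seed(4)
  y <- round(runif(84, 0, 4) * 4) / 4
  y[sample(84, 25)] <- NA
  s0 <- diary_series("P1", "SB", y)
  s1 <- impute_isolated(s0)
  obs <- !is.na(y)
  expect_equal(s1$y[obs], y[obs])
  expect_lte(sum(s1$imputed), sum(is.na(y)))
  # no interior singleton gap remains
  miss <- is.na(s1$y)
  interior_singleton <- which(miss[2:83] & !miss[1:82] & !miss[3:84]) + 1L
  expect_length(interior_singleton, 0L)
  expect_equal(impute_isolated(s1), s1)
})

test_that("retention needs six observed values and midpoint engagement", {
  y5 <- rep(NA_real_, 84); y5[1:5] <- 2
  yfull <- rep(2, 84)
  y20 <- rep(NA_real_, 84); y20[11:30] <- 2  # 20 obs, last at t=29
  yedge <- rep(NA_real_, 84); yedge[c(1:5, 42)] <- 2  # 6 obs, last at t=41
  sl <- list(diary_series("A", "SB", y5), diary_series("B", "SB", yfull),
             diary_series("C", "SB", y20), diary_series("D", "SB", yedge))
  res <- retention_filter(sl)
  ids <- vapply(res$retained, `[[`, character(1), "id")
  expect_setequal(ids, c("B", "D"))
  expect_equal(res$exclusions$reason[res$exclusions$participant_id == "A"],
               "min_measurements")
  expect_equal(res$exclusions$reason[res$exclusions$participant_id == "C"],
               "midpoint_engagement")
  # monotone: adding observations never causes exclusion
  y5more <- y5; y5more[40:45] <- 2
  res2 <- retention_filter(list(diary_series("A", "SB", y5more)))
  expect_length(res2$retained, 1L)
})

test_that("imputed values do not count towards retention", {
  y <- rep(NA_real_, 84)
  y[c(1, 3, 5, 7, 9, 43)] <- 2    # 6 observed (even t missing), last at t=42
  s <- impute_isolated(diary_series("P", "SB", y))
  expect_gt(sum(!is.na(s$y)), 6L)
  res <- retention_filter(list(s))
  expect_length(res$retained, 1L)
  # drop one observation: only 5 observed, imputation cannot rescue retention
  y2 <- y; y2[1] <- NA
  s2 <- impute_isolated(diary_series("P", "SB", y2))
  res2 <- retention_filter(list(s2))
  expect_equal(res2$exclusions$reason, "min_measurements")
})

test_that("missingness profile counts missing, imputed, and longest gap", {
  y <- rep(2, 84)
  y[c(10, 20, 30)] <- NA           # isolated singletons (imputable)
  y[50:54] <- NA                   # one 5-day gap
  s <- impute_isolated(diary_series("P1", "SB", y))
  prof <- missingness_profile(list(s))
  expect_equal(prof$per_participant$n_missing, 8L)
  expect_equal(prof$per_participant$n_imputed, 3L)
  expect_equal(prof$per_participant$longest_gap, 5L)
  expect_equal(prof$overall$denominator, 84L)

  full <- missingness_profile(lapply(1:10, function(i)
    diary_series(paste0("P", i), "SB", rep(2, 84))))
  expect_equal(full$overall$denominator, 840L)
  expect_equal(full$overall$n_missing, 0L)

  empty <- missingness_profile(list())
  expect_equal(nrow(empty$per_participant), 0L)
  expect_equal(empty$overall$n_participants, 0L)
})

test_that("preprocessing is idempotent end to end", {
  cfg <- cohort_config(group_sizes = c(SB = 6L), p_duplicate = 0, seed = 3L)
  sim <- simulate_cohort(cfg)
  p1 <- preprocess_diary(sim$responses, start_date = cfg$start_date)
  # re-export the cleaned occasions as raw rows and push them through again
  occ <- p1$occasions[!p1$occasions$imputed, ]
  items <- t(vapply(occ$y, function(v) {
    s <- as.integer(round(v * 4)); b <- s %/% 4L; e <- s %% 4L
    b + (1:4 <= e)
  }, numeric(4)))
  raw2 <- data.frame(participant_id = occ$participant_id, group = occ$group,
                     timestamp = sprintf("%sT20:00:00",
                                         cfg$start_date + 7L + occ$t),
                     item_1 = items[, 1], item_2 = items[, 2],
                     item_3 = items[, 3], item_4 = items[, 4])
  p2 <- preprocess_diary(raw2, start_date = cfg$start_date)
  expect_equal(p2$occasions, p1$occasions)
})
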