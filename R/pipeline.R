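#' Run the full habit-decay analysis pipeline
#'
#' Executes, in order: (optional) synthetic-cohort simulation, diary
#' preprocessing, person-specific fitting of the six trajectory families,
#' BIC selection plus the 4-step validity gate, stabilization estimation,
#' and (optional) group-level mixed models. All thresholds and the seed are
#' echoed into the returned `meta` block so a run is fully reproducible.
#'
#' @param cohort Either a [cohort_config] (a cohort is simulated) or a list
#'   with `responses` (raw long table) as returned by [simulate_cohort].
#' @param stages Character vector of stages to run after preprocessing;
#'   subset of `c("fit", "stabilize", "multilevel")`.
#' @param loo Run the leave-one-out stability check (step 2); expensive.
#' @param rmse_cutoff,gap_cutoff Validity-gate thresholds.
#' @param window_threshold Threshold of the 7-day-window stabilization
#'   criterion.
#' @param min_measurements,midpoint_occasion Retention-filter settings.
#' @return List with `occasions`, `exclusions`, `missingness`, `fits`
#'   (per-family table), `verdicts`, `estimates`, `stabilization_summary`,
#'   `multilevel` (ICC, cubic ladder, asymptotic two-stage), `summary`
#'   (machine-readable block, see [make_summary_tables]), `truth` (when
#'   simulated) and `meta`.
#' @export
run_pipeline <- function(cohort = cohort_config(),
                         stages = c("fit", "stabilize", "multilevel"),
                         loo = TRUE, rmse_cutoff = 0.33, gap_cutoff = 21L,
                         window_threshold = 0.1, min_measurements = 6L,
                         midpoint_occasion = 41L) {
  meta <- list(rmse_cutoff = rmse_cutoff, gap_cutoff = gap_cutoff,
               window_threshold = window_threshold,
               min_measurements = min_measurements,
               midpoint_occasion = midpoint_occasion, loo = loo,
               stages = stages)
  truth <- NULL
  if (inherits(cohort, "cohort_config")) {
    meta$seed <- cohort$seed
    sim <- simulate_cohort(cohort)
    responses <- sim$responses
    truth <- sim$truth
    start_date <- cohort$start_date
    n_days <- cohort$n_days
    day_offset <- cohort$day_offset
  } else {
    responses <- cohort$responses
    start_date <- cohort$start_date %||% as.Date("2022-09-19")
    n_days <- cohort$n_days %||% 84L
    day_offset <- cohort$day_offset %||% 7L
  }

  pre <- preprocess_diary(responses, start_date = start_date, n_days = n_days,
                          day_offset = day_offset,
                          min_measurements = min_measurements,
                          midpoint_occasion = midpoint_occasion)
  out <- list(occasions = pre$occasions, exclusions = pre$exclusions,
              missingness = pre$missingness, truth = truth, meta = meta)

  if ("fit" %in% stages) {
    fits <- lapply(pre$series, fit_all_families)
    out$fits <- fit_table(fits)
    out$verdicts <- classify_cohort(pre$series, fits, loo = loo,
                                    rmse_cutoff = rmse_cutoff,
                                    gap_cutoff = gap_cutoff)
    out$fitted_curves <- .fitted_curve_table(pre$series, fits, out$verdicts)
    if ("stabilize" %in% stages) {
      est <- list()
      for (i in seq_along(pre$series)) {
        v <- out$verdicts[i, ]
        if (is.na(v$best_family)) next
        e <- stabilization_estimates(fits[[i]][[v$best_family]],
                                     threshold = window_threshold)
        if (nrow(e)) {
          e$participant_id <- v$participant_id
          e$family <- v$best_family
          est[[length(est) + 1L]] <- e
        }
      }
      out$estimates <- if (length(est)) do.call(rbind, est) else
        data.frame(method = character(0), day = numeric(0),
                   within_window = logical(0),
                   crossed_before_stabilization = logical(0),
                   participant_id = character(0), family = character(0))
      out$stabilization_summary <-
        summarize_stabilization(out$estimates, out$verdicts)
    }
  }

  if ("multilevel" %in% stages) {
    ml_data <- pre$occasions
    names(ml_data)[names(ml_data) == "y"] <- "y"
    icc <- fit_constant_icc(ml_data)
    ladder <- cubic_mlm_ladder(ml_data)
    groups <- unique(ml_data$group)
    contrasts <- lapply(groups, function(g) {
      fit_cubic_mlm(ml_data, random = "intercept", focal_group = g)
    })
    names(contrasts) <- groups
    asym <- fit_asymptotic_mlm(pre$series)
    out$multilevel <- list(icc = icc, cubic_ladder = ladder,
                           group_contrasts = contrasts, asymptotic = asym)
  }

  out$summary <- make_summary_tables(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# data behind per-participant panels: observed points + fitted curve of the
# best family + stabilization markers are recoverable from this table
.fitted_curve_table <- function(series_list, fits, verdicts) {
  rows <- lapply(seq_along(series_list), function(i) {
    fam <- verdicts$best_family[i]
    if (is.na(fam)) return(NULL)
    f <- fits[[i]][[fam]]
    tt <- 0:max(f$t)
    data.frame(participant_id = verdicts$participant_id[i], family = fam,
               t = tt, fitted = evaluate_trajectory(fam, f$theta, tt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' Machine-readable summary of a pipeline run
#'
#' @param results Pipeline output list (any subset of stages).
#' @return List with `best_family_freq` (overall and by group), `valid_counts`
#'   per family, `stabilization` (Table-2-shaped summary), `missingness`
#'   overview, and `multilevel` highlights (ICC, ladder) when present.
#' @export
make_summary_tables <- function(results) {
  out <- list()
  out$missingness <- results$missingness$overall
  if (!is.null(results$verdicts)) {
    v <- results$verdicts
    freq <- as.data.frame(table(family = v$best_family), stringsAsFactors = FALSE)
    names(freq)[2L] <- "n"
    freq$pct <- 100 * freq$n / nrow(v)
    out$best_family_freq <- freq
    out$best_family_by_group <-
      as.data.frame(table(group = v$group, family = v$best_family),
                    stringsAsFactors = FALSE)
    valid <- stats::aggregate(
      cbind(n_valid = v$overall_valid | v$stable_habit_valid) ~ best_family,
      data = v, FUN = sum)
    names(valid)[1L] <- "family"
    out$valid_counts <- valid
    out$n_overall_valid <- sum(v$overall_valid)
    out$n_stable_habit_valid <- sum(v$stable_habit_valid)
  }
  if (!is.null(results$stabilization_summary)) {
    out$stabilization <- results$stabilization_summary
  }
  if (!is.null(results$multilevel)) {
    out$multilevel <- list(
      icc = results$multilevel$icc$icc,
      cubic_ladder = results$multilevel$cubic_ladder$ladder,
      group_intercepts = .group_intercept_table(results$multilevel$group_contrasts)
    )
  }
  out
}

.group_intercept_table <- function(contrasts) {
  if (is.null(contrasts)) return(NULL)
  rows <- lapply(names(contrasts), function(g) {
    fx <- contrasts[[g]]$fixed
    b0 <- fx[fx$term == "(Intercept)", ]
    gg <- fx[fx$term == "g", ]
    data.frame(group = g,
               others_intercept = b0$estimate,
               others_ci_lo = b0$ci_lo, others_ci_hi = b0$ci_hi,
               focal_intercept = b0$estimate + gg$estimate,
               focal_shift = gg$estimate, shift_se = gg$se,
               shift_ci_lo = gg$ci_lo, shift_ci_hi = gg$ci_hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write pipeline outputs to disk
#'
#' Emits per-stage CSV tables plus a JSON summary into `dir`.
#'
#' @param results Output of [run_pipeline].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(results$occasions, "occasions")
  wr(results$exclusions, "exclusions")
  wr(results$missingness$per_participant, "missingness_per_participant")
  wr(results$fits, "fits")
  wr(results$verdicts, "verdicts")
  wr(results$estimates, "stabilization_estimates")
  wr(results$stabilization_summary, "stabilization_summary")
  wr(results$fitted_curves, "fitted_curves")
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(results$summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  paths <- c(paths, p)
  p <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(results$meta, p, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, p))
}
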