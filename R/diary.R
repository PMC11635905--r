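#' A cleaned per-participant daily habit-strength series
#'
#' Holds one participant's SRBAI series on the full occasion grid
#' t = 0..n_days-1 (one unit = one day of the decay phase), with `NA` for
#' missing days and a per-occasion imputation flag.
#'
#' @param id Participant identifier.
#' @param group Behavioural group label.
#' @param y Numeric vector of length `n_days`, values in [0, 4] or `NA`.
#' @param imputed Logical vector of length `n_days`; `TRUE` only where a
#'   previously missing value was filled in.
#' @param n_days Number of occasions in the decay phase (default 84).
#' @return An object of class `diary_series` with fields `id`, `group`, `t`
#'   (0-based occasions), `y`, `imputed`, `n_days`.
#' @export
diary_series <- function(id, group, y, imputed = NULL, n_days = length(y)) {
  stopifnot(length(y) == n_days, n_days >= 1)
  if (is.null(imputed)) imputed <- rep(FALSE, n_days)
  stopifnot(length(imputed) == n_days)
  bad <- !is.na(y) & (y < 0 | y > 4)
  if (any(bad)) stop("SRBAI values must lie in [0, 4]", call. = FALSE)
  if (any(imputed & is.na(y))) stop("imputed occasions must carry a value", call. = FALSE)
  structure(
    list(id = as.character(id), group = as.character(group),
         t = seq_len(n_days) - 1L, y = as.numeric(y),
         imputed = as.logical(imputed), n_days = as.integer(n_days)),
    class = "diary_series"
  )
}

#' @export
print.diary_series <- function(x, ...) {
  cat(sprintf("<diary_series> id = %s, group = %s, %d/%d observed (%d imputed)\n",
              x$id, x$group, sum(!is.na(x$y)), x$n_days, sum(x$imputed)))
  invisible(x)
}

# run lengths of consecutive missing occasions
.missing_runs <- function(y) {
  r <- rle(is.na(y))
  r$lengths[r$values]
}

#' Longest run of consecutive missing occasions
#' @param series A [diary_series].
#' @return Integer; 0 when nothing is missing.
#' @export
longest_gap <- function(series) {
  runs <- .missing_runs(series$y)
  if (length(runs) == 0L) 0L else max(runs)
}

#' Score the SRBAI from its four items
#'
#' The daily habit-strength score is the mean of four automaticity items,
#' each an integer on 0--4. Rows with any missing or non-integer item are
#' rejected (partial responses are not scored).
#'
#' @param items Numeric matrix or data frame with four columns (one row per
#'   response).
#' @return Numeric vector of scores in [0, 4]; `NA` with a warning for
#'   rejected rows.
#' @export
score_srbai <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) != 4L) stop("SRBAI needs exactly four items", call. = FALSE)
  ok <- rowSums(is.na(items)) == 0L &
    rowSums(items < 0 | items > 4 | items != round(items), na.rm = TRUE) == 0L
  if (any(!ok)) {
    warning(sprintf("%d partial/invalid SRBAI response(s) rejected", sum(!ok)),
            call. = FALSE)
  }
  out <- rowMeans(items)
  out[!ok] <- NA_real_
  out
}

#' Reassign after-midnight diary responses to the previous day
#'
#' End-of-day questionnaires answered after midnight refer to the day that
#' just ended: any response with clock time in [00:00, 12:00) is moved back
#' one calendar day. Noon (12:00 exactly) and later keep their own day.
#'
#' @param responses Data frame with a `timestamp` column (POSIXct or an
#'   ISO-8601 string, interpreted in UTC).
#' @return The same data frame with a `date` column (class `Date`) giving the
#'   diary day each response refers to.
#' @export
recode_after_midnight <- function(responses) {
  ts <- responses$timestamp
  if (!inherits(ts, "POSIXct")) {
    chr <- as.character(ts)
    ts <- as.POSIXct(strptime(chr, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), tz = "UTC")
    alt <- as.POSIXct(strptime(chr, "%Y-%m-%d %H:%M:%S", tz = "UTC"), tz = "UTC")
    ts[is.na(ts)] <- alt[is.na(ts)]
  }
  bad <- is.na(ts)
  if (any(bad)) {
    stop("unparseable timestamp at row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  hour <- as.integer(format(ts, "%H", tz = "UTC"))
  date <- as.Date(ts, tz = "UTC")
  date[hour < 12L] <- date[hour < 12L] - 1L
  responses$date <- date
  responses
}

#' Average same-day duplicate responses
#'
#' When a participant answered more than once for the same diary day, the
#' retained score is the arithmetic mean of the per-response SRBAI scores.
#'
#' @param scored Data frame with columns `participant_id`, `date` (or an
#'   occasion column `t`) and `srbai`. Day recoding must already be applied.
#' @return One row per participant-day with the averaged `srbai`.
#' @export
collapse_duplicates <- function(scored) {
  key <- if ("t" %in% names(scored)) "t" else "date"
  agg <- stats::aggregate(
    scored["srbai"],
    by = list(participant_id = scored$participant_id, key = scored[[key]]),
    FUN = mean
  )
  names(agg)[2L] <- key
  extras <- setdiff(names(scored), c("participant_id", key, "srbai", "timestamp",
                                     paste0("item_", 1:4)))
  for (col in extras) {
    first <- scored[!duplicated(paste(scored$participant_id, scored[[key]])), ]
    agg[[col]] <- first[[col]][match(paste(agg$participant_id, agg[[key]]),
                                     paste(first$participant_id, first[[key]]))]
  }
  agg[order(agg$participant_id, agg[[key]]), , drop = FALSE]
}

#' Impute isolated missing days by the mean of their neighbours
#'
#' Only interior singleton gaps -- a missing occasion whose immediate
#' neighbours are both observed -- are filled, with the mean of the two
#' neighbours (for a single interior point this equals linear interpolation).
#' Runs of two or more missing days and edge-missing occasions are retained
#' as missing gaps.
#'
#' @param series A [diary_series].
#' @return The series with singleton gaps filled and `imputed` flags set.
#' @export
impute_isolated <- function(series) {
  stopifnot(inherits(series, "diary_series"))
  y <- series$y
  n <- series$n_days
  if (n >= 3L) {
    idx <- which(is.na(y))
    idx <- idx[idx > 1L & idx < n]
    idx <- idx[!is.na(y[idx - 1L]) & !is.na(y[idx + 1L])]
    if (length(idx)) {
      series$y[idx] <- (y[idx - 1L] + y[idx + 1L]) / 2
      series$imputed[idx] <- TRUE
    }
  }
  series
}

#' Retention filter for analysable participants
#'
#' A participant is retained iff they provided at least `min_measurements`
#' observed (pre-imputation) SRBAI values and engaged at least until the
#' midpoint of the decay phase: their last observed occasion is at or after
#' `midpoint_occasion` (default 41, i.e. study Day 48 under the default
#' indexing).
#'
#' @param series_list List of [diary_series] (imputation flags may be set;
#'   counts use non-imputed occasions).
#' @param min_measurements Minimum number of observed values (default 6).
#' @param midpoint_occasion Occasion the last observation must reach
#'   (default 41).
#' @return List with `retained` (list of series) and `exclusions` (data frame
#'   `participant_id`, `reason` in `min_measurements` / `midpoint_engagement`).
#' @export
retention_filter <- function(series_list, min_measurements = 6L,
                             midpoint_occasion = 41L) {
  keep <- logical(length(series_list))
  reasons <- character(0); ids <- character(0)
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    observed <- !is.na(s$y) & !s$imputed
    n_obs <- sum(observed)
    last_t <- if (n_obs) max(s$t[observed]) else -1L
    if (n_obs < min_measurements) {
      ids <- c(ids, s$id); reasons <- c(reasons, "min_measurements")
    } else if (last_t < midpoint_occasion) {
      ids <- c(ids, s$id); reasons <- c(reasons, "midpoint_engagement")
    } else {
      keep[i] <- TRUE
    }
  }
  list(
    retained = series_list[keep],
    exclusions = data.frame(participant_id = ids, reason = reasons,
                            stringsAsFactors = FALSE)
  )
}

#' Missing-data profile of a cohort
#'
#' @param series_list List of [diary_series] (post-imputation).
#' @return List with `per_participant` (missing before imputation, imputed
#'   count, longest remaining gap) and `overall` (totals over the
#'   n_participants x n_days denominator).
#' @export
missingness_profile <- function(series_list) {
  if (length(series_list) == 0L) {
    return(list(
      per_participant = data.frame(participant_id = character(0),
                                   n_missing = integer(0), n_imputed = integer(0),
                                   longest_gap = integer(0)),
      overall = data.frame(n_participants = 0L, n_days = NA_integer_,
                           denominator = 0L, n_missing = 0L, n_imputed = 0L,
                           missing_fraction = NA_real_)
    ))
  }
  pp <- do.call(rbind, lapply(series_list, function(s) {
    n_imp <- sum(s$imputed)
    n_miss <- sum(is.na(s$y)) + n_imp  # before imputation
    data.frame(participant_id = s$id, n_missing = n_miss, n_imputed = n_imp,
               longest_gap = longest_gap(s), stringsAsFactors = FALSE)
  }))
  rownames(pp) <- NULL
  n_days <- series_list[[1L]]$n_days
  denom <- length(series_list) * n_days
  list(
    per_participant = pp,
    overall = data.frame(
      n_participants = length(series_list), n_days = n_days,
      denominator = denom, n_missing = sum(pp$n_missing),
      n_imputed = sum(pp$n_imputed),
      missing_fraction = sum(pp$n_missing) / denom
    )
  )
}

#' Preprocess raw e-diary responses into cleaned series
#'
#' Runs the full preprocessing chain: after-midnight recoding, SRBAI scoring
#' (rejecting partial responses), duplicate averaging, alignment onto the
#' occasion grid, singleton imputation, and retention filtering.
#'
#' @param responses Raw long-format data frame with columns `participant_id`,
#'   `group`, `timestamp`, `item_1`..`item_4`.
#' @param start_date `Date` (or string) of study Day 0; occasion t corresponds
#'   to calendar day `start_date + day_offset + t`.
#' @param n_days Length of the decay phase in days (default 84).
#' @param day_offset Days between `start_date` and occasion 0 (default 7: the
#'   first week is cue observation, the decay phase starts the day after the
#'   baseline measurement).
#' @param impute Logical; fill interior singleton gaps (default TRUE).
#' @param min_measurements,midpoint_occasion Passed to [retention_filter].
#' @return List with `series` (retained [diary_series] list), `exclusions`,
#'   `missingness` (see [missingness_profile]) and `occasions` (tidy long
#'   data frame of the retained series with imputed flags).
#' @export
preprocess_diary <- function(responses, start_date, n_days = 84L,
                             day_offset = 7L, impute = TRUE,
                             min_measurements = 6L, midpoint_occasion = 41L) {
  stopifnot(all(c("participant_id", "group", "timestamp",
                  paste0("item_", 1:4)) %in% names(responses)))
  start_date <- as.Date(start_date)
  responses <- recode_after_midnight(responses)
  responses$srbai <- score_srbai(responses[paste0("item_", 1:4)])
  responses <- responses[!is.na(responses$srbai), , drop = FALSE]
  responses$t <- as.integer(responses$date - start_date) - as.integer(day_offset)
  responses <- responses[responses$t >= 0L & responses$t < n_days, , drop = FALSE]
  daily <- collapse_duplicates(responses[c("participant_id", "group", "t", "srbai")])

  ids <- unique(daily$participant_id)
  series_list <- lapply(ids, function(id) {
    rows <- daily[daily$participant_id == id, ]
    y <- rep(NA_real_, n_days)
    y[rows$t + 1L] <- rows$srbai
    diary_series(id, rows$group[1L], y, n_days = n_days)
  })
  names(series_list) <- ids
  if (impute) series_list <- lapply(series_list, impute_isolated)

  ret <- retention_filter(series_list, min_measurements, midpoint_occasion)
  occasions <- series_to_long(ret$retained)
  list(series = ret$retained, exclusions = ret$exclusions,
       missingness = missingness_profile(ret$retained), occasions = occasions)
}

#' Flatten diary series into a tidy long table
#'
#' @param series_list List of [diary_series].
#' @return Data frame `participant_id`, `group`, `t`, `y`, `imputed`, one row
#'   per occasion with a value.
#' @export
series_to_long <- function(series_list) {
  if (length(series_list) == 0L) {
    return(data.frame(participant_id = character(0), group = character(0),
                      t = integer(0), y = numeric(0), imputed = logical(0)))
  }
  out <- do.call(rbind, lapply(series_list, function(s) {
    obs <- !is.na(s$y)
    data.frame(participant_id = s$id, group = s$group, t = s$t[obs],
               y = s$y[obs], imputed = s$imputed[obs], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
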