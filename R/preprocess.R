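#' Participant exclusion filters
#'
#' Applies the published exclusion rules, in their published order, and
#' returns the survivors together with an accounting report.  Rules use the
#' printed absolute cut-offs by default (reproducible on arbitrary
#' cohorts); a percentile mode re-derives the 10% bounds from the cohort at
#' hand.  Boundary values survive (the rules read "less than" / "below" /
#' "above").
#'
#' `filter_study1()` expects columns `participant_id`, `series_length` and
#' `completion_minutes` and drops (1) series shorter than 103 elements,
#' then (2) completion times below 7.5 or above 15 minutes.
#'
#' `filter_study2()` expects columns `participant_id`,
#' `operations_accuracy` and `span_score` and drops (1) processing-task
#' accuracy below 85%, then (2) span scores below 4 or above 10.
#'
#' @param records data frame of participant records.
#' @param mode `"absolute"` (printed cut-offs, default) or `"percentile"`.
#' @return list with `survivors` (the filtered data frame) and `report`
#'   (class `exclusion_report`: per-rule removal counts in order, survivor
#'   ids).
#' @name exclusion_filters
NULL

apply_rules <- function(records, rules) {
  removed <- integer(0)
  for (rule_name in names(rules)) {
    if (!nrow(records)) {
      removed[rule_name] <- 0L
      next
    }
    keep <- rules[[rule_name]](records)
    if (anyNA(keep)) {
      stop_validation("missing fields for participant(s): ",
                      paste(records$participant_id[is.na(keep)],
                            collapse = ", "))
    }
    removed[rule_name] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  report <- structure(list(removed = removed,
                           survivor_ids = records$participant_id,
                           n_input = nrow(records) + sum(removed)),
                      class = "exclusion_report")
  list(survivors = records, report = report)
}

#' @rdname exclusion_filters
#' @export
filter_study1 <- function(records, mode = c("absolute", "percentile")) {
  mode <- match.arg(mode)
  need <- c("participant_id", "series_length", "completion_minutes")
  if (!all(need %in% names(records))) {
    stop_validation("records need columns: ", paste(need, collapse = ", "))
  }
  if (mode == "absolute") {
    len_cut <- 103
    time_lo <- 7.5
    time_hi <- 15
  } else {
    len_cut <- quantile(records$series_length, 0.10, names = FALSE, type = 1)
    time_lo <- quantile(records$completion_minutes, 0.10, names = FALSE)
    time_hi <- 15
  }
  apply_rules(records, list(
    short_series = function(d) d$series_length >= len_cut,
    completion_time = function(d)
      d$completion_minutes >= time_lo & d$completion_minutes <= time_hi))
}

#' @rdname exclusion_filters
#' @export
filter_study2 <- function(records, mode = c("absolute", "percentile")) {
  mode <- match.arg(mode)
  need <- c("participant_id", "operations_accuracy", "span_score")
  if (!all(need %in% names(records))) {
    stop_validation("records need columns: ", paste(need, collapse = ", "))
  }
  if (mode == "absolute") {
    acc_cut <- 0.85
    span_lo <- 4
    span_hi <- 10
  } else {
    acc_cut <- 0.85
    span_lo <- quantile(records$span_score, 0.10, names = FALSE, type = 1)
    span_hi <- quantile(records$span_score, 0.90, names = FALSE, type = 1)
  }
  apply_rules(records, list(
    operations_accuracy = function(d) d$operations_accuracy >= acc_cut,
    span_bounds = function(d)
      d$span_score >= span_lo & d$span_score <= span_hi))
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("exclusion report:", x$n_input, "records in,",
      length(x$survivor_ids), "survivors\n")
  for (nm in names(x$removed)) {
    cat(sprintf("  rule %-20s removed %d\n", nm, x$removed[[nm]]))
  }
  invisible(x)
}

#' @export
format.exclusion_report <- function(x, ...) {
  jsonlite::toJSON(list(n_input = x$n_input, removed = as.list(x$removed),
                        survivor_ids = x$survivor_ids), auto_unbox = TRUE)
}
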