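#' Build the 64-pair randomness-comparison task
#'
#' One pair per length-6 binary prefix: the two length-7 series
#' `prefix + 0` and `prefix + 1`, which differ only in their last element
#' and jointly exhaust all 128 length-7 strings.  The side on which each
#' member is displayed and the presentation order are randomized under
#' `seed`.  The scoring key marks the member with the strictly greater CTM
#' value as correct; pairs whose members have equal complexity are flagged
#' as ties.
#'
#' @param table the CTM lookup table.
#' @param seed RNG seed for side and order randomization.
#' @return a data frame of class `comparison_pairs` with columns `prefix`,
#'   `left`, `right`, `correct_side` (`"left"`, `"right"` or `"tie"`),
#'   `tie` and `presentation_order`.
#' @export
build_comparison_pairs <- function(table = ctm_table_default(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prefixes <- vapply(0:63, function(code)
    symbols_to_string(code_to_bits(code, 6L)), character(1))
  s0 <- paste0(prefixes, "0")
  s1 <- paste0(prefixes, "1")
  v <- table$values[[7L]]
  k0 <- v[strtoi(s0, base = 2L) + 1]
  k1 <- v[strtoi(s1, base = 2L) + 1]
  tie <- abs(k0 - k1) <= 1e-12
  zero_left <- runif(64) < 0.5
  left <- ifelse(zero_left, s0, s1)
  right <- ifelse(zero_left, s1, s0)
  k_left <- ifelse(zero_left, k0, k1)
  k_right <- ifelse(zero_left, k1, k0)
  correct <- ifelse(tie, "tie", ifelse(k_left > k_right, "left", "right"))
  out <- data.frame(prefix = prefixes, left = left, right = right,
                    correct_side = correct, tie = tie,
                    presentation_order = sample.int(64),
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_pairs", "data.frame")
  out
}

#' Correctness index of comparison-task responses
#'
#' The proportion of pairs answered with the objectively more complex
#' member.  Tie pairs carry no scoring key and are excluded from the
#' denominator (their count is attached as an attribute); a missing
#' response (timeout, `NA`) counts as incorrect by default or can be
#' dropped from the denominator.
#'
#' @param responses data frame with columns `pair_prefix` and
#'   `chosen_side` (`"left"`, `"right"` or `NA` for a timeout), one row per
#'   pair.
#' @param pairs the [build_comparison_pairs()] table the responses answer.
#' @param timeouts `"incorrect"` (default) or `"drop"`.
#' @return correctness index in \[0, 1\], with attributes `n_tie_pairs` and
#'   `n_scored`.
#' @export
correctness_index <- function(responses, pairs,
                              timeouts = c("incorrect", "drop")) {
  timeouts <- match.arg(timeouts)
  stopifnot(inherits(pairs, "comparison_pairs"))
  if (nrow(responses) != nrow(pairs)) {
    stop_validation("response count (", nrow(responses),
                    ") does not match pair count (", nrow(pairs), ")")
  }
  m <- match(pairs$prefix, responses$pair_prefix)
  if (anyNA(m)) stop_validation("responses missing for some pairs")
  chosen <- responses$chosen_side[m]
  scored <- !pairs$tie
  if (timeouts == "drop") scored <- scored & !is.na(chosen)
  n_scored <- sum(scored)
  if (!n_scored) stop_validation("no scorable (non-tie) pairs")
  hits <- !is.na(chosen[scored]) &
    chosen[scored] == pairs$correct_side[scored]
  structure(sum(hits) / n_scored,
            n_tie_pairs = sum(pairs$tie), n_scored = n_scored)
}

#' Partial span score of complex-span records
#'
#' Sums correct recalls over all trials.  The letter-level convention
#' (default) credits every letter recalled in its position, including in
#' failed trials; the trial-level alternative counts whole correct trials.
#'
#' @param records data frame with columns `trial_index`, `string_length`,
#'   `letters_correct`, `trial_correct`, ordered by trial.
#' @param level `"letter"` (default) or `"trial"`.
#' @return integer score (0 for an empty record set).
#' @export
partial_span_score <- function(records, level = c("letter", "trial")) {
  level <- match.arg(level)
  if (is.null(records) || !nrow(records)) return(0L)
  if (any(records$letters_correct > records$string_length) ||
      any(records$letters_correct < 0)) {
    stop_validation("letters_correct must lie in [0, string_length]")
  }
  if (any(records$trial_correct &
          records$letters_correct != records$string_length)) {
    stop_validation("a correct trial must have all letters correct")
  }
  if (level == "letter") sum(records$letters_correct)
  else sum(records$trial_correct)
}
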