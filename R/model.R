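#' Parameters of the random-series generation model
#'
#' The model casts random-like series generation as the interaction of four
#' parts: a bounded working-memory buffer that holds the last `k` produced
#' symbols, an active schema that proposes the next symbol (alternating the
#' previous one with probability `theta` — the well-documented alternation
#' bias puts this around 0.6-0.7), a randomness judgment that accepts the
#' proposal only if it does not make the remembered window less complex,
#' and fatigue: the probability `p_t` that the judgment is executed
#' correctly decays exponentially from `p0` towards `fatigue_floor` at rate
#' `lambda`.  When the display does not show the recent symbols (the
#' "invisible" condition), maintaining the buffer costs extra resources and
#' the decay is steeper by the factor `1 + kappa`.
#'
#' @param wm_capacity_k working-memory buffer length (nominally 5..9).
#' @param judgment_accuracy_p0 probability the complexity judgment is
#'   executed correctly at the start of the task.
#' @param fatigue_rate_lambda per-element decay constant (>= 0).
#' @param fatigue_floor asymptotic judgment accuracy; 0.5 means the
#'   judgment eventually degenerates to a coin flip.
#' @param storage_load_kappa multiplier of the fatigue rate when the buffer
#'   must be maintained internally (invisible condition).
#' @param schema_alternation_bias_theta probability the schema proposes an
#'   alternation of the previous symbol.
#' @param condition `"visible"` or `"invisible"`.
#' @param series_length number of stimuli presented (default 120).
#' @param omission_prob probability a stimulus receives no response.
#' @param seed RNG seed for [generate_series()]; `NULL` leaves the RNG
#'   state alone.
#' @return a validated `model_params` object.
#' @export
model_params <- function(wm_capacity_k = 7L,
                         judgment_accuracy_p0 = 0.8,
                         fatigue_rate_lambda = 0.01,
                         fatigue_floor = 0.5,
                         storage_load_kappa = 1,
                         schema_alternation_bias_theta = 0.65,
                         condition = c("invisible", "visible"),
                         series_length = 120L,
                         omission_prob = 0,
                         seed = NULL) {
  condition <- match.arg(condition)
  k <- as.integer(wm_capacity_k)
  if (k < 2L) stop_validation("wm_capacity_k must be >= 2")
  probs <- c(judgment_accuracy_p0, fatigue_floor,
             schema_alternation_bias_theta, omission_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_validation("probabilities must lie in [0, 1]")
  }
  if (fatigue_floor > judgment_accuracy_p0) {
    stop_validation("fatigue_floor must not exceed judgment_accuracy_p0")
  }
  if (fatigue_rate_lambda < 0 || storage_load_kappa < 0) {
    stop_validation("fatigue_rate_lambda and storage_load_kappa must be >= 0")
  }
  structure(list(wm_capacity_k = k,
                 judgment_accuracy_p0 = judgment_accuracy_p0,
                 fatigue_rate_lambda = fatigue_rate_lambda,
                 fatigue_floor = fatigue_floor,
                 storage_load_kappa = storage_load_kappa,
                 schema_alternation_bias_theta = schema_alternation_bias_theta,
                 condition = condition,
                 series_length = as.integer(series_length),
                 omission_prob = omission_prob,
                 seed = seed),
            class = "model_params")
}

#' Fresh agent state
#'
#' @param params a [model_params()] object.
#' @return list with an empty buffer, element index `t = 0` and the initial
#'   judgment accuracy `p_t = p0`.
#' @export
agent_state <- function(params) {
  list(buffer = integer(0), t = 0L, p_t = params$judgment_accuracy_p0)
}

# effective fatigue exponent; storage load only bites when the past
# elements are not displayed
lambda_effective <- function(params) {
  params$fatigue_rate_lambda *
    (1 + params$storage_load_kappa * (params$condition == "invisible"))
}

#' Propose the next element from the active schema
#'
#' With an empty buffer the proposal is a fair draw; otherwise the schema
#' proposes an alternation of the last produced symbol with probability
#' `theta` and a repetition otherwise.
#'
#' @param state an [agent_state()].
#' @param params a [model_params()].
#' @return 0 or 1.
#' @export
propose_element <- function(state, params) {
  if (!length(state$buffer)) {
    return(as.integer(runif(1) < 0.5))
  }
  last <- state$buffer[[length(state$buffer)]]
  if (runif(1) < params$schema_alternation_bias_theta) 1L - last else last
}

#' Randomness judgment of a candidate element
#'
#' The remembered window extended by the candidate is compared with the
#' window extended by the opposite symbol (both truncated to the last `k`
#' symbols and normalized for their own length).  With probability `p_t`
#' the judgment is veridical — the candidate is accepted iff its window is
#' at least as complex as the alternative (ties accepted) — and with
#' probability `1 - p_t` the judgment degrades to a fair coin flip.  An
#' empty buffer always accepts.
#'
#' @param state an [agent_state()].
#' @param candidate proposed symbol, 0 or 1.
#' @param params a [model_params()].
#' @param table the CTM lookup table.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
judge_accepts <- function(state, candidate, params,
                          table = ctm_table_default()) {
  if (!length(state$buffer)) return(TRUE)
  if (runif(1) >= state$p_t) {
    return(runif(1) < 0.5)
  }
  k <- params$wm_capacity_k
  win_c <- tail(c(state$buffer, candidate), k)
  win_o <- tail(c(state$buffer, 1L - candidate), k)
  w <- length(win_c)
  v <- table$values[[w]]
  v[bits_to_code(win_c) + 1] >= v[bits_to_code(win_o) + 1]
}

#' One step of the generation model
#'
#' With probability `omission_prob` the stimulus is missed: nothing is
#' emitted and only the element index (and with it fatigue) advances.
#' Otherwise the schema proposes a symbol and the judgment accepts or
#' rejects it; a rejected proposal is replaced by the opposite symbol,
#' which is then accepted unconditionally (with a binary alphabet there is
#' no third option).  The emitted symbol enters the buffer, displacing the
#' oldest one beyond capacity `k`.
#'
#' @param state an [agent_state()].
#' @param params a [model_params()].
#' @param table the CTM lookup table.
#' @return list `state` (updated) and `emitted` (0, 1, or `NA` on omission).
#' @export
model_step <- function(state, params, table = ctm_table_default()) {
  emitted <- NA_integer_
  if (params$omission_prob == 0 || runif(1) >= params$omission_prob) {
    cand <- propose_element(state, params)
    if (!judge_accepts(state, cand, params, table)) {
      cand <- 1L - cand
    }
    emitted <- cand
    state$buffer <- tail(c(state$buffer, emitted), params$wm_capacity_k)
  }
  state$t <- state$t + 1L
  state$p_t <- params$fatigue_floor +
    (params$judgment_accuracy_p0 - params$fatigue_floor) *
    exp(-lambda_effective(params) * state$t)
  list(state = state, emitted = emitted)
}

#' Generate a full series from the model
#'
#' Runs [model_step()] for `series_length` stimuli and collects the emitted
#' symbols.  Deterministic given `params$seed`.
#'
#' @param params a [model_params()].
#' @param table the CTM lookup table.
#' @param participant_id identifier attached to the series.
#' @return a [binary_series()] whose condition is the model's.
#' @export
generate_series <- function(params, table = ctm_table_default(),
                            participant_id = NA_character_) {
  stopifnot(inherits(params, "model_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  state <- agent_state(params)
  out <- integer(0)
  for (i in seq_len(params$series_length)) {
    step <- model_step(state, params, table)
    state <- step$state
    if (!is.na(step$emitted)) out <- c(out, step$emitted)
  }
  binary_series(out, participant_id = participant_id,
                condition = params$condition)
}

#' Simulate responses to the randomness-comparison task
#'
#' For each pair the (objectively) more complex member is chosen with
#' probability `plogis(alpha + gamma * delta)`, where `delta` is the
#' absolute normalized-complexity gap of the pair; `alpha` captures the
#' responder's discrimination ability and `gamma` how strongly the gap
#' helps.  Tie pairs are answered at random.
#'
#' @param discrimination_alpha responder ability on the logit scale.
#' @param gain_gamma complexity-gap gain (>= 0).
#' @param pairs a [build_comparison_pairs()] table.
#' @param table the CTM lookup table.
#' @param seed optional RNG seed.
#' @return data frame `pair_prefix`, `chosen_side` (`"left"`/`"right"`).
#' @export
simulate_comparison_responses <- function(discrimination_alpha, gain_gamma,
                                          pairs,
                                          table = ctm_table_default(),
                                          seed = NULL) {
  stopifnot(inherits(pairs, "comparison_pairs"))
  if (gain_gamma < 0) stop_validation("gain_gamma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  nc <- function(s) normalize_complexity(ctm(s, table), nchar(s), table = table)
  delta <- abs(vapply(pairs$left, nc, numeric(1)) -
               vapply(pairs$right, nc, numeric(1)))
  p_correct <- plogis(discrimination_alpha + gain_gamma * delta)
  pick_correct <- runif(nrow(pairs)) < p_correct
  chosen <- ifelse(pairs$correct_side == "tie",
                   ifelse(runif(nrow(pairs)) < 0.5, "left", "right"),
            ifelse(pick_correct, pairs$correct_side,
                   ifelse(pairs$correct_side == "left", "right", "left")))
  data.frame(pair_prefix = pairs$prefix, chosen_side = chosen,
             stringsAsFactors = FALSE)
}

#' Simulate a complex-span test
#'
#' Trials start at string length 2; each letter is recalled in position
#' with probability `plogis(slope_a * (latent_capacity_c - m))` for a trial
#' of length `m`.  A trial is correct only if every letter is; the length
#' increases after a correct trial and stays otherwise, and the procedure
#' stops after two consecutive failed trials (or at `max_trials`, flagged).
#' The partial span score sums correctly recalled letters over all trials.
#'
#' @param latent_capacity_c latent working-memory capacity (letters).
#' @param slope_a discriminability of the recall success curve (> 0).
#' @param seed optional RNG seed.
#' @param max_trials safety cap on the number of trials.
#' @return list with `score` (partial span), `records` (one row per trial:
#'   `trial_index`, `string_length`, `letters_correct`, `trial_correct`)
#'   and `capped` (`TRUE` if `max_trials` was hit).
#' @export
simulate_span_test <- function(latent_capacity_c, slope_a, seed = NULL,
                               max_trials = 25L) {
  if (slope_a <= 0) stop_validation("slope_a must be > 0")
  if (!is.null(seed)) set.seed(seed)
  m <- 2L
  consec_fail <- 0L
  rec <- list()
  i <- 0L
  while (consec_fail < 2L && i < max_trials) {
    i <- i + 1L
    p_letter <- plogis(slope_a * (latent_capacity_c - m))
    correct <- sum(runif(m) < p_letter)
    ok <- correct == m
    rec[[i]] <- data.frame(trial_index = i, string_length = m,
                           letters_correct = correct, trial_correct = ok)
    if (ok) {
      m <- m + 1L
      consec_fail <- 0L
    } else {
      consec_fail <- consec_fail + 1L
    }
  }
  records <- do.call(rbind, rec)
  list(score = sum(records$letters_correct), records = records,
       capped = consec_fail < 2L)
}
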