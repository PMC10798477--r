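# the working-memory generation model and its simulators

test_that("schema proposals follow the alternation bias", {
  st <- list(buffer = 0L, t = 1L, p_t = 1)
  p1 <- model_params(schema_alternation_bias_theta = 1)
  set.seed(31)
  expect_true(all(replicate(50, propose_element(st, p1)) == 1L))
  p5 <- model_params(schema_alternation_bias_theta = 0.5)
  set.seed(32)
  rate5 <- mean(replicate(10000, propose_element(st, p5)) != 0L)
  expect_equal(rate5, 0.5, tolerance = 0.02)
  # the 0.6-0.7 band typical of human alternation rates
  p65 <- model_params(schema_alternation_bias_theta = 0.65)
  set.seed(33)
  rate65 <- mean(replicate(10000, propose_element(st, p65)) != 0L)
  expect_equal(rate65, 0.65, tolerance = 0.02)
})

test_that("veridical judgment prefers the more complex window", {
  tb <- tab()
  # appending 1 to a run of zeros gives the strictly more complex window
  expect_gt(ctm("0000001", tb), ctm("0000000", tb))
  st <- list(buffer = rep(0L, 6), t = 7L, p_t = 1)
  par <- model_params(wm_capacity_k = 7)
  set.seed(34)
  expect_true(judge_accepts(st, 1L, par, tb))
  expect_false(judge_accepts(st, 0L, par, tb))
  # degraded judgment is a fair coin flip
  st0 <- list(buffer = rep(0L, 6), t = 7L, p_t = 0)
  set.seed(35)
  acc <- mean(replicate(10000, judge_accepts(st0, 0L, par, tb)))
  expect_equal(acc, 0.5, tolerance = 0.02)
  # empty buffer always accepts
  expect_true(judge_accepts(agent_state(par), 0L, par, tb))
})

test_that("fatigue dynamics follow the exponential decay contract", {
  tb <- mini_tab()
  run_pt <- function(cond, lambda, kappa) {
    par <- model_params(fatigue_rate_lambda = lambda,
                        storage_load_kappa = kappa, condition = cond,
                        series_length = 40)
    st <- agent_state(par)
    out <- numeric(40)
    for (i in 1:40) {
      step <- model_step(st, par, tb)
      st <- step$state
      out[i] <- st$p_t
    }
    out
  }
  set.seed(36)
  # kappa = 0: identical accuracy trajectories across conditions
  expect_identical(run_pt("visible", 0.02, 0), run_pt("invisible", 0.02, 0))
  # lambda = 0: no decay at all
  expect_true(all(run_pt("invisible", 0, 1) ==
                    model_params()$judgment_accuracy_p0))
  # kappa > 0: the invisible condition decays faster
  expect_true(all(run_pt("invisible", 0.02, 1) <=
                    run_pt("visible", 0.02, 1)))
})

test_that("buffer respects capacity and series generation is deterministic", {
  tb <- mini_tab()
  par <- model_params(wm_capacity_k = 5, seed = 99)
  st <- agent_state(par)
  set.seed(37)
  for (i in 1:120) {
    step <- model_step(st, par, tb)
    st <- step$state
    expect_lte(length(st$buffer), 5L)
  }
  s1 <- generate_series(par, tb)
  s2 <- generate_series(par, tb)
  expect_identical(s1$symbols, s2$symbols)
  expect_identical(s1$length, 120L)
  # omissions shorten the series binomially
  par_om <- model_params(omission_prob = 0.2, seed = 7)
  s3 <- generate_series(par_om, tb)
  expect_lt(s3$length, 120L)
  expect_gte(s3$length, 60L)
})

test_that("larger working memory yields more complex series", {
  tb <- tab()
  mean_oc <- function(k, n = 150) {
    vals <- numeric(n)
    for (i in seq_len(n)) {
      par <- model_params(wm_capacity_k = k, judgment_accuracy_p0 = 1,
                          fatigue_rate_lambda = 0, seed = NULL)
      vals[i] <- overall_complexity(generate_series(par, tb), tb)
    }
    vals
  }
  set.seed(38)
  lo <- mean_oc(3)
  hi <- mean_oc(9)
  tt <- t.test(hi, lo, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("comparison responder behaves across the discrimination range", {
  tb <- tab()
  pairs <- build_comparison_pairs(tb, seed = 40)
  # chance responder
  set.seed(41)
  ci0 <- mean(replicate(50, correctness_index(
    simulate_comparison_responses(0, 0, pairs, tb), pairs)))
  expect_equal(ci0, 0.5, tolerance = 0.04)
  # near-perfect responder on non-tie pairs
  set.seed(42)
  ci_inf <- correctness_index(
    simulate_comparison_responses(20, 0, pairs, tb), pairs)
  expect_equal(unclass(ci_inf)[1], 1, tolerance = 1e-9,
               ignore_attr = TRUE)
  # monotone in alpha
  set.seed(43)
  ci_mid <- mean(replicate(30, correctness_index(
    simulate_comparison_responses(1, 2, pairs, tb), pairs)))
  expect_gt(ci_mid, ci0)
  expect_lt(ci_mid, 1)
})

test_that("span simulator terminates, caps, and scales with capacity", {
  set.seed(44)
  low <- simulate_span_test(-10, 1.5)
  expect_lte(low$score, 2)
  expect_identical(nrow(low$records), 2L)
  high <- simulate_span_test(1000, 1.5)
  expect_true(high$capped)
  expect_identical(nrow(high$records), 25L)
  mean_scores <- vapply(c(4, 6, 8), function(cc) {
    mean(vapply(seq_len(500), function(i)
      simulate_span_test(cc, 1.5)$score, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_scores) > 0))
})
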