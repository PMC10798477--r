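# synthetic cohort generation, calibration properties, parameter recovery

test_that("cohorts are deterministic under the master seed", {
  spec <- cohort_spec(n_participants = 12, seed = 81)
  c1 <- generate_cohort(spec, tab())
  c2 <- generate_cohort(spec, tab())
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(lapply(c1$series, `[[`, "symbols"),
                   lapply(c2$series, `[[`, "symbols"))
  # byte-identical CSV output
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_series_csv(c1$series, file.path(d1, "s.csv"))
  write_series_csv(c2$series, file.path(d2, "s.csv"))
  expect_identical(unname(tools::md5sum(file.path(d1, "s.csv"))),
                   unname(tools::md5sum(file.path(d2, "s.csv"))))
  # a different seed moves the data
  c3 <- generate_cohort(cohort_spec(n_participants = 12, seed = 82), tab())
  expect_false(identical(c1$participants$series_length,
                         c3$participants$series_length))
})

test_that("cohort structure matches the study designs", {
  co <- generate_cohort(cohort_spec(n_participants = 20, seed = 83), tab())
  expect_identical(nrow(co$participants), 20L)
  # odd ids visible, even invisible (the parity allocation rule)
  expect_identical(co$participants$condition,
                   ifelse(seq_len(20) %% 2 == 1, "visible", "invisible"))
  expect_true(all(co$participants$series_length <= 120))
  expect_true(all(co$participants$correctness_index >= 0 &
                    co$participants$correctness_index <= 1))
  expect_true(all(co$participants$span_score >= 0))
  expect_identical(co$ground_truth$participant_id,
                   co$participants$participant_id)
  expect_true(all(co$ground_truth$k %in% 5:9))
  expect_error(cohort_spec(rho = 1), class = "randser_validation_error")
  expect_error(cohort_spec(n_participants = 2),
               class = "randser_validation_error")
})

test_that("exclusion filters pass generated cohorts at the designed rates", {
  rates1 <- rates2 <- numeric(6)
  for (s in 1:6) {
    co <- generate_cohort(cohort_spec(n_participants = 100, seed = 800 + s),
                          tab())
    rates1[s] <- nrow(filter_study1(co$participants)$survivors) / 100
    rates2[s] <- nrow(filter_study2(co$participants)$survivors) / 100
  }
  # designed survival: ~75% for the study-1 rules, ~60% for study-2
  expect_gt(mean(rates1), 0.55)
  expect_lt(mean(rates1), 0.95)
  expect_gt(mean(rates2), 0.40)
  expect_lt(mean(rates2), 0.85)
})

test_that("stronger ability coupling steepens the span-complexity slope", {
  slope_at <- function(rho, seed) {
    co <- generate_cohort(cohort_spec(n_participants = 150, rho = rho,
                                      seed = seed), tab())
    keep <- filter_study2(co$participants)$survivors
    profs <- lapply(co$series[keep$participant_id], rolling_complexity,
                    window_w = 7, table = tab())
    overall <- vapply(profs, `[[`, numeric(1), "overall")
    wls_fit(overall, keep$span_score, participant_weights(profs))$slope
  }
  s0 <- slope_at(0, 84)
  s6 <- slope_at(0.6, 84)
  expect_gt(s6, s0)
})

test_that("recovery finds the generating capacity and fatigue ordering", {
  set.seed(85)
  series <- lapply(1:30, function(i) {
    cond <- if (i %% 2) "visible" else "invisible"
    par <- model_params(wm_capacity_k = 7, judgment_accuracy_p0 = 0.9,
                        fatigue_rate_lambda = 0,
                        schema_alternation_bias_theta = 0.65,
                        condition = cond, seed = NULL)
    generate_series(par, tab(), participant_id = paste0("r", i))
  })
  rec <- recover_parameters(series, tab(), lambda_grid = c(0, 0.01, 0.05),
                            theta_grid = c(0.55, 0.65, 0.75), p0 = 0.9)
  for (g in rec$groups) {
    expect_true(g$k %in% 5:9)
  }
  # a constant series is excluded, and the run still completes
  series_c <- c(series[1:10],
                list(binary_series(rep(0L, 120), "const", "visible")))
  expect_warning(rec2 <- recover_parameters(series_c, tab(),
                                            lambda_grid = c(0, 0.01),
                                            theta_grid = c(0.6, 0.7)),
                 "constant")
  expect_identical(rec2$n_excluded, 1L)
})
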