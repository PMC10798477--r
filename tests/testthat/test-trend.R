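# penalized B-spline mixed trend model and permutation inference

mk_subj <- function(id, cond, grid, f) {
  data.frame(participant_id = id, condition = cond, position = grid,
             value = f(grid))
}

test_that("a noiseless common linear trend is recovered at edf ~ 1", {
  grid <- 0:49
  dat <- do.call(rbind, c(
    lapply(1:6, function(i) mk_subj(paste0("v", i), "visible", grid,
                                    function(t) 0.7 - 0.002 * t)),
    lapply(1:6, function(i) mk_subj(paste0("i", i), "invisible", grid,
                                    function(t) 0.7 - 0.002 * t))))
  f <- fit_trend_model(dat, K = 8)
  expect_lt(f$edf_f, 1.2)
  expect_lt(max(abs(f$difference_curve)), 1e-6)
  expect_lt(abs(f$linear_offset), 1e-8)
  expect_equal(f$curve_invisible, 0.7 - 0.002 * grid, tolerance = 1e-6)
})

test_that("pure subject offsets put the variance in the random part", {
  set.seed(71)
  grid <- 0:39
  dat <- do.call(rbind, lapply(1:16, function(i) {
    cond <- if (i %% 2) "visible" else "invisible"
    mk_subj(paste0("s", i), cond, grid,
            function(t) 0.6 + rnorm(1, 0, 0.1) + rnorm(length(t), 0, 0.02))
  }))
  f <- fit_trend_model(dat, K = 8)
  expect_lt(f$marginal_r2, 0.1)
  expect_gt(f$conditional_r2, 0.8)
  expect_lte(f$marginal_r2, f$conditional_r2)
})

test_that("an injected condition-specific decay shows up in the
           difference curve with the right sign pattern", {
  set.seed(72)
  grid <- 0:59
  decay <- function(t) -0.12 * exp(-t / 15) + 0.12 * exp(-59 / 15)
  dat <- do.call(rbind, c(
    lapply(1:10, function(i) mk_subj(paste0("v", i), "visible", grid,
      function(t) 0.72 + rnorm(1, 0, 0.02) + rnorm(length(t), 0, 0.04))),
    lapply(1:10, function(i) mk_subj(paste0("i", i), "invisible", grid,
      function(t) 0.72 + decay(t) + rnorm(1, 0, 0.02) +
        rnorm(length(t), 0, 0.04)))))
  f <- fit_trend_model(dat, K = 8)
  # invisible starts depressed and recovers: visible - invisible is
  # positive early and ~0 late
  early <- f$difference_curve[grid <= 10]
  late <- f$difference_curve[grid >= 45]
  expect_gt(mean(early), 0.04)
  expect_lt(mean(abs(late)), 0.03)
  p <- permutation_test_difference(f, B = 199, seed = 73)
  expect_lte(p$p_condition, 0.01)
  expect_true(all(c(p$p_condition, p$p_smooth_difference,
                    p$p_linear_offset) >= 1 / 200))
})

test_that("GCV trace is non-increasing and tiny penalties interpolate", {
  set.seed(74)
  grid <- 0:9
  target <- function(t) 0.5 + 0.03 * sin(t)
  dat <- do.call(rbind, lapply(1:6, function(i) {
    cond <- if (i %% 2) "visible" else "invisible"
    mk_subj(paste0("s", i), cond, grid, target)
  }))
  f <- fit_trend_model(dat, K = 10, lambda_smooth = 1e-8,
                       lambda_ridge = 1e-4)
  expect_true(all(diff(f$gcv_trace) <= 1e-12))
  expect_lt(max(abs(residuals(f))), 1e-4)
})

test_that("the common smooth agrees with an independent GAM fit", {
  skip_if_not_installed("mgcv")
  set.seed(75)
  grid <- 0:59
  shape <- function(t) 0.7 - 0.1 * exp(-t / 20) - 0.0005 * t
  dat <- do.call(rbind, lapply(1:12, function(i) {
    cond <- if (i %% 2) "visible" else "invisible"
    mk_subj(paste0("s", i), cond, grid,
            function(t) shape(t) + rnorm(1, 0, 0.01) +
              rnorm(length(t), 0, 0.03))
  }))
  ours <- fit_trend_model(dat, K = 10)
  ref <- mgcv::gam(value ~ s(position, k = 10), data = dat)
  ref_curve <- predict(ref, newdata = data.frame(position = grid))
  our_curve <- (ours$curve_invisible + ours$curve_visible) / 2
  expect_gt(cor(our_curve, ref_curve), 0.98)
  expect_lt(mean(abs(our_curve - ref_curve)), 0.01)
})

test_that("degenerate configurations are rejected", {
  grid <- 0:5
  dat <- do.call(rbind, lapply(1:4, function(i) {
    cond <- if (i %% 2) "visible" else "invisible"
    mk_subj(paste0("s", i), cond, grid, function(t) 0.5 + 0.01 * t)
  }))
  expect_error(fit_trend_model(dat, K = 12),
               class = "randser_config_error")
  one_cond <- dat[dat$condition == "visible", ]
  expect_error(fit_trend_model(one_cond, K = 5),
               class = "randser_validation_error")
})
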