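# rank-sum test, weighted least squares, inverse-variance weights

test_that("exact rank-sum enumeration matches hand results", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_identical(unname(r$statistic), 0)
  expect_equal(r$p.value, 1 / 3)      # 2 of the C(4,2)=6 assignments
  expect_identical(r$method, "exact")
  # identical multisets: central statistic, p ~ 1
  r2 <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_identical(unname(r2$statistic), 8)   # n^2/2
  expect_gt(r2$p.value, 0.95)
  expect_error(rank_sum_test(rep(1, 5), rep(1, 4)),
               class = "randser_validation_error")
})

test_that("both rank-sum modes track the reference implementation", {
  set.seed(61)
  for (i in 1:50) {                    # tie-free: exact vs wilcox.test
    x <- rnorm(sample(3:7, 1))
    y <- rnorm(sample(3:7, 1))
    ours <- rank_sum_test(x, y, mode = "exact")
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(unname(ours$statistic), unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-8)
  }
  for (i in 1:50) {                    # tied data: normal approximation
    x <- sample(1:6, 15, replace = TRUE)
    y <- sample(1:6, 18, replace = TRUE)
    if (max(c(x, y)) == min(c(x, y))) next
    ours <- rank_sum_test(x, y, mode = "normal")
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                        correct = TRUE))
    expect_equal(unname(ours$statistic), unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("exact and approximate rank-sum p-values agree to ~0.02", {
  set.seed(62)
  for (i in 1:20) {
    x <- rnorm(8)
    y <- rnorm(8)
    pe <- rank_sum_test(x, y, mode = "exact")$p.value
    pn <- rank_sum_test(x, y, mode = "normal")$p.value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("WLS with unit weights equals the OLS closed form", {
  x <- c(1, 2, 3, 5, 8)
  y <- c(2.1, 3.9, 6.2, 9.8, 16.1)
  ours <- wls_fit(y, x)
  ref <- lm(y ~ x)
  expect_equal(unname(coef(ours)), unname(coef(ref)[c(1, 2)]),
               tolerance = 1e-10)
  expect_equal(ours$weighted_r2, summary(ref)$r.squared, tolerance = 1e-10)
  expect_equal(unname(ours$slope_ci), unname(confint(ref)[2, ]),
               tolerance = 1e-10)
  set.seed(63)
  for (i in 1:20) {
    x <- rnorm(20)
    y <- 1 + 0.5 * x + rnorm(20)
    expect_equal(wls_fit(y, x)$slope, unname(coef(lm(y ~ x))[2]),
                 tolerance = 1e-10)
  }
})

test_that("WLS matches lm(weights=) and is scale invariant", {
  set.seed(64)
  x <- rnorm(25)
  y <- 0.3 + 0.7 * x + rnorm(25, 0, 0.5)
  w <- rexp(25) + 0.1
  ours <- wls_fit(y, x, w)
  ref <- lm(y ~ x, weights = w)
  expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-10)
  scaled <- wls_fit(y, x, 100 * w)
  expect_equal(scaled$slope, ours$slope, tolerance = 1e-12)
  expect_equal(scaled$weighted_r2, ours$weighted_r2, tolerance = 1e-12)
  # exact linear data: slope recovered, perfect fit
  perf <- wls_fit(2 * x, x, w)
  expect_equal(perf$slope, 2, tolerance = 1e-10)
  expect_equal(perf$weighted_r2, 1, tolerance = 1e-10)
  expect_lt(diff(perf$slope_ci), 1e-6)
  expect_error(wls_fit(y, x, c(w[-1], -1)),
               class = "randser_validation_error")
  expect_error(wls_fit(y, rep(1, 25), w),
               class = "randser_validation_error")
})

test_that("participant weights are reciprocal variances with a cap", {
  prof <- list(values = c(0.5, 0.6, 0.4, 0.5))
  class(prof) <- "complexity_profile"
  expect_equal(participant_weight(prof), 1 / var(prof$values))
  expect_equal(participant_weight(c(0, 0.2)), 1 / var(c(0, 0.2)))
  expect_error(participant_weight(0.5), class = "randser_validation_error")
  set.seed(65)
  profs <- c(lapply(1:20, function(i) rnorm(30, 0.6, 0.1)),
             list(rep(0.5, 30)))
  w <- participant_weights(profs)
  expect_identical(attr(w, "n_capped"), 1L)
  finite_w <- w[1:20]
  expect_equal(unname(w[21]), 10 * quantile(finite_w, 0.99, names = FALSE))
  expect_true(all(w > 0))
})
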