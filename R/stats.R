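#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test reported in the Mann-Whitney U convention.
#' Ties receive midranks.  For small samples (`n1 + n2 <= 16`) the exact
#' conditional null distribution is enumerated over all assignments of the
#' pooled ranks; larger samples use the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"` (size-based, default), `"exact"` or `"normal"`.
#' @return object of class `rank_sum_test`: `statistic` (W), `p.value`,
#'   `method`, `n1`, `n2`.
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y)) stop_validation("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  pooled <- c(x, y)
  if (max(pooled) == min(pooled)) {
    stop_validation("degenerate samples: all values identical")
  }
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (mode == "auto") mode <- if (n <= 16) "exact" else "normal"

  if (mode == "exact") {
    subsets <- combn(n, n1)
    Us <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) stop_validation("degenerate rank variance")
    z <- U - mu
    correction <- sign(z) * 0.5
    p <- min(1, 2 * pnorm(-abs((z - correction) / sqrt(sigma2))))
    method <- "normal_approx_tie_corrected"
  }
  structure(list(statistic = c(W = U), p.value = p, method = method,
                 n1 = n1, n2 = n2),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum test (%s): W = %g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p.value, x$n1, x$n2))
  invisible(x)
}

#' Weighted least-squares simple regression
#'
#' Closed-form WLS of `y` on a single predictor, the workhorse behind the
#' complexity-on-correctness and complexity-on-span analyses, where each
#' participant is weighted by the inverse variance of their rolling
#' complexity.  With equal weights the fit reduces to ordinary least
#' squares.
#'
#' @param y response vector.
#' @param x predictor vector.
#' @param weights positive weights; `NULL` for OLS.
#' @param conf_level confidence level of the slope interval.
#' @param weights_spec free-text description recorded in the result.
#' @return object of class `wls_fit`: `slope`, `intercept`, `slope_ci`,
#'   `slope_se`, `weighted_r2`, `F`, `p.value`, `n`, `df`, `fitted`,
#'   `residuals`, `weights`, `weights_spec`.
#' @export
wls_fit <- function(y, x, weights = NULL, conf_level = 0.95,
                    weights_spec = "user-supplied") {
  y <- as.numeric(y)
  x <- as.numeric(x)
  if (is.null(weights)) {
    weights <- rep(1, length(y))
    weights_spec <- "equal (OLS)"
  }
  w <- as.numeric(weights)
  if (length(y) != length(x) || length(y) != length(w)) {
    stop_validation("y, x and weights must have equal length")
  }
  if (length(y) < 3) stop_validation("need at least 3 points")
  if (any(w <= 0) || anyNA(w)) stop_validation("weights must be positive")
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  if (sxx < 1e-14 * sum(w) * max(1, mean(x)^2)) {
    stop_validation("degenerate predictor: zero weighted variance")
  }
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  fit <- intercept + slope * x
  res <- y - fit
  sse <- sum(w * res^2)
  sst <- sum(w * (y - yb)^2)
  df <- length(y) - 2L
  s2 <- sse / df
  se <- sqrt(s2 / sxx)
  tval <- slope / se
  ci <- slope + c(-1, 1) * qt(1 - (1 - conf_level) / 2, df) * se
  structure(list(slope = slope, intercept = intercept, slope_ci = ci,
                 slope_se = se, weighted_r2 = 1 - sse / sst,
                 F = tval^2, p.value = 2 * pt(-abs(tval), df),
                 n = length(y), df = df, fitted = fit, residuals = res,
                 weights = w, weights_spec = weights_spec,
                 conf_level = conf_level),
            class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf("weighted least squares (n = %d, weights: %s)\n", x$n,
              x$weights_spec))
  cat(sprintf("  slope     %8.4f  [%0.4f, %0.4f] (%.0f%% CI)\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], 100 * x$conf_level))
  cat(sprintf("  intercept %8.4f\n", x$intercept))
  cat(sprintf("  weighted R2 = %.4f, F(1, %d) = %.3f, p = %.4g\n",
              x$weighted_r2, x$df, x$F, x$p.value))
  invisible(x)
}

#' @export
coef.wls_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.wls_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  object$intercept + object$slope * as.numeric(newdata)
}

#' @export
residuals.wls_fit <- function(object, ...) object$residuals

#' Inverse-variance participant weight
#'
#' The analysis weight of one participant: the reciprocal of the sample
#' variance of their rolling-complexity values.  A near-constant profile
#' (variance below `1e-12`) receives `cap` instead of an infinite weight.
#'
#' @param profile a [rolling_complexity()] profile (or numeric vector of
#'   complexities).
#' @param cap weight assigned to zero-variance profiles.
#' @return positive weight.
#' @seealso [participant_weights()] for the cohort-level capping rule.
#' @export
participant_weight <- function(profile, cap = Inf) {
  vals <- if (inherits(profile, "complexity_profile")) profile$values
          else as.numeric(profile)
  if (length(vals) < 2) {
    stop_validation("cannot form a weight from fewer than 2 values")
  }
  v <- var(vals)
  if (v < 1e-12) cap else 1 / v
}

#' Cohort inverse-variance weights with percentile capping
#'
#' Computes [participant_weight()] for every profile and replaces
#' zero-variance (infinite) weights by 10 times the 99th percentile of the
#' finite weights, so a flat profile is very influential but not dominant.
#'
#' @param profiles list of profiles (or numeric vectors).
#' @return weight vector with attribute `n_capped`.
#' @export
participant_weights <- function(profiles) {
  w <- vapply(profiles, participant_weight, numeric(1), cap = Inf)
  finite <- is.finite(w)
  if (!any(finite)) stop_validation("all profiles have zero variance")
  cap <- 10 * quantile(w[finite], 0.99, names = FALSE)
  n_capped <- sum(!finite)
  w[!finite] <- cap
  structure(w, n_capped = n_capped)
}
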