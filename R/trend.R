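# Penalized B-spline mixed trend model for rolling-complexity profiles.
#
# Model, per subject i at window position t:
#   y_it = beta0 + beta1 * vis_i + f(t) + f_d(t) * vis_i + b0_i + b1_i * t + e
# with f and f_d cubic B-spline smooths (dimension K, second-difference
# penalties, sum-to-zero over the observed grid), subject intercepts and
# slopes as ridge-penalized effects, and all smoothing/ridge parameters
# chosen by generalized cross-validation.  The invisible condition is the
# reference; vis_i indicates the visible condition, so beta1 + f_d(t) is
# the visible-minus-invisible difference curve.
#
# The implementation exploits the profile structure (every subject is
# observed on a prefix of a common grid) to assemble normal equations from
# per-length cached cross-products and to solve by a Schur complement over
# the 2x2 subject blocks; a label permutation then costs a fraction of a
# millisecond, which is what makes permutation inference on the condition
# difference practical.

profiles_to_long <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(participant_id = p$participant_id, condition = p$condition,
               position = p$positions, value = p$values,
               stringsAsFactors = FALSE)
  }))
}

# cubic B-spline basis of dimension K on [0,1] with uniformly spaced knots
# (uniform spacing makes the second-difference coefficient penalty
# annihilate exactly the constant and linear functions)
bspline_basis <- function(u, K) {
  if (K < 5) stop_config("basis dimension K must be at least 5")
  knots <- seq(-3L, K) / (K - 3)   # exact 0 and 1 at the boundary knots
  splines::splineDesign(knots, u, ord = 4)
}

build_trend_context <- function(data, K) {
  df <- if (is.data.frame(data)) data else profiles_to_long(data)
  need <- c("participant_id", "condition", "position", "value")
  if (!all(need %in% names(df))) {
    stop_validation("trend data needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$condition %in% c("visible", "invisible"))) {
    stop_validation("conditions must be 'visible' or 'invisible'")
  }
  grid <- sort(unique(df$position))
  n_grid <- length(grid)
  if (n_grid < K) {
    stop_config("only ", n_grid, " time points for basis dimension K = ", K,
                "; choose a smaller K")
  }
  u <- (grid - grid[1]) / (grid[n_grid] - grid[1])
  B <- bspline_basis(u, K)
  D2 <- diff(diag(K), differences = 2)
  S_raw <- crossprod(D2)
  Zc <- qr.Q(qr(matrix(colSums(B), ncol = 1)), complete = TRUE)[, -1,
                                                                drop = FALSE]
  Bz <- B %*% Zc                              # sum-to-zero smooth basis
  Sz <- t(Zc) %*% S_raw %*% Zc                # penalty in constrained space
  uc <- u - mean(u)
  U1 <- cbind(1, Bz)                          # intercept + smooth columns
  Ug <- cbind(U1, uc)                         # + subject-slope column
  q <- ncol(Ug)                               # K + 1

  sp <- split(df, df$participant_id)
  ids <- names(sp)
  n_subj <- length(ids)
  Tlen <- integer(n_subj)
  vis <- logical(n_subj)
  Uy <- matrix(0, q, n_subj)
  y_list <- vector("list", n_subj)
  yy <- 0
  for (i in seq_len(n_subj)) {
    d <- sp[[i]][order(sp[[i]]$position), ]
    Ti <- nrow(d)
    if (!isTRUE(all.equal(d$position, grid[seq_len(Ti)]))) {
      stop_validation("subject ", ids[i],
                      " is not observed on a prefix of the common grid")
    }
    Tlen[i] <- Ti
    vis[i] <- d$condition[[1]] == "visible"
    y_list[[i]] <- d$value
    Uy[, i] <- crossprod(Ug[seq_len(Ti), , drop = FALSE], d$value)
    yy <- yy + sum(d$value^2)
  }
  if (sum(vis) < 2 || sum(!vis) < 2) {
    stop_validation("need at least 2 subjects per condition")
  }
  # cumulative cross-products of Ug, cached at each needed prefix length
  Tset <- sort(unique(Tlen))
  CUU <- vector("list", max(Tset))
  acc <- matrix(0, q, q)
  for (t in seq_len(max(Tset))) {
    acc <- acc + tcrossprod(Ug[t, ])
    if (t %in% Tset) CUU[[t]] <- acc
  }
  list(grid = grid, u = u, K = K, Bz = Bz, Sz = Sz, U1 = U1, Ug = Ug,
       ids = ids, Tlen = Tlen, vis = vis, Uy = Uy, y = y_list, yy = yy,
       n_obs = sum(Tlen), n_subj = n_subj, Tset = Tset, CUU = CUU)
}

# per-candidate cache of everything that depends on the ridge penalties but
# not on the condition labels
ridge_cache <- function(ctx, lam_r0, lam_r1) {
  K <- ctx$K
  q <- K + 1
  zi <- c(1, q)                               # subject intercept/slope cols
  Pz <- diag(c(lam_r0, lam_r1), 2)
  per_T <- list()
  for (t in ctx$Tset) {
    CU <- ctx$CUU[[t]]
    A <- CU[1:K, 1:K]
    Jb <- CU[1:K, zi]
    H <- CU[zi, zi]
    Ci <- solve(H + Pz)
    per_T[[as.character(t)]] <- list(
      A = A, Jb = Jb, H = H, Ci = Ci,
      M = Jb %*% Ci %*% t(Jb),
      N = Jb %*% Ci %*% H %*% Ci %*% t(Jb),
      JC = Jb %*% Ci,
      tcH = sum(diag(Ci %*% H)))
  }
  # y-dependent per-subject pieces
  r <- matrix(0, K, ctx$n_subj)
  qz <- numeric(ctx$n_subj)
  for (i in seq_len(ctx$n_subj)) {
    pt <- per_T[[as.character(ctx$Tlen[i])]]
    zy <- ctx$Uy[c(1, q), i]
    r[, i] <- pt$JC %*% zy
    qz[i] <- sum(zy * (pt$Ci %*% zy))
  }
  list(per_T = per_T, r = r, qz = qz, Pz = Pz)
}

# solve the penalized normal equations for a given label assignment.
# terms: "full", "no_offset" (drop beta1), "no_diff" (drop f_d),
#        "none" (drop both).
solve_trend <- function(ctx, rc, lam_f, lam_d, vis, terms = "full",
                        light = FALSE) {
  K <- ctx$K
  q <- K + 1
  sumA <- matrix(0, K, K); sumAv <- matrix(0, K, K)
  sumM <- matrix(0, K, K); sumMv <- matrix(0, K, K)
  sumN <- matrix(0, K, K); sumNv <- matrix(0, K, K)
  tcH_tot <- 0
  for (t in ctx$Tset) {
    pt <- rc$per_T[[as.character(t)]]
    n_all <- sum(ctx$Tlen == t)
    n_vis <- sum(ctx$Tlen == t & vis)
    sumA <- sumA + n_all * pt$A;  sumAv <- sumAv + n_vis * pt$A
    sumM <- sumM + n_all * pt$M;  sumMv <- sumMv + n_vis * pt$M
    if (!light) {
      sumN <- sumN + n_all * pt$N; sumNv <- sumNv + n_vis * pt$N
    }
    tcH_tot <- tcH_tot + n_all * pt$tcH
  }
  uy <- ctx$Uy[1:K, , drop = FALSE]
  Fy_all <- rowSums(uy); Fy_vis <- rowSums(uy[, vis, drop = FALSE])
  r_all <- rowSums(rc$r); r_vis <- rowSums(rc$r[, vis, drop = FALSE])

  two_block <- function(Mall, Mvis) {
    rbind(cbind(Mall, Mvis), cbind(Mvis, Mvis))
  }
  FF <- two_block(sumA, sumAv)
  W <- two_block(sumM, sumMv)
  GN <- two_block(sumN, sumNv)
  rhs_full <- c(Fy_all - r_all, Fy_vis - r_vis)
  Pf <- matrix(0, 2 * K, 2 * K)
  fidx <- 2:K                 # smooth f columns within block 1
  didx <- K + (2:K)           # difference smooth columns within block 2
  Pf[fidx, fidx] <- lam_f * ctx$Sz
  Pf[didx, didx] <- lam_d * ctx$Sz

  keep <- switch(terms,
                 full = 1:(2 * K),
                 no_offset = setdiff(1:(2 * K), K + 1),
                 no_diff = 1:(K + 1),
                 none = 1:K)
  Smat <- (FF + Pf - W)[keep, keep, drop = FALSE]
  rhs <- rhs_full[keep]
  bf_k <- solve(Smat, rhs)
  bf <- numeric(2 * K)
  bf[keep] <- bf_k

  g_inv <- bf[1:K]
  g_vis <- bf[1:K] + bf[K + 1:K]
  sum_gr <- sum(g_inv * (r_all - r_vis)) + sum(g_vis * r_vis)
  bXy <- sum(bf[1:K] * Fy_all) + sum(bf[K + 1:K] * Fy_vis) +
    (sum(rc$qz) - sum_gr)
  prss <- ctx$yy - bXy
  if (light) return(list(prss = prss, bf = bf))

  # random effects, penalties, edf, GCV
  b <- matrix(0, 2, ctx$n_subj)
  pen_z <- 0
  for (i in seq_len(ctx$n_subj)) {
    pt <- rc$per_T[[as.character(ctx$Tlen[i])]]
    zy <- ctx$Uy[c(1, q), i]
    g_i <- if (vis[i]) g_vis else g_inv
    b[, i] <- pt$Ci %*% (zy - crossprod(pt$Jb, g_i))
    pen_z <- pen_z + sum(b[, i]^2 * diag(rc$Pz))
  }
  pen_f <- sum(bf[fidx] * (lam_f * ctx$Sz %*% bf[fidx])) +
    sum(bf[didx] * (lam_d * ctx$Sz %*% bf[didx]))
  rss <- prss - pen_f - pen_z

  Sinv_E <- solve(Smat, (FF - W)[keep, keep, drop = FALSE])
  edf_fixed_diag <- numeric(2 * K)
  edf_fixed_diag[keep] <- diag(Sinv_E)
  edf_rand <- tcH_tot +
    sum(diag(solve(Smat, (GN - W)[keep, keep, drop = FALSE])))
  edf_total <- sum(diag(Sinv_E)) + edf_rand
  list(prss = prss, rss = rss, bf = bf, b = b,
       edf_total = edf_total,
       edf_f = sum(edf_fixed_diag[fidx]),
       edf_diff = sum(edf_fixed_diag[didx]),
       edf_fixed_diag = edf_fixed_diag,
       Smat = Smat, keep = keep, FF = FF, W = W, GN = GN)
}

#' Fit the penalized-spline mixed trend model
#'
#' Fits rolling-complexity trends over window position with a common smooth,
#' a condition-difference smooth plus linear condition offset (invisible
#' condition as reference), and subject random intercepts and slopes.
#' Smoothing and ridge parameters are selected by generalized
#' cross-validation on a log-spaced grid followed by a local refinement.
#'
#' @param data list of [rolling_complexity()] profiles, or a long data
#'   frame with columns `participant_id`, `condition` (`visible` /
#'   `invisible`), `position`, `value`.
#' @param K basis dimension of each smooth (default 10).
#' @param lambda_smooth,lambda_ridge candidate grids for the smooth and
#'   ridge penalties (log-spaced defaults).
#' @return an object of class `trend_fit`; see [print.trend_fit()],
#'   [predict.trend_fit()], [plot.trend_fit()] and
#'   [permutation_test_difference()].
#' @export
fit_trend_model <- function(data, K = 10L,
                            lambda_smooth = 10^seq(-2, 6, by = 2),
                            lambda_ridge = 10^seq(-1, 3, by = 1)) {
  ctx <- build_trend_context(data, as.integer(K))
  best <- NULL
  gcv_trace <- numeric(0)
  eval_cand <- function(lf, ld, l0, l1) {
    rc <- ridge_cache(ctx, l0, l1)
    fit <- solve_trend(ctx, rc, lf, ld, ctx$vis, "full")
    gcv <- ctx$n_obs * fit$rss / (ctx$n_obs - fit$edf_total)^2
    list(gcv = gcv, lam = c(lf, ld, l0, l1), rc = rc, fit = fit)
  }
  # GCV ties (e.g. noiseless inputs) resolve towards the smoother fit
  better <- function(cand, best) {
    if (is.null(best)) return(TRUE)
    tol <- 1e-12 + 1e-7 * abs(best$gcv)
    if (cand$gcv < best$gcv - tol) return(TRUE)
    if (cand$gcv <= best$gcv + tol &&
        sum(log(cand$lam)) > sum(log(best$lam))) return(TRUE)
    FALSE
  }
  for (lf in lambda_smooth) for (ld in lambda_smooth) {
    for (l0 in lambda_ridge) for (l1 in lambda_ridge) {
      cand <- eval_cand(lf, ld, l0, l1)
      if (better(cand, best)) best <- cand
      gcv_trace <- c(gcv_trace, best$gcv)
    }
  }
  # one local refinement pass (half-decade steps around the coarse optimum)
  steps <- 10^c(-0.5, 0, 0.5)
  centre <- best$lam
  for (lf in centre[1] * steps) for (ld in centre[2] * steps) {
    for (l0 in centre[3] * steps) for (l1 in centre[4] * steps) {
      cand <- eval_cand(lf, ld, l0, l1)
      if (better(cand, best)) best <- cand
      gcv_trace <- c(gcv_trace, best$gcv)
    }
  }
  lam <- best$lam
  fit <- best$fit
  rc <- best$rc

  # fitted decomposition over all observations
  K1 <- ctx$K
  g_vis <- fit$bf[1:K1] + fit$bf[K1 + 1:K1]
  g_inv <- fit$bf[1:K1]
  fixed_fit <- rand_fit <- resid <- vector("list", ctx$n_subj)
  for (i in seq_len(ctx$n_subj)) {
    Ti <- ctx$Tlen[i]
    g_i <- if (ctx$vis[i]) g_vis else g_inv
    fx <- ctx$U1[seq_len(Ti), , drop = FALSE] %*% g_i
    rn <- cbind(1, ctx$Ug[seq_len(Ti), K1 + 1]) %*% fit$b[, i]
    fixed_fit[[i]] <- drop(fx)
    rand_fit[[i]] <- drop(rn)
    resid[[i]] <- ctx$y[[i]] - fixed_fit[[i]] - rand_fit[[i]]
  }
  vf <- var(unlist(fixed_fit))
  vr <- var(unlist(rand_fit))
  ve <- var(unlist(resid))
  marginal_r2 <- vf / (vf + vr + ve)
  conditional_r2 <- (vf + vr) / (vf + vr + ve)

  curve_inv <- drop(ctx$U1 %*% g_inv)
  curve_vis <- drop(ctx$U1 %*% g_vis)

  structure(list(
    K = K1, lambdas = setNames(lam, c("f", "diff", "ridge_b0", "ridge_b1")),
    grid = ctx$grid,
    curve_invisible = curve_inv, curve_visible = curve_vis,
    difference_curve = curve_vis - curve_inv,
    linear_offset = fit$bf[K1 + 1],
    edf_f = fit$edf_f, edf_diff = fit$edf_diff,
    edf_total = fit$edf_total,
    random_effect_sd = c(intercept = sd(fit$b[1, ]), slope = sd(fit$b[2, ])),
    sigma2 = fit$rss / max(1, ctx$n_obs - fit$edf_total),
    marginal_r2 = marginal_r2, conditional_r2 = conditional_r2,
    rss = fit$rss, prss = fit$prss, gcv = best$gcv, gcv_trace = gcv_trace,
    n_obs = ctx$n_obs, n_subjects = ctx$n_subj,
    n_visible = sum(ctx$vis), n_invisible = sum(!ctx$vis),
    coefficients = fit$bf, random_effects = fit$b,
    ctx = ctx, rc = rc),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("penalized B-spline mixed trend model\n")
  cat(sprintf("  %d obs, %d subjects (%d visible / %d invisible), K = %d\n",
              x$n_obs, x$n_subjects, x$n_visible, x$n_invisible, x$K))
  cat(sprintf("  edf: common smooth %.2f, difference smooth %.2f\n",
              x$edf_f, x$edf_diff))
  cat(sprintf("  linear condition offset (visible - invisible): %.4f\n",
              x$linear_offset))
  cat(sprintf("  marginal R2 = %.4f, conditional R2 = %.4f\n",
              x$marginal_r2, x$conditional_r2))
  invisible(x)
}

#' @export
summary.trend_fit <- function(object, ...) {
  out <- object[c("K", "lambdas", "edf_f", "edf_diff", "edf_total",
                  "linear_offset", "marginal_r2", "conditional_r2",
                  "random_effect_sd", "sigma2", "n_obs", "n_subjects")]
  class(out) <- "summary.trend_fit"
  out
}

#' @export
print.summary.trend_fit <- function(x, ...) {
  str(x, give.attr = FALSE)
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) object$coefficients

#' Predicted condition trend curves
#'
#' @param object a [fit_trend_model()] fit.
#' @param newdata optional data frame with columns `position` and
#'   `condition`; defaults to both conditions over the fitted grid.
#' @param se whether to attach approximate pointwise standard errors
#'   (sandwich form, fixed-effects part).
#' @param ... unused.
#' @return data frame `position`, `condition`, `fit` (and `se`).
#' @export
predict.trend_fit <- function(object, newdata = NULL, se = FALSE, ...) {
  ctx <- object$ctx
  if (is.null(newdata)) {
    newdata <- data.frame(
      position = rep(ctx$grid, 2),
      condition = rep(c("invisible", "visible"), each = length(ctx$grid)))
  }
  u <- (newdata$position - ctx$grid[1]) /
    (ctx$grid[length(ctx$grid)] - ctx$grid[1])
  if (any(u < -1e-9 | u > 1 + 1e-9)) {
    stop_validation("positions outside the fitted grid")
  }
  B <- bspline_basis(pmin(1, pmax(0, u)), object$K)
  Zc <- qr.Q(qr(matrix(colSums(bspline_basis(ctx$u, object$K)), ncol = 1)),
             complete = TRUE)[, -1, drop = FALSE]
  U1 <- cbind(1, B %*% Zc)
  visflag <- newdata$condition == "visible"
  Xrow <- cbind(U1, U1 * visflag)
  fitv <- drop(Xrow %*% object$coefficients)
  out <- data.frame(position = newdata$position,
                    condition = newdata$condition, fit = fitv)
  if (se) {
    f <- solve_trend(ctx, object$rc, object$lambdas[1], object$lambdas[2],
                     ctx$vis, "full")
    Vff <- object$sigma2 * solve(f$Smat,
        t(solve(f$Smat, (f$FF - 2 * f$W + f$GN)[f$keep, f$keep])))
    out$se <- sqrt(pmax(0, rowSums((Xrow[, f$keep, drop = FALSE] %*% Vff) *
                                   Xrow[, f$keep, drop = FALSE])))
  }
  out
}

#' @export
plot.trend_fit <- function(x, ...) {
  graphics::plot(x$grid, x$curve_invisible, type = "l", col = "firebrick",
                 ylim = range(c(x$curve_invisible, x$curve_visible)),
                 xlab = "window end index", ylab = "normalized complexity",
                 main = "fitted condition trends", ...)
  graphics::lines(x$grid, x$curve_visible, col = "steelblue")
  graphics::legend("topright", legend = c("invisible", "visible"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
fitted.trend_fit <- function(object, ...) {
  ctx <- object$ctx
  K1 <- object$K
  g_vis <- object$coefficients[1:K1] + object$coefficients[K1 + 1:K1]
  g_inv <- object$coefficients[1:K1]
  unlist(lapply(seq_len(ctx$n_subj), function(i) {
    Ti <- ctx$Tlen[i]
    g_i <- if (ctx$vis[i]) g_vis else g_inv
    drop(ctx$U1[seq_len(Ti), , drop = FALSE] %*% g_i) +
      drop(cbind(1, ctx$Ug[seq_len(Ti), K1 + 1]) %*% object$random_effects[, i])
  }))
}

#' @export
residuals.trend_fit <- function(object, ...) {
  unlist(object$ctx$y) - fitted(object)
}

#' Permutation test of the condition difference
#'
#' Tests whether the visible and invisible trend curves differ, by
#' permuting condition labels at the subject level (the design is
#' between-subject).  To keep the observed labelling exchangeable with its
#' permutations, the smoothing and ridge parameters are re-estimated by
#' GCV under the null model (common smooth and subject effects only, no
#' condition terms) and then held fixed for the observed data and every
#' permutation; the difference smooth inherits the common smooth's
#' penalty.  The test statistic is the penalized-RSS reduction
#' attributable to the condition terms; three variants are reported: the
#' joint condition effect (difference smooth + linear offset), the
#' difference smooth alone, and the linear offset alone.  p-values are
#' `(1 + #permuted >= observed) / (B + 1)`.
#'
#' @param fit a [fit_trend_model()] object.
#' @param B number of permutations (>= 99).
#' @param seed optional RNG seed.
#' @return object of class `trend_permutation` with fields `p_condition`,
#'   `p_smooth_difference`, `p_linear_offset`, observed statistics and the
#'   permutation distributions.
#' @export
permutation_test_difference <- function(fit, B = 199L, seed = NULL) {
  stopifnot(inherits(fit, "trend_fit"))
  B <- as.integer(B)
  if (B < 99L) stop_validation("B must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  ctx <- fit$ctx

  # Null-model GCV over the fit's candidate penalties.  The ridge grids
  # are floored at the half-shrinkage scale (penalty ~ column sum of
  # squares): condition assignment is constant within subject, so fully
  # flexible subject intercepts would absorb the very between-group
  # signal the test is after.  All choices depend on the profiles only,
  # never on the labels, which keeps the permutation exchangeable.
  Tbar <- mean(ctx$Tlen)
  r0_min <- Tbar
  r1_min <- sum(ctx$Ug[seq_len(ceiling(Tbar)), ctx$K + 1]^2)
  best <- NULL
  for (lf0 in unique(c(fit$lambdas[["f"]], 10^seq(-2, 6, by = 2)))) {
    for (l0 in r0_min * c(1, 10, 100)) {
      for (l1 in r1_min * c(1, 10, 100)) {
        rc0 <- ridge_cache(ctx, l0, l1)
        f0 <- solve_trend(ctx, rc0, lf0, lf0, ctx$vis, "none")
        gcv <- ctx$n_obs * f0$rss / (ctx$n_obs - f0$edf_total)^2
        if (is.null(best) || gcv < best$gcv) {
          best <- list(gcv = gcv, lf = lf0, rc = rc0)
        }
      }
    }
  }
  rc <- best$rc
  lf <- best$lf
  ld <- best$lf

  stat <- function(vis) {
    full <- solve_trend(ctx, rc, lf, ld, vis, "full", light = TRUE)$prss
    none <- solve_trend(ctx, rc, lf, ld, vis, "none", light = TRUE)$prss
    no_off <- solve_trend(ctx, rc, lf, ld, vis, "no_offset",
                          light = TRUE)$prss
    no_diff <- solve_trend(ctx, rc, lf, ld, vis, "no_diff",
                           light = TRUE)$prss
    c(condition = none - full, smooth = no_diff - full,
      offset = no_off - full)
  }
  obs <- stat(ctx$vis)
  perm <- matrix(NA_real_, B, 3)
  for (b in seq_len(B)) {
    perm[b, ] <- stat(sample(ctx$vis))
  }
  pvals <- (1 + colSums(sweep(perm, 2, obs, `>=`))) / (B + 1)
  structure(list(p_condition = pvals[[1]], p_smooth_difference = pvals[[2]],
                 p_linear_offset = pvals[[3]], observed = obs,
                 permuted = perm, B = B),
            class = "trend_permutation")
}

#' @export
print.trend_permutation <- function(x, ...) {
  cat(sprintf("subject-level permutation test (B = %d)\n", x$B))
  cat(sprintf("  joint condition effect: stat = %.4g, p = %.4f\n",
              x$observed[[1]], x$p_condition))
  cat(sprintf("  difference smooth:      stat = %.4g, p = %.4f\n",
              x$observed[[2]], x$p_smooth_difference))
  cat(sprintf("  linear offset:          stat = %.4g, p = %.4f\n",
              x$observed[[3]], x$p_linear_offset))
  invisible(x)
}

#' Export Fig-3-style fitted trend curves
#'
#' @param fit a [fit_trend_model()] object.
#' @param path output CSV (columns `position`, `condition`, `fit`,
#'   `lower`, `upper`; 95% pointwise band from the approximate fixed-part
#'   covariance).
#' @export
write_trend_curves_csv <- function(fit, path) {
  pr <- predict(fit, se = TRUE)
  pr$lower <- pr$fit - 1.96 * pr$se
  pr$upper <- pr$fit + 1.96 * pr$se
  utils::write.csv(pr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
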