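test_that("intercept-only fit averages each outcome; proportional residuals give r = 1", {
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  Y <- cbind(y1 = c(1, 2, 3), y2 = c(2, 4, 6))
  fit <- fit_mvreg(X, Y)
  expect_equal(unname(coef(fit)), matrix(c(2, 4), 1))
  expect_equal(residual_correlation(fit), 1)
})

test_that("estimates and standard errors match the brute-force normal equations", {
  toy <- toy_fit_data()
  fit <- fit_mvreg(toy$X, toy$Y)
  # independent oracle: explicit normal-equation solve and Kronecker covariance
  XtXi <- solve(t(toy$X) %*% toy$X)
  B <- XtXi %*% t(toy$X) %*% toy$Y
  expect_equal(unname(coef(fit)), unname(B), tolerance = 1e-10)
  E <- toy$Y - toy$X %*% B
  S <- t(E) %*% E / (nrow(toy$X) - ncol(toy$X))
  expect_equal(unname(fit$sigma), unname(S), tolerance = 1e-10)
  V <- kronecker(S, XtXi)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-10)
  sm <- summary(fit)
  expect_equal(sm$coefficients$se, sqrt(diag(V)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("weighted fits match a brute-force WLS oracle and keep invariances", {
  set.seed(13)
  n <- 40
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  Y <- cbind(s = 120 + X[, 2] + rnorm(n), d = 80 + X[, 3] + rnorm(n))
  w <- runif(n, 0.5, 2)
  fit <- fit_mvreg(X, Y, weights = w)
  wn <- w / mean(w)
  B <- solve(t(X) %*% (wn * X)) %*% t(X) %*% (wn * Y)
  expect_equal(unname(coef(fit)), unname(B), tolerance = 1e-10)
  # constant weights reproduce the unweighted fit exactly
  f0 <- fit_mvreg(X, Y)
  f2 <- fit_mvreg(X, Y, weights = rep(2.7, n))
  expect_equal(coef(f2), coef(f0), tolerance = 1e-12)
  expect_equal(f2$vcov, f0$vcov, tolerance = 1e-12)
  # residual covariance is invariant to row order
  idx <- sample(n)
  f3 <- fit_mvreg(X[idx, ], Y[idx, ], weights = w[idx])
  expect_equal(f3$sigma, fit$sigma, tolerance = 1e-10)
})

test_that("rank deficiency and insufficient data raise named errors", {
  X <- cbind("(Intercept)" = rep(1, 6), a = 1:6, dup = 1:6)
  Y <- cbind(rnorm(6), rnorm(6))
  expect_error(fit_mvreg(X, Y), "dup")
  expect_error(fit_mvreg(X[1:3, ], Y[1:3, ]), "insufficient data")
})

test_that("cluster-robust covariance with singleton clusters equals the HC0 sandwich", {
  toy <- toy_fit_data()
  fit <- fit_mvreg(toy$X, toy$Y)
  Vr <- coef_covariance(fit, "cluster_robust", clusters = as.character(1:6),
                        small_sample = FALSE)
  # direct sandwich oracle
  E <- toy$Y - toy$X %*% solve(t(toy$X) %*% toy$X) %*% t(toy$X) %*% toy$Y
  U <- cbind(toy$X * E[, 1], toy$X * E[, 2])
  A <- kronecker(diag(2), solve(t(toy$X) %*% toy$X))
  expect_equal(unname(Vr), unname(A %*% crossprod(U) %*% A), tolerance = 1e-10)
  expect_error(coef_covariance(fit, "cluster_robust", clusters = rep("c1", 6)),
               "at least 2 clusters")
  expect_error(coef_covariance(fit, "cluster_robust"), "requires cluster labels")
})

test_that("iid and cluster-robust standard errors agree under independent errors", {
  reps <- 200
  rat <- matrix(NA_real_, reps, 2)
  for (s in seq_len(reps)) {
    cohort <- gen_small(150, seed = 20000L + s)
    cohort$psu <- rep(1:15, each = 10)
    enc <- encode_model(cohort, small_spec())
    fit <- fit_mvreg(enc$X, enc$Y)
    Vr <- coef_covariance(fit, "cluster_robust", clusters = cohort$psu)
    rat[s, ] <- sqrt(c(Vr[2, 2] / fit$vcov[2, 2], Vr[5, 5] / fit$vcov[5, 5]))
  }
  expect_lt(abs(mean(rat[, 1]) - 1), 0.1)
  expect_lt(abs(mean(rat[, 2]) - 1), 0.1)
})

test_that("summary reproduces t-quantile confidence bounds and marks degeneracy", {
  toy <- toy_fit_data()
  fit <- fit_mvreg(toy$X, toy$Y)
  sm <- summary(fit)$coefficients
  q <- qt(0.975, fit$df_residual)
  expect_equal(sm$ci_low, sm$estimate - q * sm$se, tolerance = 1e-12)
  expect_equal(sm$ci_high, sm$estimate + q * sm$se, tolerance = 1e-12)
  expect_true(all(sm$ci_low <= sm$estimate & sm$estimate <= sm$ci_high))
  # a noise-free fit has zero SEs, degenerate CIs, p = 0, and warns
  X <- cbind("(Intercept)" = 1, x = c(1, 2, 3, 4))
  Y0 <- cbind(s = 2 + 3 * X[, 2], d = 1 + 0.5 * X[, 2])
  f0 <- fit_mvreg(X, Y0)
  expect_warning(sm0 <- summary(f0), "degenerate")
  expect_true(all(sm0$coefficients$se == 0))
  expect_true(all(sm0$coefficients$p_value == 0))
  expect_equal(sm0$coefficients$ci_low, sm0$coefficients$estimate)
})

test_that("parameter recovery: standardized bias small across all coefficients", {
  reps <- 200
  truth <- small_beta()
  est <- array(NA_real_, c(reps, 3, 2))
  for (s in seq_len(reps)) {
    cohort <- gen_small(300, seed = 40000L + s)
    est[s, , ] <- coef(fit_mvreg(encode_model(cohort, small_spec())))
  }
  bias <- apply(est, c(2, 3), mean) - truth
  mcse <- apply(est, c(2, 3), sd) / sqrt(reps)
  # joint bound over the 6 cells (per-cell 2-SE checks would fail by chance)
  expect_lt(max(abs(bias / mcse)), 3.5)
})

test_that("nominal 95% confidence intervals cover at the nominal rate", {
  reps <- 500
  truth <- small_beta()["grp[b]", "sbp"]
  cover <- logical(reps)
  for (s in seq_len(reps)) {
    cohort <- gen_small(200, seed = 60000L + s)
    sm <- summary(fit_mvreg(encode_model(cohort, small_spec())))$coefficients
    row <- sm[sm$term == "grp[b]" & sm$outcome == "sbp", ]
    cover[s] <- row$ci_low <= truth && truth <= row$ci_high
  }
  # 99% binomial band around 0.95 at 500 replicates
  expect_lt(abs(mean(cover) - 0.95), 2.58 * sqrt(0.05 * 0.95 / reps))
})
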