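test_that("joint F test matches the brute-force quadratic form", {
  cohort <- gen_small(80, seed = 2L)
  fit <- fit_mvreg(encode_model(cohort, small_spec()))
  jf <- joint_f_test(fit)
  # oracle: c'V^-1 c / q expanded by hand from the stacked coefficients
  b <- as.vector(coef(fit))[c(2, 3, 5, 6)]
  V <- fit$vcov[c(2, 3, 5, 6), c(2, 3, 5, 6)]
  stat <- drop(t(b) %*% solve(V) %*% b) / 4
  expect_equal(jf$statistic, stat, tolerance = 1e-10)
  expect_identical(jf$df1, 4L)
  expect_identical(jf$df2, fit$df_residual)
  expect_equal(jf$p_value, pf(stat, 4, fit$df_residual, lower.tail = FALSE))
  # intercept-only fit cannot be tested
  f0 <- fit_mvreg(matrix(1, 5, 1, dimnames = list(NULL, "(Intercept)")),
                  cbind(rnorm(5), rnorm(5)))
  expect_error(joint_f_test(f0), "non-intercept")
})

test_that("joint F p-values are uniform under the global null", {
  reps <- 500
  beta0 <- small_beta(age = c(0, 0), grp = c(0, 0))
  pv <- vapply(seq_len(reps), function(s) {
    cohort <- gen_small(60, seed = 80000L + s, beta = beta0)
    joint_f_test(fit_mvreg(encode_model(cohort, small_spec())))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.001)
})

test_that("cross-equation test equals the squared t of the difference contrast", {
  for (s in 1:10) {
    cohort <- gen_small(70, seed = 300L + s)
    fit <- fit_mvreg(encode_model(cohort, small_spec()))
    ct <- cross_equation_test(fit, "age")
    # oracle: contrast variance expanded from the Kronecker covariance
    p <- fit$p
    d <- coef(fit)["age", 1] - coef(fit)["age", 2]
    vd <- fit$vcov[2, 2] + fit$vcov[p + 2, p + 2] - 2 * fit$vcov[2, p + 2]
    expect_equal(ct$statistic, d^2 / vd, tolerance = 1e-10)
    expect_equal(ct$statistic, (d / sqrt(vd))^2, tolerance = 1e-8)
    expect_identical(ct$df1, 1L)
  }
  # chi-square flavour agrees on the statistic
  cohort <- gen_small(70, seed = 311L)
  fit <- fit_mvreg(encode_model(cohort, small_spec()))
  expect_equal(cross_equation_test(fit, "age", statistic = "chisq")$statistic,
               cross_equation_test(fit, "age")$statistic)
  expect_error(cross_equation_test(fit, "nosuch"), "not found")
})

test_that("a term with identical estimated effects yields F = 0, p = 1", {
  # force equality: duplicate one outcome so both equations are identical
  set.seed(5)
  X <- cbind("(Intercept)" = 1, x = rnorm(20))
  y <- 120 + 2 * X[, "x"] + rnorm(20)
  fit <- fit_mvreg(X, cbind(a = y, b = y))
  expect_error(cross_equation_test(fit, "x"), "singular")
  # non-degenerate equality: shift the second equation so its estimates
  # match the first exactly, then the contrast must vanish
  b_raw <- y + rnorm(20, sd = 3)
  fit2 <- fit_mvreg(X, cbind(a = y, b = b_raw))
  fit3 <- fit_mvreg(X, cbind(a = y,
                             b = b_raw - drop(X %*% (coef(fit2)[, 2] - coef(fit2)[, 1]))))
  ct <- cross_equation_test(fit3, "x")
  expect_lt(ct$statistic, 1e-10)
  expect_gt(ct$p_value, 1 - 1e-6)
})

test_that("Breusch-Pagan statistic is n r^2 with exact special cases", {
  E <- exact_corr_pairs(100, 0.5, seed = 7)
  fit <- fit_mvreg(matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)")),
                   E + cbind(rep(120, 100), rep(80, 100)))
  bp <- breusch_pagan_independence(fit)
  expect_equal(bp$residual_correlation, 0.5, tolerance = 1e-12)
  expect_equal(bp$statistic, 25, tolerance = 1e-9)
  expect_equal(bp$p_value, pchisq(25, 1, lower.tail = FALSE))
  # r = 0: statistic 0, p = 1
  E0 <- exact_corr_pairs(50, 0, seed = 8)
  f0 <- fit_mvreg(matrix(1, 50, 1, dimnames = list(NULL, "(Intercept)")),
                  E0 + cbind(rep(120, 50), rep(80, 50)))
  bp0 <- breusch_pagan_independence(f0)
  expect_lt(bp0$statistic, 1e-20)
  expect_equal(bp0$p_value, 1)
})

test_that("Breusch-Pagan is invariant to affine rescaling of either outcome", {
  cohort <- gen_small(200, seed = 12L)
  enc <- encode_model(cohort, small_spec())
  f1 <- fit_mvreg(enc$X, enc$Y)
  Y2 <- enc$Y
  Y2[, 1] <- 3.7 * Y2[, 1] - 40
  Y2[, 2] <- 0.2 * Y2[, 2] + 11
  f2 <- fit_mvreg(enc$X, Y2)
  expect_equal(breusch_pagan_independence(f2)$statistic,
               breusch_pagan_independence(f1)$statistic, tolerance = 1e-10)
})

test_that("the bivariate Shapiro-Wilk transform matches an independent reference", {
  set.seed(17)
  n <- 500
  # bivariate exponential residuals: clearly non-normal
  E <- cbind(rexp(n), rexp(n))
  res <- multivariate_shapiro(E)
  expect_lt(res$p_value, 0.01)
  # independently coded reference: centre, inverse upper Cholesky, univariate SW
  Ec <- sweep(E, 2, colMeans(E))
  Z <- Ec %*% solve(chol(crossprod(Ec) / (n - 1)))
  ref <- shapiro.test(as.vector(Z))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-6)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("the bivariate Shapiro-Wilk test is calibrated under normality", {
  pv <- vapply(1:100, function(s) {
    set.seed(90000 + s)
    E <- matrix(rnorm(1000), 500, 2)
    multivariate_shapiro(E)$p_value
  }, numeric(1))
  expect_gte(mean(pv > 0.05), 0.90)
})

test_that("Shapiro-Wilk preconditions and subsampling behave", {
  expect_error(multivariate_shapiro(matrix(rnorm(4), 2, 2)), "at least 3")
  perfect <- cbind(1:10, 2 * (1:10))  # singular covariance
  expect_error(multivariate_shapiro(perfect), "singular")
  big <- matrix(rnorm(12000), 6000, 2)
  res <- multivariate_shapiro(big, max_n = 100, seed = 4)
  expect_identical(res$n_used, 100L)
  res2 <- multivariate_shapiro(big, max_n = 100, seed = 4)
  expect_identical(res$statistic, res2$statistic)  # fixed-seed subsample
})

test_that("Pearson correlation test handles exact and hand-computed cases", {
  y1 <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  expect_equal(pearson_correlation_test(y1, 2 * y1)$estimate, 1)
  # orthogonal after centring: r = 0, p = 1
  u <- c(-1, 1, -1, 1); v <- c(-1, -1, 1, 1)
  res0 <- pearson_correlation_test(u, v)
  expect_equal(res0$estimate, 0)
  expect_equal(res0$p_value, 1)
  # ten-point pair against the hand-computed covariance ratio
  y2 <- c(2.1, 2.9, 2.4, 4.8, 4.1, 6.5, 6.2, 9.3, 8.1, 9.9)
  res <- pearson_correlation_test(y1, y2)
  r_hand <- sum((y1 - mean(y1)) * (y2 - mean(y2))) /
    sqrt(sum((y1 - mean(y1))^2) * sum((y2 - mean(y2))^2))
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  expect_equal(res$df1, 8)
  expect_error(pearson_correlation_test(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_correlation_test(1:2, 1:2), "n >= 3")
})
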