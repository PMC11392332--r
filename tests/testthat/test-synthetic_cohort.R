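test_that("schema validation rejects bad probability vectors and references", {
  expect_error(categorical_variable("x", c("a", "b"), c(0.5, -0.1)), "probability")
  expect_error(categorical_variable("x", c("a", "b"), c(0.5, NA)), "probability")
  expect_error(categorical_variable("x", c("a", "b"), c(1, 1), ref = "c"), "reference")
  expect_error(categorical_variable("x", c("a", "a"), c(0.5, 0.5)), "duplicated")
  # counts are accepted and normalised
  v <- categorical_variable("x", c("a", "b"), c(30, 70))
  expect_equal(sum(v$probs), 1)
})

test_that("sampled covariate marginals converge to the schema marginals", {
  big <- big_covariates()
  share_central <- mean(big$region == "central")
  expect_lt(abs(share_central - 0.355), 0.005)
  expect_lt(abs(mean(big$sex == "female") - 0.597), 0.005)
  # age calibrated to median 32, IQR 25-44, bounded to 18-69
  expect_true(all(big$age >= 18 & big$age <= 69))
  expect_lt(abs(stats::median(big$age) - 32), 1.5)
  qs <- stats::quantile(big$age, c(0.25, 0.75))
  expect_lt(abs(qs[[1]] - 25), 1.5)
  expect_lt(abs(qs[[2]] - 44), 2.5)
})

test_that("region counts pass an exact multinomial goodness-of-fit check", {
  cov <- sample_covariates(steps_schema(), 5e4, seed = 11L)
  counts <- table(cov$region)
  gof <- stats::chisq.test(counts, p = c(0.355, 0.264, 0.214, 0.167))
  expect_gt(gof$p.value, 0.001)
})

test_that("n = 0 yields an empty table with the full column set", {
  empty <- sample_covariates(steps_schema(), 0)
  expect_identical(nrow(empty), 0L)
  expect_setequal(names(empty), names(steps_schema()))
  expect_s3_class(empty$region, "factor")
})

test_that("with zero residual noise the outcomes equal the linear predictor", {
  cohort <- data.frame(
    age = c(0, 10, 50),
    grp = factor(c("a", "b", "b"), levels = c("a", "b")))
  beta <- small_beta()
  out <- sample_blood_pressure(cohort, beta, residual_covariance(0, 0, 0), seed = 3L)
  # hand-computed linear predictors
  expect_equal(out$sbp, c(122, 122 + 10 * 0.22 + 4, 122 + 50 * 0.22 + 4))
  expect_equal(out$dbp, c(78, 78 + 10 * 0.24 + 2.5, 78 + 50 * 0.24 + 2.5))
})

test_that("a reference individual's mean SBP converges to the generating constant", {
  n <- 20000L
  sch <- steps_schema()
  ref_cohort <- as.data.frame(lapply(sch, function(v) {
    if (v$kind == "continuous") rep(0, n)
    else factor(rep(v$ref, n), levels = v$levels)
  }))
  out <- sample_blood_pressure(ref_cohort, seed = 5L)
  expect_lt(abs(mean(out$sbp) - 122.98), 4 * 16 / sqrt(n))
  expect_lt(abs(mean(out$dbp) - 78.84), 4 * 10 / sqrt(n))
})

test_that("generated outcomes reproduce the configured residual correlation", {
  beta0 <- matrix(0, 2, 2, dimnames = list(c("(Intercept)", "age"), c("sbp", "dbp")))
  cohort <- data.frame(age = rep(1, 1e5))
  out <- sample_blood_pressure(cohort, beta0, residual_covariance(16, 10, 0.7307),
                               seed = 21L)
  expect_lt(abs(stats::cor(out$sbp, out$dbp) - 0.7307), 0.01)
})

test_that("unresolvable coefficient labels raise a configuration error", {
  cohort <- data.frame(age = 1:5)
  beta <- matrix(0, 2, 2, dimnames = list(c("(Intercept)", "nosuch"), c("s", "d")))
  expect_error(sample_blood_pressure(cohort, beta), "not resolvable")
  beta2 <- matrix(0, 2, 2, dimnames = list(c("(Intercept)", "foo[bar]"), c("s", "d")))
  expect_error(sample_blood_pressure(cohort, beta2), "missing cohort column")
})

test_that("degenerate survey design leaves the weighted fit equal to unweighted", {
  cohort <- gen_small(400, seed = 31L)
  cohort <- attach_survey_design(cohort, survey_design(1L, 1L), seed = 31L)
  expect_true(all(cohort$weight == 1))
  enc <- encode_model(cohort, small_spec())
  f0 <- fit_mvreg(enc$X, enc$Y)
  f1 <- fit_mvreg(enc$X, enc$Y, weights = cohort$weight)
  expect_equal(coef(f1), coef(f0), tolerance = 1e-12)
  expect_equal(f1$sigma, f0$sigma, tolerance = 1e-12)
})

test_that("non-positive explicit weights are rejected", {
  expect_error(survey_design(weights = c(1, 0, 2)), "strictly positive")
  expect_error(survey_design(weights = c(1, -1)), "strictly positive")
})

test_that("a PSU random intercept inflates the cluster-robust intercept SE", {
  reps <- 100
  spec <- small_spec()
  ratio <- vapply(seq_len(reps), function(s) {
    cohort <- gen_small(300, seed = 5000L + s)
    cohort <- attach_survey_design(cohort, survey_design(1L, 15L, psu_sd = 6),
                                   seed = 6000L + s)
    enc <- encode_model(cohort, spec)
    fit <- fit_mvreg(enc$X, enc$Y)
    Vr <- coef_covariance(fit, "cluster_robust", clusters = cohort$psu)
    sqrt(Vr[1, 1] / fit$vcov[1, 1])
  }, numeric(1))
  expect_gt(mean(ratio), 1)
})

test_that("generation is deterministic: same seed gives byte-identical CSV", {
  cfg <- generator_config(n = 250, seed = 77L)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  generate_cohort(cfg, path = f1)
  generate_cohort(cfg, path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("replicate mode stores means that recompute exactly from the replicates", {
  cfg <- generator_config(n = 500, seed = 41L,
                          measurement = measurement_settings(replicates = 3L))
  cohort <- generate_cohort(cfg)
  expect_true(all(c("sbp1", "sbp2", "sbp3", "dbp1", "dbp2", "dbp3") %in% names(cohort)))
  expect_equal(cohort$sbp, (cohort$sbp1 + cohort$sbp2 + cohort$sbp3) / 3)
  expect_equal(cohort$dbp, (cohort$dbp1 + cohort$dbp2 + cohort$dbp3) / 3)
})

test_that("replicate-mean variance decomposes into person + measurement/3 parts", {
  beta0 <- matrix(0, 1, 2, dimnames = list("(Intercept)", c("sbp", "dbp")))
  cohort <- data.frame(dummy = rep(1, 4e4))
  out <- sample_blood_pressure(cohort, beta0, residual_covariance(16, 10, 0.7307),
                               measurement_settings(3L, sd_sbp = 5, sd_dbp = 4),
                               seed = 55L)
  expect_equal(stats::var(out$sbp), 16^2 + 5^2 / 3, tolerance = 0.05)
  expect_equal(stats::var(out$dbp), 10^2 + 4^2 / 3, tolerance = 0.05)
})

test_that("the medication indicator defaults to all-false and honours its rate", {
  c0 <- generate_cohort(generator_config(n = 100, seed = 1L))
  expect_false(any(c0$on_bp_medication))
  c1 <- generate_cohort(generator_config(n = 5000, seed = 1L, medication_prob = 0.3))
  expect_lt(abs(mean(c1$on_bp_medication) - 0.3), 0.03)
})
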