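# shared fixtures: built in code, no files

# six-row toy design/response used by the brute-force oracles
toy_fit_data <- function() {
  X <- cbind("(Intercept)" = 1, x = c(-2.5, -1, 0, 1.5, 2, 4))
  Y <- cbind(sbp = c(118.2, 121.0, 119.5, 126.3, 124.8, 131.1),
             dbp = c(79.4, 80.2, 78.9, 84.1, 82.6, 88.0))
  list(X = X, Y = Y)
}

# a small three-term cohort generator for fast simulation loops
small_beta <- function(age = c(0.22, 0.24), grp = c(4, 2.5), int = c(122, 78)) {
  matrix(c(int[1], age[1], grp[1], int[2], age[2], grp[2]), ncol = 2,
         dimnames = list(c("(Intercept)", "age", "grp[b]"), c("sbp", "dbp")))
}

small_schema <- function() {
  covariate_schema(
    continuous_variable("age", "lnorm",
                        params = list(meanlog = log(32), sdlog = 0.4),
                        lower = 18, upper = 69),
    categorical_variable("grp", c("a", "b"), c(0.6, 0.4)))
}

small_spec <- function() {
  model_spec(terms = list(age = "continuous", grp = list(ref = "a")))
}

gen_small <- function(n, seed, beta = small_beta(), rho = 0.7307,
                      sd_sbp = 16, sd_dbp = 10) {
  cohort <- sample_covariates(small_schema(), n, seed = seed)
  sample_blood_pressure(cohort, beta,
                        residual_covariance(sd_sbp, sd_dbp, rho),
                        seed = seed + 10000L)
}

# residual pairs with an exact sample correlation r (zero mean columns)
exact_corr_pairs <- function(n, r, seed = 1) {
  set.seed(seed)
  u <- stats::rnorm(n); v <- stats::rnorm(n)
  u <- u - mean(u)
  v <- stats::residuals(stats::lm(v ~ u))      # orthogonal to u, mean zero
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  cbind(u, r * u + sqrt(1 - r^2) * v)
}

# big covariate-only draw shared by marginal-convergence tests
big_covariates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sample_covariates(steps_schema(), 2e5, seed = 99L)
    cache
  }
})
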