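#' Published joint-model coefficients used as generating truth
#'
#' The default ground-truth coefficient matrix for the synthetic cohort: one
#' row per design column (intercept first, then the 19 predictor columns of
#' the adjusted joint model), one column per outcome equation (SBP, DBP),
#' all in mmHg. Row names use the `variable[level]` label convention of
#' [encode_model()].
#'
#' @return A 20 x 2 numeric matrix with dimnames.
#' @export
#' @examples
#' steps_true_coefficients()["cholesterol[hypercholesterolemic]", ]
steps_true_coefficients <- function() {
  terms <- c(
    "(Intercept)", "age",
    "bmi[underweight]", "bmi[overweight]", "bmi[obese]",
    "glucose[impaired]", "glucose[diabetic]",
    "region[eastern]", "region[northern]", "region[western]",
    "marital[married/cohabiting]", "marital[separated/widowed/divorced]",
    "fruit_daily[yes]",
    "salt[often/sometimes]", "salt[rarely/never]",
    "active[yes]",
    "income[278-2777]", "income[>=2778]",
    "cholesterol[hypercholesterolemic]",
    "central_obesity[obese]")
  sbp <- c(122.98, 0.22, -1.89, 0.38, 4.00, 3.69, 1.95, -2.95, -4.84, -5.26,
           0.94, -0.95, -1.66, 1.41, 1.83, -0.71, -3.24, 2.09, 11.09, 1.98)
  dbp <- c(78.84, 0.24, -0.34, 0.54, 2.53, 0.68, 0.18, 0.27, -0.21, -0.23,
           0.02, -1.45, -0.91, 0.97, 1.27, 0.10, -1.44, 0.79, 6.89, 0.71)
  matrix(c(sbp, dbp), ncol = 2L, dimnames = list(terms, c("sbp", "dbp")))
}

#' Residual covariance specification for the bivariate error
#'
#' The generator draws person-level errors \eqn{(\epsilon_1, \epsilon_2)}
#' from a bivariate normal with standard deviations `sd_sbp`, `sd_dbp` and
#' correlation `rho`. The default correlation is the published residual
#' correlation estimate (0.7307); the residual standard deviations are not
#' published, so typical adult population values (16 and 10 mmHg) are used.
#'
#' @param sd_sbp,sd_dbp Residual standard deviations in mmHg (>= 0).
#' @param rho Residual correlation, |rho| < 1 (ignored when either sd is 0).
#' @return An object of class `residual_covariance`.
#' @export
residual_covariance <- function(sd_sbp = 16, sd_dbp = 10, rho = 0.7307) {
  stopifnot(is_scalar_number(sd_sbp), sd_sbp >= 0,
            is_scalar_number(sd_dbp), sd_dbp >= 0,
            is_scalar_number(rho))
  if (abs(rho) >= 1 && sd_sbp > 0 && sd_dbp > 0)
    stop("|rho| must be < 1 when both standard deviations are positive", call. = FALSE)
  structure(list(sd_sbp = sd_sbp, sd_dbp = sd_dbp, rho = rho),
            class = "residual_covariance")
}

as_sigma_matrix <- function(sigma) {
  s1 <- sigma$sd_sbp; s2 <- sigma$sd_dbp; r <- sigma$rho
  matrix(c(s1^2, r * s1 * s2, r * s1 * s2, s2^2), 2L, 2L)
}

#' Measurement protocol settings
#'
#' The survey took three SBP/DBP readings per participant and analysed their
#' averages. With `replicates = 1` (default) person-level averages are
#' generated directly, so the residual correlation seen downstream equals
#' the configured `rho` exactly. With `replicates = 3` three replicate pairs
#' are emitted (`sbp1..3`, `dbp1..3`) with independent device noise added to
#' each, plus their means in `sbp`/`dbp`.
#'
#' @param replicates 1 or 3.
#' @param sd_sbp,sd_dbp Replicate-level device noise standard deviations in
#'   mmHg (used only when `replicates = 3`); replicate noise is uncorrelated
#'   across the two outcomes.
#' @return An object of class `measurement_settings`.
#' @export
measurement_settings <- function(replicates = 1L, sd_sbp = 5, sd_dbp = 4) {
  replicates <- as.integer(replicates)
  if (!replicates %in% c(1L, 3L)) stop("`replicates` must be 1 or 3", call. = FALSE)
  stopifnot(is_scalar_number(sd_sbp), sd_sbp >= 0, is_scalar_number(sd_dbp), sd_dbp >= 0)
  structure(list(replicates = replicates, sd_sbp = sd_sbp, sd_dbp = sd_dbp),
            class = "measurement_settings")
}

#' Survey design settings
#'
#' Emulates a stratified multi-stage cluster design: rows are assigned to
#' `n_strata` design strata and, within each, to one of `psus_per_stratum`
#' primary sampling units. Weights default to 1 for everyone; a positive
#' `weight_sdlog` draws log-normal weights normalised to mean 1. A positive
#' `psu_sd` adds an independent normal PSU-level shift (per outcome) to the
#' generated blood pressures, inducing within-cluster correlation.
#'
#' @param n_strata Number of design strata.
#' @param psus_per_stratum PSUs per stratum.
#' @param weight_sdlog Log-scale SD of the weight distribution (0 = equal).
#' @param psu_sd PSU random-intercept SD in mmHg (0 = none).
#' @param weights Optional explicit per-row weights overriding the
#'   distribution; must be strictly positive.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(n_strata = 10L, psus_per_stratum = 20L,
                          weight_sdlog = 0, psu_sd = 0, weights = NULL) {
  stopifnot(is_count(n_strata), n_strata >= 1,
            is_count(psus_per_stratum), psus_per_stratum >= 1,
            is_scalar_number(weight_sdlog), weight_sdlog >= 0,
            is_scalar_number(psu_sd), psu_sd >= 0)
  if (!is.null(weights)) {
    if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights <= 0))
      stop("explicit weights must be finite and strictly positive", call. = FALSE)
  }
  structure(list(n_strata = as.integer(n_strata),
                 psus_per_stratum = as.integer(psus_per_stratum),
                 weight_sdlog = weight_sdlog, psu_sd = psu_sd, weights = weights),
            class = "survey_design")
}

resolve_beta_design <- function(cohort, beta) {
  if (!is.matrix(beta) || ncol(beta) != 2L)
    stop("`beta` must be a matrix with two columns (SBP, DBP)", call. = FALSE)
  labs <- rownames(beta)
  if (is.null(labs) || anyDuplicated(labs))
    stop("`beta` needs unique row names labelling the design columns", call. = FALSE)
  n <- nrow(cohort)
  X <- matrix(0, n, length(labs), dimnames = list(NULL, labs))
  for (j in seq_along(labs)) {
    lab <- labs[[j]]
    if (lab == "(Intercept)") { X[, j] <- 1; next }
    m <- regmatches(lab, regexec("^([^\\[]+)\\[(.+)\\]$", lab))[[1L]]
    if (length(m) == 3L) {            # categorical indicator: variable[level]
      var <- m[[2L]]; lev <- m[[3L]]
      if (!var %in% names(cohort))
        stop("term '", lab, "' refers to missing cohort column '", var, "'", call. = FALSE)
      X[, j] <- as.numeric(as.character(cohort[[var]]) == lev)
    } else {                          # continuous column used as-is
      if (!lab %in% names(cohort))
        stop("term '", lab, "' not resolvable from cohort columns", call. = FALSE)
      X[, j] <- as.numeric(cohort[[lab]])
    }
  }
  X
}

#' Add simulated blood-pressure outcomes to a cohort
#'
#' Computes the two linear predictors from `beta` and the cohort covariates
#' and adds a correlated bivariate-normal person-level error with covariance
#' given by `sigma`. In replicate mode, three measurement pairs with
#' additional independent device noise are emitted along with their means.
#'
#' @param cohort Covariate table, e.g. from [sample_covariates()].
#' @param beta Coefficient matrix (rows labelled like
#'   [steps_true_coefficients()]); row names are resolved against cohort
#'   columns.
#' @param sigma A [residual_covariance()].
#' @param measurement A [measurement_settings()].
#' @param seed Optional integer seed.
#' @return The cohort with `sbp`/`dbp` columns added (and `sbp1..3`,
#'   `dbp1..3` in replicate mode).
#' @export
sample_blood_pressure <- function(cohort, beta = steps_true_coefficients(),
                                  sigma = residual_covariance(),
                                  measurement = measurement_settings(),
                                  seed = NULL) {
  stopifnot(is.data.frame(cohort), inherits(sigma, "residual_covariance"),
            inherits(measurement, "measurement_settings"))
  local_seed(seed)
  n <- nrow(cohort)
  X <- resolve_beta_design(cohort, beta)
  eta <- X %*% beta
  S <- as_sigma_matrix(sigma)
  eps <- if (n == 0L) matrix(0, 0L, 2L) else draw_mvn2(n, S)
  person <- eta + eps
  if (measurement$replicates == 3L) {
    for (k in 1:3) {
      cohort[[paste0("sbp", k)]] <- person[, 1L] + stats::rnorm(n, 0, measurement$sd_sbp)
      cohort[[paste0("dbp", k)]] <- person[, 2L] + stats::rnorm(n, 0, measurement$sd_dbp)
    }
    cohort$sbp <- rowMeans(cohort[paste0("sbp", 1:3)])
    cohort$dbp <- rowMeans(cohort[paste0("dbp", 1:3)])
  } else {
    cohort$sbp <- person[, 1L]
    cohort$dbp <- person[, 2L]
  }
  cohort
}

# bivariate normal draw via Cholesky-like construction that degrades
# gracefully when one or both variances are zero
draw_mvn2 <- function(n, S) {
  if (all(S == 0)) return(matrix(0, n, 2L))
  z <- matrix(stats::rnorm(2L * n), n, 2L)
  s1 <- sqrt(S[1L, 1L]); s2 <- sqrt(S[2L, 2L])
  r <- if (s1 > 0 && s2 > 0) S[1L, 2L] / (s1 * s2) else 0
  e1 <- s1 * z[, 1L]
  e2 <- s2 * (r * z[, 1L] + sqrt(1 - r^2) * z[, 2L])
  cbind(e1, e2, deparse.level = 0L)
}

#' Attach survey-design columns to a cohort
#'
#' Adds `stratum`, `psu` (labelled `stratum.psu`) and `weight` columns. If
#' the design declares a positive PSU random-intercept SD and the cohort
#' already carries blood-pressure columns, independent PSU-level shifts are
#' added to them (replicates and means alike), inducing intra-cluster
#' correlation that a cluster-robust variance should pick up.
#'
#' @param cohort Cohort table.
#' @param design A [survey_design()].
#' @param seed Optional integer seed.
#' @return The cohort with design columns added.
#' @export
attach_survey_design <- function(cohort, design = survey_design(), seed = NULL) {
  stopifnot(is.data.frame(cohort), inherits(design, "survey_design"))
  local_seed(seed)
  n <- nrow(cohort)
  stratum <- sample.int(design$n_strata, n, replace = TRUE)
  psu_in <- sample.int(design$psus_per_stratum, n, replace = TRUE)
  cohort$stratum <- stratum
  cohort$psu <- sprintf("%d.%d", stratum, psu_in)
  if (!is.null(design$weights)) {
    if (length(design$weights) != n)
      stop("explicit weights must have one entry per row", call. = FALSE)
    if (any(design$weights <= 0))
      stop("survey weights must be strictly positive", call. = FALSE)
    cohort$weight <- design$weights
  } else if (design$weight_sdlog > 0) {
    w <- stats::rlnorm(n, 0, design$weight_sdlog)
    cohort$weight <- w / mean(w)
  } else {
    cohort$weight <- rep(1, n)
  }
  if (design$psu_sd > 0) {
    ids <- unique(cohort$psu)
    eff_s <- stats::rnorm(length(ids), 0, design$psu_sd)
    eff_d <- stats::rnorm(length(ids), 0, design$psu_sd)
    names(eff_s) <- names(eff_d) <- ids
    bp_cols <- intersect(c("sbp", paste0("sbp", 1:3)), names(cohort))
    for (cl in bp_cols) cohort[[cl]] <- cohort[[cl]] + eff_s[cohort$psu]
    bp_cols <- intersect(c("dbp", paste0("dbp", 1:3)), names(cohort))
    for (cl in bp_cols) cohort[[cl]] <- cohort[[cl]] + eff_d[cohort$psu]
  }
  cohort
}

#' Full generator configuration
#'
#' Bundles all generator settings. Defaults reproduce the structure of the
#' emulated survey: n = 3,646 adults, published covariate marginals,
#' published joint-model coefficients as ground truth, residual correlation
#' 0.7307, replicate noise off, equal weights.
#'
#' @param n Cohort size.
#' @param seed Integer seed driving all generator randomness via named
#'   substreams.
#' @param schema A [covariate_schema()].
#' @param beta True coefficient matrix.
#' @param sigma A [residual_covariance()].
#' @param measurement A [measurement_settings()].
#' @param design A [survey_design()].
#' @param medication_prob Probability a participant is on anti-hypertensive
#'   medication (such rows are excluded by the analysis pipeline); default 0.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 3646L, seed = NULL, schema = steps_schema(),
                             beta = steps_true_coefficients(),
                             sigma = residual_covariance(),
                             measurement = measurement_settings(),
                             design = survey_design(),
                             medication_prob = 0) {
  stopifnot(is_count(n), inherits(schema, "covariate_schema"),
            inherits(sigma, "residual_covariance"),
            inherits(measurement, "measurement_settings"),
            inherits(design, "survey_design"),
            is_scalar_number(medication_prob),
            medication_prob >= 0, medication_prob <= 1)
  structure(list(n = as.integer(n), seed = seed, schema = schema, beta = beta,
                 sigma = sigma, measurement = measurement, design = design,
                 medication_prob = medication_prob),
            class = "generator_config")
}

#' Generate a complete synthetic cohort
#'
#' Composes [sample_covariates()], [sample_blood_pressure()] and
#' [attach_survey_design()] under one seed (split into named substreams) and
#' adds the anti-hypertensive-medication indicator. Optionally writes the
#' cohort as CSV together with a column manifest (see [write_cohort()]).
#'
#' @param config A [generator_config()].
#' @param path Optional CSV output path.
#' @return The cohort `data.frame` (invisibly when `path` is given).
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n = 100, seed = 1))
#' dim(cohort)
generate_cohort <- function(config = generator_config(), path = NULL) {
  stopifnot(inherits(config, "generator_config"))
  cohort <- sample_covariates(config$schema, config$n,
                              seed = substream_seed(config$seed, "covariates"))
  cohort <- sample_blood_pressure(cohort, config$beta, config$sigma,
                                  config$measurement,
                                  seed = substream_seed(config$seed, "blood_pressure"))
  cohort <- attach_survey_design(cohort, config$design,
                                 seed = substream_seed(config$seed, "design"))
  med_seed <- substream_seed(config$seed, "medication")
  local_seed(med_seed)
  cohort$on_bp_medication <-
    if (config$medication_prob > 0)
      stats::runif(config$n) < config$medication_prob
    else rep(FALSE, config$n)
  if (!is.null(path)) {
    write_cohort(cohort, path)
    return(invisible(cohort))
  }
  cohort
}
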