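#' Descriptive summary of a cohort
#'
#' Counts and percentages (1 decimal) per level for every categorical
#' variable, and median/IQR for continuous ones, in schema order.
#'
#' @param cohort Cohort data (non-empty).
#' @param schema A [covariate_schema()] naming the variables to summarise;
#'   defaults to every cohort column that is a factor/character (plus
#'   numeric `age` if present).
#' @return A list of class `bp_descriptives` with elements `categorical`
#'   (data.frame: variable, level, n, pct) and `continuous` (data.frame:
#'   variable, median, q1, q3).
#' @export
describe_cohort <- function(cohort, schema = NULL) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("cannot describe an empty cohort", call. = FALSE)
  if (!is.null(schema)) {
    vars <- names(schema)[names(schema) %in% names(cohort)]
    kinds <- vapply(schema[vars], `[[`, character(1L), "kind")
  } else {
    isfac <- vapply(cohort, function(x) is.factor(x) || is.character(x), logical(1L))
    vars <- names(cohort)[isfac]
    kinds <- rep("categorical", length(vars))
    if ("age" %in% names(cohort) && is.numeric(cohort$age)) {
      vars <- c("age", vars); kinds <- c("continuous", kinds)
    }
    names(kinds) <- vars
  }
  n <- nrow(cohort)
  cat_rows <- list(); cont_rows <- list()
  for (v in vars) {
    if (kinds[[v]] == "categorical") {
      x <- cohort[[v]]
      tab <- table(if (is.factor(x)) x else factor(x))
      cat_rows[[v]] <- data.frame(variable = v, level = names(tab),
                                  n = as.integer(tab),
                                  pct = round(100 * as.integer(tab) / n, 1L),
                                  stringsAsFactors = FALSE)
    } else {
      qs <- stats::quantile(cohort[[v]], c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      cont_rows[[v]] <- data.frame(variable = v, median = qs[[2L]],
                                   q1 = qs[[1L]], q3 = qs[[3L]],
                                   stringsAsFactors = FALSE)
    }
  }
  structure(list(
    n = n,
    categorical = if (length(cat_rows)) do.call(rbind, c(cat_rows, make.row.names = FALSE))
                  else data.frame(),
    continuous = if (length(cont_rows)) do.call(rbind, c(cont_rows, make.row.names = FALSE))
                 else data.frame()),
    class = "bp_descriptives")
}

#' @export
print.bp_descriptives <- function(x, ...) {
  cat("Cohort descriptives (n = ", x$n, ")\n", sep = "")
  if (nrow(x$continuous))
    for (i in seq_len(nrow(x$continuous)))
      cat(sprintf("  %s: median %.1f (IQR %.1f-%.1f)\n", x$continuous$variable[i],
                  x$continuous$median[i], x$continuous$q1[i], x$continuous$q3[i]))
  if (nrow(x$categorical)) print(x$categorical, row.names = FALSE)
  invisible(x)
}

#' Hypertension prevalence under the survey thresholds
#'
#' Classifies each participant hypertensive under three rules: average SBP
#' at or above `sbp_threshold`, average DBP at or above `dbp_threshold`,
#' and either. Boundary values count as hypertensive. Percentages are
#' reported to 1 decimal.
#'
#' @param cohort Cohort with averaged `sbp` and `dbp` columns.
#' @param sbp_threshold,dbp_threshold Thresholds in mmHg (defaults 140/90).
#' @return A list of class `bp_prevalence` with counts (`n`, `n_sbp`,
#'   `n_dbp`, `n_either`, `n_both`) and percentages (`pct_sbp`, `pct_dbp`,
#'   `pct_either`).
#' @export
#' @examples
#' cohort <- data.frame(sbp = c(150, 120, 140), dbp = c(95, 80, 85))
#' prevalence(cohort)
prevalence <- function(cohort, sbp_threshold = 140, dbp_threshold = 90) {
  stopifnot(is.data.frame(cohort))
  if (!all(c("sbp", "dbp") %in% names(cohort)))
    stop("cohort must carry averaged `sbp` and `dbp` columns", call. = FALSE)
  sbp <- cohort$sbp; dbp <- cohort$dbp
  if (anyNA(sbp) || anyNA(dbp))
    stop("missing blood-pressure values; impute or drop before computing prevalence",
         call. = FALSE)
  n <- nrow(cohort)
  hi_s <- sbp >= sbp_threshold
  hi_d <- dbp >= dbp_threshold
  structure(list(
    n = n,
    n_sbp = sum(hi_s), n_dbp = sum(hi_d),
    n_either = sum(hi_s | hi_d), n_both = sum(hi_s & hi_d),
    pct_sbp = round(100 * sum(hi_s) / n, 1L),
    pct_dbp = round(100 * sum(hi_d) / n, 1L),
    pct_either = round(100 * sum(hi_s | hi_d) / n, 1L),
    sbp_threshold = sbp_threshold, dbp_threshold = dbp_threshold),
    class = "bp_prevalence")
}

#' @export
print.bp_prevalence <- function(x, ...) {
  cat(sprintf("Hypertension prevalence (SBP >= %g, DBP >= %g mmHg), n = %d\n",
              x$sbp_threshold, x$dbp_threshold, x$n))
  cat(sprintf("  either rule: %d (%.1f%%)\n", x$n_either, x$pct_either))
  cat(sprintf("  SBP rule:    %d (%.1f%%)\n", x$n_sbp, x$pct_sbp))
  cat(sprintf("  DBP rule:    %d (%.1f%%)\n", x$n_dbp, x$pct_dbp))
  invisible(x)
}

#' Compare separate per-equation fits with the joint fit
#'
#' With identical regressors the joint point estimates coincide with two
#' separate per-equation least-squares fits; standard errors may differ
#' only through the degrees-of-freedom convention. Flags any point-estimate
#' difference above 1e-8.
#'
#' @param separate Coefficient data.frame of the separate fits (columns
#'   term, outcome, estimate, se), e.g. built from two [stats::lm()] fits.
#' @param joint Coefficient data.frame of the joint fit (from
#'   [summary.mvreg_fit()]).
#' @return A data.frame of class `bp_fit_comparison` with per-term/outcome
#'   estimate and SE differences and a `flagged` column.
#' @export
compare_fits <- function(separate, joint) {
  need <- c("term", "outcome", "estimate", "se")
  stopifnot(all(need %in% names(separate)), all(need %in% names(joint)))
  key_s <- paste(separate$term, separate$outcome)
  key_j <- paste(joint$term, joint$outcome)
  if (!setequal(key_s, key_j))
    stop("separate and joint tables cover different terms", call. = FALSE)
  j <- match(key_s, key_j)
  out <- data.frame(term = separate$term, outcome = separate$outcome,
                    estimate_separate = separate$estimate,
                    estimate_joint = joint$estimate[j],
                    estimate_diff = separate$estimate - joint$estimate[j],
                    se_separate = separate$se,
                    se_joint = joint$se[j],
                    se_diff = separate$se - joint$se[j],
                    stringsAsFactors = FALSE)
  out$flagged <- abs(out$estimate_diff) > 1e-8
  class(out) <- c("bp_fit_comparison", "data.frame")
  out
}

#' Assemble a run configuration
#'
#' @param generator A [generator_config()] used when no `data` path is
#'   given.
#' @param data Optional path to a cohort CSV to analyse instead of
#'   generating one.
#' @param model A [model_spec()].
#' @param p_threshold Exploratory screen retention threshold (default 0.20).
#' @param vif_threshold Collinearity threshold (default 10).
#' @param robust Use the cluster-robust coefficient covariance for
#'   inference (requires psu/stratum columns in the model spec).
#' @param design_df Optional denominator df override for the joint F test.
#' @param seed Run seed feeding every stochastic stage.
#' @return A list of class `bp_run_config`.
#' @export
run_config <- function(generator = generator_config(), data = NULL,
                       model = steps_model_spec(), p_threshold = 0.20,
                       vif_threshold = 10, robust = FALSE, design_df = NULL,
                       seed = NULL) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(model, "bp_model_spec"),
            is_scalar_number(p_threshold), p_threshold > 0, p_threshold <= 1,
            is_scalar_number(vif_threshold), vif_threshold > 0)
  structure(list(generator = generator, data = data, model = model,
                 p_threshold = p_threshold, vif_threshold = vif_threshold,
                 robust = isTRUE(robust), design_df = design_df, seed = seed),
            class = "bp_run_config")
}

#' Run the full screening-and-joint-modelling analysis
#'
#' Stages, in order: load or generate the cohort; exclude participants on
#' anti-hypertensive medication; descriptives; hypertension prevalence;
#' Pearson correlation of the two outcomes; VIF screen (terms whose every
#' design column has VIF below the threshold are kept); exploratory
#' per-predictor screen at the p threshold; separate per-equation
#' least-squares fits; the joint two-response fit; diagnostics (joint F,
#' bivariate Shapiro-Wilk, Breusch-Pagan, residual correlation);
#' cross-equation equality tests for every design column significant at 5%
#' in either equation of the joint model; and the separate-vs-joint
#' comparison. Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, tables are written as CSV
#'   and run metadata as JSON.
#' @return A list of class `bp_report`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "bp_run_config"))
  log <- list()
  cohort <- if (!is.null(config$data)) {
    read_cohort(config$data)
  } else {
    gen <- config$generator
    gen$seed <- gen$seed %||% substream_seed(config$seed, "pipeline")
    generate_cohort(gen)
  }
  log$rows_input <- nrow(cohort)

  if ("on_bp_medication" %in% names(cohort)) {
    medicated <- cohort$on_bp_medication %in% TRUE
    cohort <- cohort[!medicated, , drop = FALSE]
    log$rows_excluded_medication <- sum(medicated)
  } else log$rows_excluded_medication <- 0L
  if (nrow(cohort) == 0L) stop("pipeline: no rows left after exclusions", call. = FALSE)

  descriptives <- describe_cohort(cohort, schema = if (is.null(config$data))
    config$generator$schema else NULL)
  prev <- prevalence(cohort)
  pearson <- pearson_correlation_test(cohort$sbp, cohort$dbp)

  enc_all <- encode_model(cohort, config$model)
  log$rows_dropped_missing <- enc_all$n_dropped
  vif <- compute_vif(enc_all$X, threshold = config$vif_threshold)
  term_of <- design_column_terms(colnames(enc_all$X), names(config$model$terms))
  bad_terms <- unique(term_of[match(vif$column[!vif$retained], colnames(enc_all$X))])
  vif_terms <- setdiff(names(config$model$terms), bad_terms)

  screen <- exploratory_screen(cohort, candidates = vif_terms, spec = config$model,
                               threshold = config$p_threshold)
  kept <- screen$term[screen$retained %in% TRUE]
  if (length(kept) == 0L) stop("pipeline: no predictors survived screening", call. = FALSE)
  final_spec <- config$model
  final_spec$terms <- final_spec$terms[kept]

  enc <- encode_model(cohort, final_spec)
  joint <- fit_mvreg(enc)
  V <- if (config$robust) coef_covariance(joint, "cluster_robust") else joint$vcov
  joint_summary <- summary(joint, vcov = if (config$robust) V else NULL)

  separate <- separate_lm_table(enc, final_spec$outcomes)

  diagnostics <- list(
    pearson = pearson,
    joint_f = joint_f_test(joint, vcov = if (config$robust) V else NULL,
                           df2 = config$design_df),
    breusch_pagan = breusch_pagan_independence(joint),
    mshapiro = multivariate_shapiro(joint,
                                    seed = substream_seed(config$seed %||% 1L, "subsample")),
    residual_correlation = residual_correlation(joint))

  ctab <- joint_summary$coefficients
  sig_terms <- unique(ctab$term[ctab$p_value < 0.05 & ctab$term != "(Intercept)"])
  cross <- lapply(sig_terms, function(tm)
    cross_equation_test(joint, tm, vcov = if (config$robust) V else NULL))
  names(cross) <- sig_terms
  cross_table <- if (length(cross)) data.frame(
    term = sig_terms,
    df1 = 1L,
    statistic = vapply(cross, `[[`, numeric(1L), "statistic"),
    p_value = vapply(cross, `[[`, numeric(1L), "p_value"),
    sig = p_stars(vapply(cross, `[[`, numeric(1L), "p_value")),
    stringsAsFactors = FALSE, row.names = NULL) else data.frame()

  comparison <- compare_fits(separate, joint_summary$coefficients)

  report <- structure(list(
    descriptives = descriptives, prevalence = prev,
    vif = vif, screening = screen,
    separate = separate, joint = joint_summary,
    fit = joint, diagnostics = diagnostics,
    cross_equation = cross_table,
    comparison = comparison,
    meta = list(seed = config$seed, robust = config$robust,
                design_df = config$design_df,
                p_threshold = config$p_threshold,
                vif_threshold = config$vif_threshold,
                n_used = joint$n, p = joint$p,
                df_residual = joint$df_residual, log = log)),
    class = "bp_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# map design-column labels back to their model-spec terms
design_column_terms <- function(labels, terms) {
  out <- labels
  for (tm in terms) out[startsWith(labels, paste0(tm, "["))] <- tm
  out[labels %in% terms] <- labels[labels %in% terms]
  out
}

# separate per-equation least-squares fits via lm on the same design
separate_lm_table <- function(enc, outcomes) {
  rows <- lapply(1:2, function(eq) {
    fit <- if (is.null(enc$weights)) stats::lm(enc$Y[, eq] ~ enc$X - 1)
           else stats::lm(enc$Y[, eq] ~ enc$X - 1, weights = enc$weights / mean(enc$weights))
    cf <- summary(fit)$coefficients
    data.frame(term = colnames(enc$X), outcome = outcomes[[eq]],
               estimate = cf[, 1L], se = cf[, 2L],
               statistic = cf[, 3L], p_value = cf[, 4L],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' @export
print.bp_report <- function(x, ...) {
  cat("=== Joint SBP/DBP analysis report ===\n\n")
  print(x$prevalence); cat("\n")
  cat("Pearson r(SBP, DBP) =", round(x$diagnostics$pearson$estimate, 4L),
      "(p =", format.pval(x$diagnostics$pearson$p_value, digits = 3L), ")\n\n")
  cat("Retained after screening:", paste(x$screening$term[x$screening$retained %in% TRUE],
                                         collapse = ", "), "\n\n")
  print(x$joint); cat("\n")
  print(x$diagnostics$joint_f); cat("\n")
  print(x$diagnostics$breusch_pagan); cat("\n")
  if (nrow(x$cross_equation)) {
    cat("Cross-equation equality tests (significant terms):\n")
    print(transform(x$cross_equation, statistic = round(statistic, 2L),
                    p_value = signif(p_value, 3L)), row.names = FALSE)
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$joint$coefficients,
                   file.path(out_dir, "coefficients_joint.csv"), row.names = FALSE)
  utils::write.csv(report$separate,
                   file.path(out_dir, "coefficients_separate.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(report$vif)),
                   file.path(out_dir, "vif.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(report$screening)),
                   file.path(out_dir, "screening.csv"), row.names = FALSE)
  utils::write.csv(report$descriptives$categorical,
                   file.path(out_dir, "descriptives.csv"), row.names = FALSE)
  if (nrow(report$cross_equation))
    utils::write.csv(report$cross_equation,
                     file.path(out_dir, "cross_equation_tests.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$fit$sigma),
                   file.path(out_dir, "residual_covariance.csv"), row.names = TRUE)
  diag <- report$diagnostics
  meta <- c(report$meta[setdiff(names(report$meta), "log")],
            report$meta$log,
            list(prevalence = unclass(report$prevalence)[c("n", "n_sbp", "n_dbp",
                                                           "n_either", "pct_sbp",
                                                           "pct_dbp", "pct_either")],
                 residual_correlation = diag$residual_correlation,
                 joint_f = diag$joint_f$statistic,
                 joint_f_p = diag$joint_f$p_value,
                 breusch_pagan = diag$breusch_pagan$statistic,
                 mshapiro_p = diag$mshapiro$p_value,
                 pearson_r = diag$pearson$estimate))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
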