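#' Declare the regression terms for the two-outcome model
#'
#' A model specification names the two outcome columns (SBP first) and an
#' ordered list of predictor terms. Categorical terms carry their reference
#' level; with treatment coding the reference level is omitted from the
#' design matrix and coefficients measure differences from it.
#'
#' @param outcomes Character vector of exactly two outcome column names,
#'   `c(sbp, dbp)`.
#' @param terms Named list: each element either `"continuous"` or a list
#'   with a `ref` entry giving the reference level of a categorical term.
#' @param weight,stratum,psu Optional design column names.
#' @return An object of class `bp_model_spec`.
#' @export
#' @examples
#' spec <- model_spec(terms = list(age = "continuous", region = list(ref = "central")))
model_spec <- function(outcomes = c("sbp", "dbp"), terms,
                       weight = NULL, stratum = NULL, psu = NULL) {
  if (length(outcomes) != 2L || anyDuplicated(outcomes))
    stop("exactly two distinct outcome columns are required", call. = FALSE)
  if (!is.list(terms) || is.null(names(terms)) || any(names(terms) == ""))
    stop("`terms` must be a fully named list", call. = FALSE)
  if (anyDuplicated(names(terms)))
    stop("duplicated term names in model spec", call. = FALSE)
  terms <- lapply(terms, function(t) {
    if (identical(t, "continuous")) return(list(kind = "continuous"))
    if (is.list(t) && !is.null(t$ref))
      return(list(kind = "categorical", ref = as.character(t$ref)))
    stop("each term must be \"continuous\" or list(ref = <level>)", call. = FALSE)
  })
  structure(list(outcomes = outcomes, terms = terms,
                 weight = weight, stratum = stratum, psu = psu),
            class = "bp_model_spec")
}

#' The published 19-column model specification
#'
#' The eleven predictors retained by the exploratory screen, with the
#' published reference categories, in table order: age, BMI, fasting
#' glucose, region, marital status, daily fruit servings, dietary salt,
#' physical activity, income, total cholesterol, central obesity.
#'
#' @param weight,stratum,psu Optional design column names (e.g. `"weight"`,
#'   `"stratum"`, `"psu"` for generated cohorts).
#' @return A `bp_model_spec`.
#' @export
steps_model_spec <- function(weight = NULL, stratum = NULL, psu = NULL) {
  model_spec(
    outcomes = c("sbp", "dbp"),
    terms = list(
      age = "continuous",
      bmi = list(ref = "normal weight"),
      glucose = list(ref = "normal"),
      region = list(ref = "central"),
      marital = list(ref = "never married"),
      fruit_daily = list(ref = "no"),
      salt = list(ref = "always"),
      active = list(ref = "no"),
      income = list(ref = "<277"),
      cholesterol = list(ref = "not hypercholesterolemic"),
      central_obesity = list(ref = "normal")),
    weight = weight, stratum = stratum, psu = psu)
}

#' Build a model spec from a compact formula-like string
#'
#' Dialect: `"sbp + dbp ~ age + region(ref=central) + ..."`. Terms without
#' a `ref` are continuous; terms with `(ref=<level>)` are categorical with
#' that reference level.
#'
#' @param x A single string.
#' @return A `bp_model_spec`.
#' @export
#' @examples
#' as_model_spec("sbp + dbp ~ age + region(ref=central)")
as_model_spec <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  sides <- strsplit(x, "~", fixed = TRUE)[[1L]]
  if (length(sides) != 2L) stop("expected '<outcomes> ~ <terms>'", call. = FALSE)
  outcomes <- trimws(strsplit(sides[[1L]], "+", fixed = TRUE)[[1L]])
  rhs <- trimws(strsplit(sides[[2L]], "+", fixed = TRUE)[[1L]])
  terms <- list()
  for (tk in rhs) {
    m <- regmatches(tk, regexec("^([^()]+)\\(\\s*ref\\s*=\\s*([^)]+)\\)$", tk))[[1L]]
    if (length(m) == 3L) {
      terms[[trimws(m[[2L]])]] <- list(ref = trimws(m[[3L]]))
    } else {
      terms[[tk]] <- "continuous"
    }
  }
  model_spec(outcomes = outcomes, terms = terms)
}

#' Encode a cohort into design and response matrices
#'
#' Treatment (reference) coding: for each categorical term the reference
#' level is omitted and one indicator column per remaining observed level is
#' created, labelled `variable[level]`, in declared level order. The
#' intercept column comes first and term blocks follow the spec's term
#' order. Rows with a missing value in any used column (outcomes, terms,
#' design columns) are dropped (listwise deletion) and counted.
#'
#' @param cohort Cohort `data.frame`.
#' @param spec A [model_spec()].
#' @return A list of class `bp_design` with elements `X` (n x p design
#'   matrix), `Y` (n x 2 response matrix), `weights`, `strata`, `clusters`,
#'   `n_dropped`, `dropped_levels`.
#' @export
encode_model <- function(cohort, spec) {
  stopifnot(is.data.frame(cohort), inherits(spec, "bp_model_spec"))
  used <- c(spec$outcomes, names(spec$terms), spec$weight, spec$stratum, spec$psu)
  missing_cols <- setdiff(used, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  keep <- stats::complete.cases(cohort[used])
  n_dropped <- sum(!keep)
  data <- cohort[keep, used, drop = FALSE]
  n <- nrow(data)

  Y <- as.matrix(data[spec$outcomes])
  if (!is.numeric(Y)) stop("outcome columns must be numeric", call. = FALSE)
  if (any(!is.finite(Y))) stop("non-finite outcome values present", call. = FALSE)
  colnames(Y) <- spec$outcomes

  blocks <- list(`(Intercept)` = matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  dropped_levels <- list()
  for (v in names(spec$terms)) {
    tm <- spec$terms[[v]]
    if (tm$kind == "continuous") {
      col <- as.numeric(data[[v]])
      if (any(!is.finite(col)))
        stop("non-finite values in continuous term '", v, "'", call. = FALSE)
      blocks[[v]] <- matrix(col, n, 1L, dimnames = list(NULL, v))
    } else {
      f <- data[[v]]
      if (!is.factor(f)) f <- factor(f)
      present <- levels(f)[levels(f) %in% unique(as.character(f))]
      empty <- setdiff(levels(f), present)
      if (length(empty)) dropped_levels[[v]] <- empty
      if (!tm$ref %in% levels(f))
        stop("reference level '", tm$ref, "' unknown for term '", v, "'", call. = FALSE)
      if (n > 0L && !tm$ref %in% present)
        stop("reference level '", tm$ref, "' of term '", v,
             "' not observed in the data", call. = FALSE)
      if (n > 0L && length(present) < 2L) {
        warning("term '", v, "' has a single observed level and contributes no columns",
                call. = FALSE)
        next
      }
      f <- factor(as.character(f), levels = c(tm$ref, setdiff(present, tm$ref)))
      M <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(M) <- paste0(v, "[", levels(f)[-1L], "]")
      rownames(M) <- NULL
      blocks[[v]] <- M
    }
  }
  X <- do.call(cbind, blocks)

  const <- apply(X[, -1L, drop = FALSE], 2L, function(x) length(x) > 1L && all(x == x[1L]))
  if (any(const))
    warning("constant non-intercept column(s): ",
            paste(colnames(X)[-1L][const], collapse = ", "),
            " - the design is rank deficient", call. = FALSE)

  structure(list(
    X = X, Y = Y,
    weights = if (!is.null(spec$weight)) as.numeric(data[[spec$weight]]) else NULL,
    strata = if (!is.null(spec$stratum)) data[[spec$stratum]] else NULL,
    clusters = if (!is.null(spec$psu)) data[[spec$psu]] else NULL,
    n_dropped = n_dropped, dropped_levels = dropped_levels),
    class = "bp_design")
}

#' Report data problems relevant to model estimation
#'
#' A non-failing audit of the cohort against a model spec: missingness per
#' used column, levels observed in the data but foreign to the generator
#' schema (if one is supplied), rank deficiency of the encodable design,
#' non-finite outcome values, and the number of rows the
#' anti-hypertensive-medication exclusion would remove.
#'
#' @param cohort Cohort `data.frame`.
#' @param spec A [model_spec()].
#' @param schema Optional [covariate_schema()] used to flag unseen levels.
#' @return A list of class `bp_validation`.
#' @export
validate_cohort <- function(cohort, spec, schema = NULL) {
  stopifnot(is.data.frame(cohort), inherits(spec, "bp_model_spec"))
  used <- intersect(c(spec$outcomes, names(spec$terms),
                      spec$weight, spec$stratum, spec$psu), names(cohort))
  missing_by_col <- vapply(cohort[used], function(x) sum(is.na(x)), integer(1L))
  nonfinite_outcomes <- vapply(intersect(spec$outcomes, names(cohort)), function(oc) {
    x <- cohort[[oc]]
    if (!is.numeric(x)) return(NA_integer_)
    sum(!is.finite(x) & !is.na(x))
  }, integer(1L))
  unseen <- list()
  if (!is.null(schema)) {
    for (v in intersect(names(schema), names(cohort))) {
      if (schema[[v]]$kind != "categorical") next
      obs <- unique(as.character(cohort[[v]]))
      extra <- setdiff(obs[!is.na(obs)], schema[[v]]$levels)
      if (length(extra)) unseen[[v]] <- extra
    }
  }
  rank_deficient <- FALSE
  aliased <- character(0L)
  enc <- tryCatch(suppressWarnings(encode_model(cohort, spec)), error = function(e) NULL)
  if (!is.null(enc) && nrow(enc$X) > 0L) {
    qd <- qr(enc$X)
    if (qd$rank < ncol(enc$X)) {
      rank_deficient <- TRUE
      aliased <- colnames(enc$X)[qd$pivot[seq.int(qd$rank + 1L, ncol(enc$X))]]
    }
  }
  n_medicated <- if ("on_bp_medication" %in% names(cohort))
    sum(cohort$on_bp_medication %in% TRUE) else 0L
  structure(list(n = nrow(cohort), missing_by_column = missing_by_col,
                 nonfinite_outcomes = nonfinite_outcomes,
                 unseen_levels = unseen, rank_deficient = rank_deficient,
                 aliased_columns = aliased, n_medicated = n_medicated),
            class = "bp_validation")
}

#' @export
print.bp_validation <- function(x, ...) {
  cat("Cohort validation (n = ", x$n, ")\n", sep = "")
  miss <- x$missing_by_column[x$missing_by_column > 0L]
  if (length(miss)) {
    cat("  missing values:\n")
    for (v in names(miss)) cat("    ", v, ": ", miss[[v]], "\n", sep = "")
  } else cat("  no missing values in used columns\n")
  if (x$rank_deficient)
    cat("  RANK DEFICIENT design; aliased: ",
        paste(x$aliased_columns, collapse = ", "), "\n", sep = "")
  if (length(x$unseen_levels))
    cat("  unseen levels in: ", paste(names(x$unseen_levels), collapse = ", "), "\n", sep = "")
  cat("  rows excluded by medication filter: ", x$n_medicated, "\n", sep = "")
  invisible(x)
}
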