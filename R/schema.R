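#' Declare a categorical covariate with marginal level probabilities
#'
#' Categorical covariates are sampled independently from their declared
#' marginal distribution. The first level (or `ref`) is the reference level
#' used when the variable enters a regression with treatment coding.
#'
#' @param name Column name in the generated cohort.
#' @param levels Character vector of level labels, reference first unless
#'   `ref` says otherwise.
#' @param probs Marginal probabilities, same length as `levels`; must be
#'   non-negative and sum to 1 (within 1e-9). Counts may be supplied and are
#'   normalised.
#' @param ref Reference level; must be one of `levels`.
#' @return An object of class `bp_variable`.
#' @export
categorical_variable <- function(name, levels, probs, ref = levels[[1L]]) {
  stopifnot(is.character(name), length(name) == 1L)
  levels <- as.character(levels)
  if (anyDuplicated(levels)) stop("duplicated levels for '", name, "'", call. = FALSE)
  if (length(probs) != length(levels))
    stop("probs and levels differ in length for '", name, "'", call. = FALSE)
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("invalid probability vector for '", name, "': entries must be finite and >= 0",
         call. = FALSE)
  s <- sum(probs)
  if (s <= 0) stop("invalid probability vector for '", name, "': sum is zero", call. = FALSE)
  if (abs(s - 1) > 1e-9) probs <- probs / s
  if (abs(sum(probs) - 1) > 1e-9)
    stop("invalid probability vector for '", name, "'", call. = FALSE)
  if (!ref %in% levels)
    stop("reference level '", ref, "' not among levels of '", name, "'", call. = FALSE)
  structure(list(name = name, kind = "categorical", levels = levels,
                 probs = as.numeric(probs), ref = ref),
            class = "bp_variable")
}

#' Declare a continuous covariate
#'
#' The only continuous covariate in the default cohort is age, drawn from a
#' log-normal distribution truncated to the adult age range of the survey.
#' Truncation is exact (inverse-CDF on the truncated probability range), so
#' no rejection sampling is involved.
#'
#' @param name Column name in the generated cohort.
#' @param dist Distribution family: `"lnorm"`, `"norm"` or `"unif"`.
#' @param params Named list of family parameters (`meanlog`/`sdlog`,
#'   `mean`/`sd`, or `min`/`max`).
#' @param lower,upper Truncation bounds (values outside are impossible).
#' @return An object of class `bp_variable`.
#' @export
continuous_variable <- function(name, dist = c("lnorm", "norm", "unif"),
                                params, lower = -Inf, upper = Inf) {
  dist <- match.arg(dist)
  stopifnot(is.character(name), length(name) == 1L, is.list(params), lower < upper)
  structure(list(name = name, kind = "continuous", dist = dist,
                 params = params, lower = lower, upper = upper),
            class = "bp_variable")
}

#' Bundle covariate declarations into a schema
#'
#' @param ... `bp_variable` objects created by [categorical_variable()] or
#'   [continuous_variable()].
#' @return An object of class `covariate_schema`.
#' @export
covariate_schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && is.list(vars[[1L]]) && !inherits(vars[[1L]], "bp_variable"))
    vars <- vars[[1L]]
  ok <- vapply(vars, inherits, logical(1L), what = "bp_variable")
  if (!all(ok)) stop("all schema entries must be bp_variable objects", call. = FALSE)
  nm <- vapply(vars, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("duplicated variable names in schema", call. = FALSE)
  names(vars) <- nm
  structure(vars, class = "covariate_schema")
}

#' Default cohort schema: the 2014 Uganda STEPS survey marginals
#'
#' Marginal level probabilities are the published cohort counts divided by
#' n = 3,646. Age is log-normal with median 32 years and IQR 25-44 (meanlog
#' = log 32, sdlog chosen so the untruncated quartiles are 25 and 44),
#' truncated to 18-69 years. Covariates are sampled independently: the
#' published description gives marginals only, so no joint dependence
#' structure is imposed.
#'
#' @return A `covariate_schema` with 17 variables.
#' @export
#' @examples
#' sch <- steps_schema()
#' names(sch)
steps_schema <- function() {
  n <- 3646
  covariate_schema(
    continuous_variable("age", "lnorm",
                        params = list(meanlog = log(32),
                                      sdlog = (log(44) - log(25)) / (2 * stats::qnorm(0.75))),
                        lower = 18, upper = 69),
    categorical_variable("sex", c("female", "male"), c(2178, 1468) / n),
    categorical_variable("residence", c("rural", "urban"), c(2616, 1030) / n),
    categorical_variable("education",
                         c("no formal education", "primary", "secondary", "university/tertiary"),
                         c(577, 1479, 1233, 357) / n),
    categorical_variable("region", c("central", "eastern", "northern", "western"),
                         c(1294, 964, 779, 609) / n),
    categorical_variable("cholesterol",
                         c("not hypercholesterolemic", "hypercholesterolemic"),
                         c(3333, 313) / n),
    categorical_variable("income", c("<277", "278-2777", ">=2778"),
                         c(116, 1951, 1579) / n),
    categorical_variable("marital",
                         c("never married", "married/cohabiting", "separated/widowed/divorced"),
                         c(583, 2412, 651) / n),
    categorical_variable("fruit_daily", c("no", "yes"), c(3280, 366) / n),
    categorical_variable("salt", c("always", "often/sometimes", "rarely/never"),
                         c(435, 1272, 1939) / n),
    categorical_variable("vegetables_daily", c("no", "yes"), c(3348, 298) / n),
    categorical_variable("smoking", c("never", "1-10/day", ">10/day"),
                         c(3390, 213, 43) / n),
    categorical_variable("alcohol", c("no", "yes"), c(1904, 1742) / n),
    categorical_variable("active", c("no", "yes"), c(617, 3029) / n),
    categorical_variable("glucose", c("normal", "impaired", "diabetic"),
                         c(3553, 67, 26) / n),
    categorical_variable("bmi", c("normal weight", "underweight", "overweight", "obese"),
                         c(2506, 319, 585, 236) / n),
    categorical_variable("central_obesity", c("normal", "obese"),
                         c(2480, 1166) / n)
  )
}

#' Sample covariates from a schema
#'
#' Draws `n` independent rows. Categorical columns are returned as factors
#' with the schema's level order (reference first); continuous columns as
#' numeric.
#'
#' @param schema A `covariate_schema`.
#' @param n Number of participants (may be 0).
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @return A `data.frame` with `n` rows, one column per schema variable.
#' @export
#' @examples
#' head(sample_covariates(steps_schema(), 5, seed = 1))
sample_covariates <- function(schema, n, seed = NULL) {
  if (!inherits(schema, "covariate_schema"))
    stop("`schema` must be a covariate_schema", call. = FALSE)
  if (!is_count(n)) stop("`n` must be a non-negative integer", call. = FALSE)
  local_seed(seed)
  cols <- lapply(schema, function(v) {
    if (v$kind == "categorical") {
      if (n == 0L) return(factor(character(0L), levels = v$levels))
      factor(sample(v$levels, n, replace = TRUE, prob = v$probs), levels = v$levels)
    } else {
      sample_continuous(v, n)
    }
  })
  out <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  names(out) <- names(schema)
  if (n == 0L) out <- out[0L, , drop = FALSE]
  out
}

sample_continuous <- function(v, n) {
  if (n == 0L) return(numeric(0L))
  u <- stats::runif(n)
  pfun <- switch(v$dist, lnorm = stats::plnorm, norm = stats::pnorm, unif = stats::punif)
  qfun <- switch(v$dist, lnorm = stats::qlnorm, norm = stats::qnorm, unif = stats::qunif)
  args <- v$params
  plo <- do.call(pfun, c(list(v$lower), args))
  phi <- do.call(pfun, c(list(v$upper), args))
  do.call(qfun, c(list(plo + u * (phi - plo)), args))
}
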