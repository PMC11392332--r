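new_test_result <- function(name, statistic, df1, df2, p_value, null_hypothesis,
                            extra = list()) {
  structure(c(list(name = name, statistic = statistic, df1 = df1, df2 = df2,
                   p_value = p_value, null_hypothesis = null_hypothesis), extra),
            class = "bp_test")
}

#' @export
print.bp_test <- function(x, ...) {
  dftxt <- if (is.finite(x$df2 %||% Inf)) paste0("(", x$df1, ", ", x$df2, ")")
           else paste0("(", x$df1, ")")
  cat(x$name, ": statistic ", dftxt, " = ", signif(x$statistic, 6L),
      ", p = ", format.pval(x$p_value, digits = 4L), "\n",
      "H0: ", x$null_hypothesis, "\n", sep = "")
  invisible(x)
}

#' Joint significance of both equations
#'
#' Wald F test that every non-intercept coefficient in both equations is
#' zero, using the full stacked coefficient covariance (so the
#' cross-equation residual correlation enters). Numerator df is 2(p - 1);
#' the denominator df defaults to the residual df and can be overridden with
#' a design-based value.
#'
#' @param fit An `mvreg_fit`.
#' @param vcov Optional replacement covariance (e.g. cluster robust).
#' @param df2 Denominator degrees of freedom override.
#' @return A `bp_test`.
#' @export
joint_f_test <- function(fit, vcov = NULL, df2 = NULL) {
  stopifnot(inherits(fit, "mvreg_fit"))
  p <- fit$p
  inter <- which(rownames(fit$coefficients) == "(Intercept)")
  if (length(inter) != 1L) inter <- 1L
  if (p <= 1L) stop("joint F test needs at least one non-intercept term", call. = FALSE)
  V <- vcov %||% fit$vcov
  df2 <- df2 %||% fit$df_residual
  idx <- setdiff(seq_len(2L * p), c(inter, p + inter))
  b <- as.vector(fit$coefficients)[idx]
  q <- length(idx)
  stat <- as.numeric(crossprod(b, solve(V[idx, idx, drop = FALSE], b))) / q
  new_test_result("Joint F test of both equations", stat, q, df2,
                  stats::pf(stat, q, df2, lower.tail = FALSE),
                  "all non-intercept coefficients in both equations are zero")
}

#' Cross-equation equality of one coefficient
#'
#' Tests H0: the term's effect on SBP equals its effect on DBP, via the
#' contrast on the stacked coefficient vector using the full 2p x 2p
#' covariance including the cross-equation block. Reported as F with 1
#' numerator df (the square of the t statistic of the difference); a
#' chi-square version is available.
#'
#' @param fit An `mvreg_fit`.
#' @param term A design-column label, e.g. `"age"` or `"region[eastern]"`.
#' @param vcov Optional replacement covariance.
#' @param df2 Denominator df override (F version).
#' @param statistic `"F"` (default) or `"chisq"`.
#' @return A `bp_test` with extra fields `difference` and `se_difference`.
#' @export
cross_equation_test <- function(fit, term, vcov = NULL, df2 = NULL,
                                statistic = c("F", "chisq")) {
  stopifnot(inherits(fit, "mvreg_fit"))
  statistic <- match.arg(statistic)
  j <- match(term, rownames(fit$coefficients))
  if (is.na(j)) stop("term '", term, "' not found in the fit", call. = FALSE)
  p <- fit$p
  V <- vcov %||% fit$vcov
  d <- fit$coefficients[j, 1L] - fit$coefficients[j, 2L]
  vd <- V[j, j] + V[p + j, p + j] - 2 * V[j, p + j]
  if (!is.finite(vd) || vd <= .Machine$double.eps * max(1, abs(V[j, j])))
    stop("contrast variance is singular for term '", term, "'", call. = FALSE)
  stat <- d^2 / vd
  if (statistic == "F") {
    df2 <- df2 %||% fit$df_residual
    pv <- stats::pf(stat, 1L, df2, lower.tail = FALSE)
  } else {
    df2 <- Inf
    pv <- stats::pchisq(stat, 1L, lower.tail = FALSE)
  }
  new_test_result(paste0("Cross-equation equality test: ", term), stat, 1L, df2, pv,
                  paste0("effect of ", term, " on ", colnames(fit$coefficients)[1L],
                         " equals its effect on ", colnames(fit$coefficients)[2L]),
                  extra = list(term = term, difference = d, se_difference = sqrt(vd)))
}

#' Breusch-Pagan Lagrange-multiplier test of residual independence
#'
#' With two equations the LM statistic is \eqn{n r^2}, where r is the
#' cross-equation residual correlation, referred to chi-square with 1 df.
#' Invariant to affine rescaling of either outcome.
#'
#' @param fit An `mvreg_fit`.
#' @return A `bp_test` with extra field `residual_correlation`.
#' @export
breusch_pagan_independence <- function(fit) {
  stopifnot(inherits(fit, "mvreg_fit"))
  if (fit$n < 3L) stop("Breusch-Pagan test needs n >= 3", call. = FALSE)
  r <- residual_correlation(fit)
  stat <- fit$n * r^2
  new_test_result("Breusch-Pagan test of independence", stat, 1L, Inf,
                  stats::pchisq(stat, 1L, lower.tail = FALSE),
                  "the residuals of the two equations are uncorrelated",
                  extra = list(residual_correlation = r))
}

#' Shapiro-Wilk test of bivariate residual normality
#'
#' Generalises the univariate Shapiro-Wilk test: the residual pairs are
#' centred and transformed by the inverse Cholesky factor of their sample
#' covariance, after which all 2n standardised entries are iid standard
#' normal under the null and the univariate Shapiro-Wilk statistic is
#' applied to them. Because the univariate statistic is defined for at most
#' 5,000 values, rows are subsampled (default cap 2,500 pairs = 5,000
#' values) under a fixed seed when needed.
#'
#' @param fit An `mvreg_fit`, or an n x 2 residual matrix.
#' @param max_n Maximum number of residual pairs used (default 2500).
#' @param seed Seed for the subsample draw (default 1; only consulted when
#'   subsampling happens).
#' @return A `bp_test` with extra field `n_used`.
#' @export
multivariate_shapiro <- function(fit, max_n = 2500L, seed = 1L) {
  E <- if (inherits(fit, "mvreg_fit")) fit$residuals else as.matrix(fit)
  if (ncol(E) != 2L) stop("expected two residual columns", call. = FALSE)
  n <- nrow(E)
  max_n <- as.integer(max_n)
  if (n < 3L) stop("Shapiro-Wilk test needs at least 3 observations", call. = FALSE)
  if (n > max_n) {
    local_seed(seed)
    E <- E[sample.int(n, max_n), , drop = FALSE]
    n <- max_n
  }
  Ec <- sweep(E, 2L, colMeans(E))
  S <- crossprod(Ec) / (n - 1)
  if (S[1L, 1L] <= 0 || S[2L, 2L] <= 0 ||
      S[1L, 1L] * S[2L, 2L] - S[1L, 2L]^2 <= 1e-12 * S[1L, 1L] * S[2L, 2L])
    stop("singular residual covariance: normality test undefined", call. = FALSE)
  R <- chol(S)
  Z <- Ec %*% solve(R)   # rows iid N2(0, I) under H0
  sw <- stats::shapiro.test(as.vector(Z))
  new_test_result("Multivariate Shapiro-Wilk normality test",
                  unname(sw$statistic), NA_integer_, NA_integer_, sw$p.value,
                  "the residual pairs are bivariate normal",
                  extra = list(n_used = n))
}

#' Pearson correlation test between the two blood pressures
#'
#' The pre-model justification for joint modelling: Pearson r with the
#' exact t reference on n - 2 df, two sided.
#'
#' @param y1,y2 Numeric vectors of equal length (n >= 3), e.g. average SBP
#'   and DBP.
#' @return A `bp_test` with extra field `estimate` (r).
#' @export
pearson_correlation_test <- function(y1, y2) {
  if (length(y1) != length(y2)) stop("`y1` and `y2` differ in length", call. = FALSE)
  if (length(y1) < 3L) stop("correlation test needs n >= 3", call. = FALSE)
  if (any(!is.finite(y1)) || any(!is.finite(y2)))
    stop("non-finite values in the outcomes", call. = FALSE)
  if (stats::sd(y1) == 0 || stats::sd(y2) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(y1, y2, method = "pearson")
  new_test_result("Pearson correlation test", unname(ct$statistic),
                  unname(ct$parameter), NA_integer_, ct$p.value,
                  "the two blood pressures are uncorrelated",
                  extra = list(estimate = unname(ct$estimate)))
}
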