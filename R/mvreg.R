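#' Fit the two-response linear model with bivariate-normal errors
#'
#' Solves the (weighted) normal equations for each outcome on the shared
#' design matrix. With identical regressors in both equations this is the
#' maximum-likelihood point estimate under the bivariate-normal error model,
#' and coincides with two separate per-equation least-squares fits. The
#' residual covariance is estimated as \eqn{\hat\Sigma = \hat E' W \hat E /
#' (n - p)} (denominator switchable to \eqn{n} for ML), and the default
#' coefficient covariance is \eqn{\hat\Sigma \otimes (X'WX)^{-1}} for the
#' column-stacked coefficient vector (SBP equation first).
#'
#' Weights, when supplied, are normalised to mean 1, so constant weights
#' reproduce the unweighted fit exactly, including \eqn{\hat\Sigma}.
#'
#' @param X Design matrix (n x p, intercept first) or a `bp_design` from
#'   [encode_model()], in which case `Y`, `weights`, strata and clusters are
#'   taken from it.
#' @param Y Response matrix (n x 2).
#' @param weights Optional strictly positive per-row weights.
#' @param sigma_denom `"df"` (n - p, default) or `"n"` (ML).
#' @return An object of class `mvreg_fit` with components `coefficients`
#'   (p x 2), `residuals`, `fitted`, `sigma`, `vcov`, `xtxinv`, `n`, `p`,
#'   `df_residual`, `weights`, `strata`, `clusters`.
#' @export
#' @examples
#' X <- cbind(`(Intercept)` = 1, x = c(-2, -1, 0, 1, 2, 3))
#' Y <- cbind(sbp = c(120, 118, 125, 124, 130, 131),
#'            dbp = c(80, 78, 82, 81, 85, 86))
#' fit <- fit_mvreg(X, Y)
#' coef(fit)
fit_mvreg <- function(X, Y = NULL, weights = NULL, sigma_denom = c("df", "n")) {
  sigma_denom <- match.arg(sigma_denom)
  strata <- clusters <- NULL
  if (inherits(X, "bp_design")) {
    design <- X
    X <- design$X
    Y <- design$Y
    weights <- weights %||% design$weights
    strata <- design$strata
    clusters <- design$clusters
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- c("y1", "y2")
  n <- nrow(X); p <- ncol(X)
  if (ncol(Y) != 2L) stop("`Y` must have exactly two columns", call. = FALSE)
  if (nrow(Y) != n) stop("`X` and `Y` row counts differ", call. = FALSE)
  if (n <= p) stop("insufficient data: n (", n, ") must exceed p (", p, ")", call. = FALSE)
  if (!is.null(weights)) {
    if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0))
      stop("weights must be strictly positive, one per row", call. = FALSE)
    w <- weights / mean(weights)
  } else {
    w <- rep(1, n)
  }

  qd <- qr(X * sqrt(w))
  if (qd$rank < p) {
    bad <- colnames(X)[qd$pivot[seq.int(qd$rank + 1L, p)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qd, Y * sqrt(w))
  dimnames(B) <- list(colnames(X), colnames(Y))
  fitted <- X %*% B
  E <- Y - fitted
  denom <- if (sigma_denom == "df") n - p else n
  Sigma <- crossprod(E, w * E) / denom
  dimnames(Sigma) <- list(colnames(Y), colnames(Y))
  xtxinv <- chol2inv(qr.R(qd))[order(qd$pivot), order(qd$pivot), drop = FALSE]
  dimnames(xtxinv) <- list(colnames(X), colnames(X))
  V <- kronecker(Sigma, xtxinv)
  vnames <- as.vector(outer(colnames(X), colnames(Y), function(a, b) paste(b, a, sep = ":")))
  dimnames(V) <- list(vnames, vnames)

  structure(list(coefficients = B, residuals = E, fitted = fitted,
                 sigma = Sigma, vcov = V, xtxinv = xtxinv,
                 n = n, p = p, df_residual = n - p,
                 sigma_denom = sigma_denom,
                 weights = w, weighted = !is.null(weights),
                 strata = strata, clusters = clusters,
                 X = X),
            class = "mvreg_fit")
}

#' Residual correlation of a fitted two-response model
#' @param fit An `mvreg_fit`.
#' @return The off-diagonal of the residual covariance, standardised.
#' @export
residual_correlation <- function(fit) {
  stopifnot(inherits(fit, "mvreg_fit"))
  S <- fit$sigma
  if (S[1L, 1L] <= 0 || S[2L, 2L] <= 0)
    stop("zero residual variance: residual correlation undefined", call. = FALSE)
  S[1L, 2L] / sqrt(S[1L, 1L] * S[2L, 2L])
}

#' Covariance of the stacked coefficient vector
#'
#' `"iid"` returns \eqn{\hat\Sigma \otimes (X'WX)^{-1}}. `"cluster_robust"`
#' returns the stacked-equation sandwich with scores aggregated at the
#' cluster (PSU) level; when `strata` are supplied, cluster scores are
#' centred within stratum and scaled by \eqn{C_h/(C_h - 1)} per stratum,
#' otherwise the global small-sample factor \eqn{(n-1)/(n-p) \cdot C/(C-1)}
#' is applied. The stacking order matches `fit$vcov`: all p coefficients of
#' the first (SBP) equation, then the second.
#'
#' @param fit An `mvreg_fit`.
#' @param mode `"iid"` or `"cluster_robust"`.
#' @param clusters Per-row cluster labels (defaults to those stored in the
#'   fit); required for robust mode.
#' @param strata Optional per-row stratum labels.
#' @param small_sample Apply the small-sample correction (default TRUE).
#' @return A 2p x 2p covariance matrix.
#' @export
coef_covariance <- function(fit, mode = c("iid", "cluster_robust"),
                            clusters = NULL, strata = NULL,
                            small_sample = TRUE) {
  stopifnot(inherits(fit, "mvreg_fit"))
  mode <- match.arg(mode)
  if (mode == "iid") return(fit$vcov)
  clusters <- clusters %||% fit$clusters
  strata <- strata %||% fit$strata
  if (is.null(clusters))
    stop("cluster_robust mode requires cluster labels", call. = FALSE)
  clusters <- as.character(clusters)
  if (length(clusters) != fit$n)
    stop("cluster labels must have one entry per row used in the fit", call. = FALSE)
  C <- length(unique(clusters))
  if (C < 2L) stop("cluster-robust variance needs at least 2 clusters", call. = FALSE)

  n <- fit$n; p <- fit$p
  U <- cbind(fit$X * (fit$weights * fit$residuals[, 1L]),
             fit$X * (fit$weights * fit$residuals[, 2L]))     # n x 2p scores
  if (is.null(strata)) {
    G <- rowsum(U, clusters)
    M <- crossprod(G)
    if (small_sample) M <- M * (n - 1) / (n - p) * C / (C - 1)
  } else {
    strata <- as.character(strata)
    if (length(strata) != n)
      stop("stratum labels must have one entry per row used in the fit", call. = FALSE)
    M <- matrix(0, 2L * p, 2L * p)
    for (h in unique(strata)) {
      idx <- strata == h
      Gh <- rowsum(U[idx, , drop = FALSE], clusters[idx])
      Ch <- nrow(Gh)
      if (Ch < 2L) next  # singleton-PSU stratum carries no variance information
      Gh <- sweep(Gh, 2L, colMeans(Gh))
      M <- M + crossprod(Gh) * (if (small_sample) Ch / (Ch - 1) else 1)
    }
    if (small_sample) M <- M * (n - 1) / (n - p)
  }
  Ainv <- kronecker(diag(2L), fit$xtxinv)
  V <- Ainv %*% M %*% Ainv
  dimnames(V) <- dimnames(fit$vcov)
  V
}

#' @export
coef.mvreg_fit <- function(object, ...) object$coefficients

#' @export
vcov.mvreg_fit <- function(object, ...) object$vcov

#' @export
residuals.mvreg_fit <- function(object, ...) object$residuals

#' @export
fitted.mvreg_fit <- function(object, ...) object$fitted

#' @export
print.mvreg_fit <- function(x, ...) {
  cat("Two-response linear model (", if (x$weighted) "weighted" else "unweighted",
      "), n = ", x$n, ", p = ", x$p, "\n", sep = "")
  print(round(x$coefficients, 4L))
  rc <- tryCatch(residual_correlation(x), error = function(e) NA_real_)
  cat("Residual correlation: ", round(rc, 4L), "\n", sep = "")
  invisible(x)
}

#' Coefficient table for both equations
#'
#' Per term and equation: estimate, standard error, 95% confidence bounds,
#' t statistic and two-sided p-value using the residual degrees of freedom
#' (or a caller-supplied design df), with the significance marker
#' convention *** p<0.01, ** p<0.05, * p<0.1.
#'
#' @param object An `mvreg_fit`.
#' @param vcov Optional replacement covariance, e.g. from
#'   [coef_covariance()] in cluster-robust mode.
#' @param df Degrees of freedom for the t reference (default: residual df).
#' @param level Confidence level, default 0.95.
#' @param ... Unused.
#' @return A `summary.mvreg_fit` whose `coefficients` element is a
#'   data.frame with columns term, outcome, estimate, se, ci_low, ci_high,
#'   statistic, p_value, sig.
#' @export
summary.mvreg_fit <- function(object, vcov = NULL, df = NULL, level = 0.95, ...) {
  V <- vcov %||% object$vcov
  df <- df %||% object$df_residual
  p <- object$p
  B <- object$coefficients
  se <- matrix(sqrt(pmax(diag(V), 0)), nrow = p, ncol = 2L,
               dimnames = dimnames(B))
  if (any(se == 0))
    warning("degenerate fit: zero standard error for some coefficients", call. = FALSE)
  tval <- ifelse(se > 0, B / se, Inf * sign(B))
  pval <- ifelse(se > 0, 2 * stats::pt(abs(B / se), df, lower.tail = FALSE), 0)
  q <- stats::qt(1 - (1 - level) / 2, df)
  tab <- data.frame(
    term = rep(rownames(B), 2L),
    outcome = rep(colnames(B), each = p),
    estimate = as.vector(B),
    se = as.vector(se),
    ci_low = as.vector(B - q * se),
    ci_high = as.vector(B + q * se),
    statistic = as.vector(tval),
    p_value = as.vector(pval),
    sig = p_stars(as.vector(pval)),
    stringsAsFactors = FALSE)
  rc <- tryCatch(residual_correlation(object), error = function(e) NA_real_)
  structure(list(coefficients = tab, sigma = object$sigma,
                 residual_correlation = rc,
                 n = object$n, p = p, df = df, level = level),
            class = "summary.mvreg_fit")
}

#' @export
print.summary.mvreg_fit <- function(x, ...) {
  cat("Coefficients (t reference on", x$df, "df):\n")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, 2L)
  tab$se <- round(tab$se, 2L)
  tab$ci_low <- round(tab$ci_low, 2L)
  tab$ci_high <- round(tab$ci_high, 2L)
  tab$p_value <- signif(tab$p_value, 3L)
  tab$statistic <- NULL
  print(tab, row.names = FALSE)
  cat("Residual correlation estimate:", round(x$residual_correlation, 4L), "\n")
  invisible(x)
}

#' Residual diagnostics plot
#'
#' Scatter of the two equations' residuals plus normal Q-Q panels.
#'
#' @param x An `mvreg_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mvreg_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, 3L))
  on.exit(graphics::par(op))
  E <- x$residuals
  graphics::plot(E[, 1L], E[, 2L], xlab = paste(colnames(E)[1L], "residual"),
                 ylab = paste(colnames(E)[2L], "residual"),
                 main = "Residual scatter", ...)
  stats::qqnorm(E[, 1L], main = paste(colnames(E)[1L], "Q-Q")); stats::qqline(E[, 1L])
  stats::qqnorm(E[, 2L], main = paste(colnames(E)[2L], "Q-Q")); stats::qqline(E[, 2L])
  invisible(x)
}
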