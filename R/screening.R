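#' Variance inflation factors of a design matrix
#'
#' For each non-intercept column j, regresses it on all other non-intercept
#' columns plus the intercept and reports VIF_j = 1/(1 - R^2_j) together
#' with the tolerance 1/VIF and a retained flag at the configured
#' threshold. Exactly collinear columns get an infinite VIF and an
#' `aliased` flag rather than an error.
#'
#' @param X Design matrix with a leading intercept column, or a
#'   `bp_design`.
#' @param threshold Retention threshold; columns with VIF below it are
#'   flagged retained (default 10).
#' @return A data.frame of class `bp_vif` with columns column, vif,
#'   tolerance, retained, aliased.
#' @export
#' @examples
#' X <- cbind(1, a = rnorm(50), b = rnorm(50))
#' compute_vif(X)
compute_vif <- function(X, threshold = 10) {
  if (inherits(X, "bp_design")) X <- X$X
  X <- as.matrix(X)
  stopifnot(is_scalar_number(threshold), threshold > 0)
  inter <- which(apply(X, 2L, function(x) all(x == 1)))
  if (length(inter) == 0L)
    stop("design matrix must contain an intercept column", call. = FALSE)
  inter <- inter[[1L]]
  pred <- setdiff(seq_len(ncol(X)), inter)
  if (length(pred) < 2L)
    stop("VIF needs at least two non-intercept columns", call. = FALSE)
  cn <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  out <- data.frame(column = cn[pred], vif = NA_real_, tolerance = NA_real_,
                    retained = NA, aliased = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(pred)) {
    j <- pred[[k]]
    y <- X[, j]
    Z <- X[, setdiff(seq_len(ncol(X)), j), drop = FALSE]
    res <- stats::lm.fit(Z, y)$residuals
    tss <- sum((y - mean(y))^2)
    if (tss == 0) { # constant column: undefined, flag as aliased
      out$vif[k] <- Inf; out$aliased[k] <- TRUE; next
    }
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) {
      out$vif[k] <- Inf; out$aliased[k] <- TRUE
    } else {
      out$vif[k] <- 1 / (1 - r2)
    }
  }
  out$tolerance <- 1 / out$vif
  out$retained <- is.finite(out$vif) & out$vif < threshold
  class(out) <- c("bp_vif", "data.frame")
  out
}

#' Exploratory per-predictor screen of candidate terms
#'
#' Fits, for each candidate alone (plus intercept), the two-response model
#' and computes one p-value per equation: the joint F over the candidate's
#' design-column block within that equation (so multi-level categorical
#' candidates are judged as a block, not by their best level). A candidate
#' is retained when either equation's p-value is at or below the threshold
#' (default 0.20). Estimation failures for individual candidates are
#' recorded, not fatal.
#'
#' @param cohort Cohort data.
#' @param candidates Character vector of term names to screen; defaults to
#'   every term in `spec`.
#' @param spec A [model_spec()] supplying outcomes and term declarations.
#' @param threshold Retention p-value threshold in (0, 1].
#' @param block `"joint"` (default: block F per equation) or `"min_level"`
#'   (smallest level-wise p per equation).
#' @return A data.frame of class `bp_screen` with columns term, p_sbp,
#'   p_dbp, retained, error.
#' @export
exploratory_screen <- function(cohort, candidates = NULL, spec = steps_model_spec(),
                               threshold = 0.20, block = c("joint", "min_level")) {
  stopifnot(is.data.frame(cohort), inherits(spec, "bp_model_spec"),
            is_scalar_number(threshold), threshold > 0, threshold <= 1)
  block <- match.arg(block)
  candidates <- candidates %||% names(spec$terms)
  unknown <- setdiff(candidates, names(spec$terms))
  if (length(unknown))
    stop("candidates not declared in the model spec: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- data.frame(term = candidates, p_sbp = NA_real_, p_dbp = NA_real_,
                    retained = NA, error = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    sub <- spec
    sub$terms <- spec$terms[cand]
    sub$stratum <- sub$psu <- NULL
    res <- tryCatch({
      fit <- fit_mvreg(encode_model(cohort, sub))
      term_block_p(fit, block)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out$error[k] <- res
    } else {
      out$p_sbp[k] <- res[[1L]]
      out$p_dbp[k] <- res[[2L]]
      out$retained[k] <- min(res) <= threshold
    }
  }
  attr(out, "threshold") <- threshold
  class(out) <- c("bp_screen", "data.frame")
  out
}

# per-equation p-value for the non-intercept block of a single-candidate fit
term_block_p <- function(fit, block) {
  idx <- which(rownames(fit$coefficients) != "(Intercept)")
  q <- length(idx)
  if (q == 0L) stop("candidate contributes no design columns", call. = FALSE)
  vapply(1:2, function(eq) {
    b <- fit$coefficients[idx, eq]
    Vb <- fit$sigma[eq, eq] * fit$xtxinv[idx, idx, drop = FALSE]
    if (block == "joint") {
      stat <- as.numeric(crossprod(b, solve(Vb, b))) / q
      stats::pf(stat, q, fit$df_residual, lower.tail = FALSE)
    } else {
      tv <- abs(b) / sqrt(diag(Vb))
      min(2 * stats::pt(tv, fit$df_residual, lower.tail = FALSE))
    }
  }, numeric(1L))
}
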