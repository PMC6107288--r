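## Nodewise-regression inference engines.  All three regression-based
## methods share the same first step — p nodewise lasso-type regressions in
## Gram form — and differ only in how the second-step statistics are built
## from the residual moments.

#' Fit all nodewise regressions
#'
#' Regresses each gene on all remaining genes with either the scaled lasso
#' (tuning-free, default penalty `sqrt(2 * log(p) / n)`) or the plain lasso
#' at a fixed penalty.  The p x p second-moment matrix is computed once and
#' shared by all p sub-problems.
#'
#' @param x Centered expression matrix (see [preprocess()]).
#' @param regression `"scaled_lasso"` or `"lasso"`.
#' @param lambda Penalty: the scale-free `lambda0` for the scaled lasso
#'   (default `sqrt(2 * log(p) / n)`) or the fixed lasso penalty.
#' @param beta_init Optional `p x p` warm-start coefficient matrix (column
#'   `i` holds the coefficients for node `i`).
#' @param config A [solver_config()].
#' @return Object of class `"ggm_nodewise"`: list with `beta` (`p x p`,
#'   `beta[k, i]` = coefficient of gene `k` in the regression of gene `i`,
#'   zero diagonal), `sigma_hat`, `lambda_used`, `residuals` (`n x p`),
#'   `n`, `gram` (the shared second-moment matrix) and `gene_names`.
#' @export
fit_all_nodewise <- function(x, regression = c("scaled_lasso", "lasso"),
                             lambda = NULL, beta_init = NULL,
                             config = solver_config()) {
  regression <- match.arg(regression)
  n <- nrow(x); p <- ncol(x)
  if (max(abs(colMeans(x))) > 1e-8)
    stop("data must be centered; call preprocess() first", call. = FALSE)
  S <- crossprod(x) / n
  if (is.null(lambda)) {
    if (regression == "lasso")
      stop("'lambda' must be supplied for regression = \"lasso\"",
           call. = FALSE)
    lambda <- sqrt(2 * log(p) / n)
  }
  if (is.null(beta_init)) beta_init <- matrix(0, p, p)
  mode <- if (regression == "lasso") 0L else 1L
  fit <- nodewise_cpp(S, n, mode, lambda, lambda, beta_init,
                      config$tol, config$max_iter, config$outer_tol,
                      config$outer_max_iter, config$sigma_floor)
  if (length(fit$degenerate))
    stop("degenerate response for gene(s): ",
         paste(colnames(x)[fit$degenerate], collapse = ", "),
         " (residual scale below floor)", call. = FALSE)
  if (!all(fit$converged))
    warning("nodewise lasso did not converge for ",
            sum(!fit$converged), " gene(s)", call. = FALSE)
  res <- x - x %*% fit$beta
  structure(list(beta = fit$beta, sigma_hat = as.numeric(fit$sigma),
                 lambda_used = as.numeric(fit$lambda_used),
                 residuals = res, n = n, gram = S,
                 regression = regression, gene_names = colnames(x)),
            class = "ggm_nodewise")
}

#' Residual second moments of the nodewise fits
#'
#' @param fits A `"ggm_nodewise"` object.
#' @return Symmetric `p x p` matrix with entry `(i, j)` equal to
#'   `crossprod(resid_i, resid_j) / n`.
#' @export
residual_moments <- function(fits) {
  stopifnot(inherits(fits, "ggm_nodewise"))
  R <- crossprod(fits$residuals) / fits$n
  (R + t(R)) / 2
}

#' First-order bias correction of the residual moments
#'
#' Removes the shrinkage bias of the raw residual cross-moments: for
#' `i != j`, `rtilde_ij = -(rhat_ij + rhat_ii * b[i, j] + rhat_jj * b[j, i])`
#' where `b[i, j]` is the coefficient of gene `i` in the regression of gene
#' `j`.  The de-biased precision estimates are
#' `omega_ij = rtilde_ij / (rhat_ii * rhat_jj)` with diagonal
#' `omega_ii = 1 / rhat_ii`.  At the population values the correction is an
#' exact fixed point.
#'
#' @param moments Matrix from [residual_moments()].
#' @param fits The `"ggm_nodewise"` object the moments came from.
#' @return List with `omega` (`p x p` de-biased estimates, true diagonal)
#'   and `rtilde` (`p x p` bias-corrected moments, diagonal = `rhat` diag).
#' @export
bias_corrected_estimates <- function(moments, fits) {
  stopifnot(inherits(fits, "ggm_nodewise"))
  d <- diag(moments)
  if (any(d <= 0)) stop("non-positive residual variance", call. = FALSE)
  B <- fits$beta
  ## (d * B)[i, j] = rhat_ii * beta[i, j]; its transpose gives the j-term
  rtilde <- -(moments + d * B + t(d * B))
  omega <- rtilde / outer(d, d)
  diag(omega) <- 1 / d
  diag(rtilde) <- d
  dimnames(omega) <- dimnames(rtilde) <- list(fits$gene_names,
                                              fits$gene_names)
  list(omega = (omega + t(omega)) / 2, rtilde = (rtilde + t(rtilde)) / 2)
}

## assemble the individual-inference surfaces from a symmetric de-biased
## estimate: the variance of each entry is the inverse Fisher information
## (omega_ii * omega_jj + omega_ij^2) / n
build_inference_result <- function(method, omega, n, ci_level = 0.95,
                                   scale_factors = NULL, gene_names = NULL) {
  p <- ncol(omega)
  diag_prec <- diag(omega)
  se <- sqrt((outer(diag_prec, diag_prec) + omega^2) / n)
  if (!is.null(scale_factors)) {
    omega <- rescale_precision(omega, scale_factors)
    se <- rescale_precision(se, scale_factors)
    diag_prec <- diag(omega)
  }
  est <- omega; diag(est) <- 0
  z <- est / se; diag(z) <- 0
  pval <- 2 * pnorm(-abs(z)); diag(pval) <- 0
  q <- qnorm((1 + ci_level) / 2)
  lo <- est - q * se; hi <- est + q * se
  diag(lo) <- diag(hi) <- 0
  diag(se) <- 0  # display form: all surfaces carry a zero diagonal
  nm <- list(gene_names, gene_names)
  dimnames(est) <- dimnames(se) <- dimnames(z) <- nm
  dimnames(pval) <- dimnames(lo) <- dimnames(hi) <- nm
  structure(list(method = method, estimate = est, std_err = se, z_score = z,
                 p_value = pval, ci_low = lo, ci_high = hi,
                 ci_level = ci_level, diag_precision = diag_prec,
                 n = n, p = p, gene_names = gene_names),
            class = "ggm_inference")
}

#' Bivariate nodewise scaled-lasso inference (B_NW_SL)
#'
#' Asymptotically efficient entrywise inference on the precision matrix via
#' p nodewise scaled-lasso regressions followed by first-order bias
#' correction of the residual moments.  Each standardized estimate is
#' asymptotically normal with variance equal to the inverse Fisher
#' information, yielding entrywise confidence intervals and p-values.
#'
#' @param x Centered (optionally standardized) expression matrix from
#'   [preprocess()].
#' @param lambda0 Scale-free scaled-lasso penalty; default
#'   `sqrt(2 * log(p) / n)`.
#' @param ci_level Confidence level, default 0.95.
#' @param config A [solver_config()].
#' @return A `"ggm_inference"` object: `p x p` symmetric matrices
#'   `estimate`, `std_err`, `z_score`, `p_value`, `ci_low`, `ci_high`
#'   (zero diagonal in display form) and `diag_precision`.
#' @export
b_nw_sl <- function(x, lambda0 = NULL, ci_level = 0.95,
                    config = solver_config()) {
  fits <- fit_all_nodewise(x, "scaled_lasso", lambda = lambda0,
                           config = config)
  bc <- bias_corrected_estimates(residual_moments(fits), fits)
  build_inference_result("B_NW_SL", bc$omega, fits$n, ci_level,
                         scale_factors = attr(x, "scale"),
                         gene_names = fits$gene_names)
}

#' De-sparsified nodewise scaled-lasso inference (D-S_NW_SL)
#'
#' Builds the relaxed-inverse matrix `Theta` from the nodewise scaled-lasso
#' fits (`Theta[j, j] = 1 / sigma_j^2`,
#' `Theta[k, j] = -beta[k, j] / sigma_j^2`) and removes the first-order
#' shrinkage bias by `Omega = Theta + t(Theta) - t(Theta) S Theta`, with
#' the triple product evaluated over the non-zeros of `Theta` only.  With
#' `n > p` and no penalty the de-sparsification is a fixed point at the
#' inverse sample covariance.
#'
#' @inheritParams b_nw_sl
#' @return A `"ggm_inference"` object.
#' @export
ds_nw_sl <- function(x, lambda0 = NULL, ci_level = 0.95,
                     config = solver_config()) {
  fits <- fit_all_nodewise(x, "scaled_lasso", lambda = lambda0,
                           config = config)
  s2 <- fits$sigma_hat^2
  Theta <- -sweep(fits$beta, 2, s2, "/")
  diag(Theta) <- 1 / s2
  Omega <- Theta + t(Theta) - sparse_quadform(Theta, fits$gram)
  Omega <- (Omega + t(Omega)) / 2
  build_inference_result("D-S_NW_SL", Omega, fits$n, ci_level,
                         scale_factors = attr(x, "scale"),
                         gene_names = fits$gene_names)
}

#' Standardized bias-corrected test statistics (GFC_SL / GFC_L)
#'
#' The FDR-oriented test statistics
#' `T_ij = sqrt(n) * rtilde_ij / sqrt(rhat_ii * rhat_jj)`, asymptotically
#' standard normal under the null `omega_ij = 0`.  With scaled-lasso
#' regressions this is the tuning-free GFC_SL statistic; with plain lasso
#' regressions at a supplied penalty it is the GFC_L statistic.
#'
#' @param x Centered expression matrix.
#' @param regression `"scaled_lasso"` or `"lasso"`.
#' @param lambda Penalty passed to [fit_all_nodewise()].
#' @param beta_init Optional warm-start coefficient matrix.
#' @param config A [solver_config()].
#' @return Object of class `"ggm_statistics"`: list with `T` (`p x p`
#'   symmetric, zero diagonal), `method`, `n`, `p`, `gene_names`, and the
#'   nodewise `beta` for warm-starting.
#' @export
gfc_statistics <- function(x, regression = c("scaled_lasso", "lasso"),
                           lambda = NULL, beta_init = NULL,
                           config = solver_config()) {
  regression <- match.arg(regression)
  fits <- fit_all_nodewise(x, regression, lambda = lambda,
                           beta_init = beta_init, config = config)
  moments <- residual_moments(fits)
  bc <- bias_corrected_estimates(moments, fits)
  d <- diag(moments)
  Tm <- sqrt(fits$n) * bc$rtilde / sqrt(outer(d, d))
  diag(Tm) <- 0
  Tm <- (Tm + t(Tm)) / 2
  stopifnot(all(is.finite(Tm)))
  structure(list(T = Tm,
                 method = if (regression == "scaled_lasso") "GFC_SL"
                          else "GFC_L",
                 n = fits$n, p = ncol(Tm), gene_names = fits$gene_names,
                 beta = fits$beta, lambda_used = fits$lambda_used),
            class = "ggm_statistics")
}
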