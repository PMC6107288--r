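## Conventional comparison methods: marginal Pearson correlation with the
## Fisher z-transformation, and the maximum-likelihood partial correlation
## from the inverted sample covariance.  Both produce asymptotically
## standard-normal statistic matrices that plug into the same global FDR
## machinery as the GGM inference methods.

#' Fisher-z statistics of marginal Pearson correlations
#'
#' `z_ij = sqrt(n - 3) * atanh(r_ij)` for the sample Pearson correlation
#' `r_ij`.
#'
#' @param x Expression matrix (samples x genes), `n >= 4`.
#' @return A `"ggm_statistics"` object with the symmetric z-score matrix.
#' @export
pearson_fisher_z <- function(x) {
  x <- as_expression_matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need n >= 4 for the Fisher z-transformation", call. = FALSE)
  r <- cor(x)
  diag(r) <- 0
  bad <- which(abs(r) >= 1 - 1e-12, arr.ind = TRUE)
  if (nrow(bad))
    stop("perfectly correlated gene pair: ",
         colnames(x)[bad[1, 1]], " / ", colnames(x)[bad[1, 2]],
         call. = FALSE)
  z <- sqrt(n - 3) * atanh(r)
  structure(list(T = z, method = "PearsonCorr", n = n, p = ncol(x),
                 gene_names = colnames(x)),
            class = "ggm_statistics")
}

#' Fisher-z statistics of MLE partial correlations
#'
#' Inverts the sample covariance (`n > p` required), converts to partial
#' correlations `rho_ij = -omega_ij / sqrt(omega_ii * omega_jj)` and
#' applies the Fisher z-transformation with the conditioning-set
#' degrees-of-freedom correction `z_ij = sqrt(n - p - 1) * atanh(rho_ij)`.
#'
#' @param x Expression matrix with `n > p` and non-singular sample
#'   covariance.
#' @param df Degrees of freedom for the z-scores; default `n - p - 1`.
#' @return A `"ggm_statistics"` object; element `partial_cor` holds the
#'   partial-correlation matrix.
#' @export
mle_partial <- function(x, df = NULL) {
  x <- as_expression_matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p)
    stop("MLE requires n > p (sample covariance not invertible)",
         call. = FALSE)
  S <- cov(x)
  Omega <- tryCatch(solve(S), error = function(e)
    stop("sample covariance is singular", call. = FALSE))
  d <- sqrt(diag(Omega))
  rho <- -Omega / outer(d, d)
  diag(rho) <- 0
  rho <- (rho + t(rho)) / 2
  if (is.null(df)) df <- n - p - 1
  z <- sqrt(df) * atanh(pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15))
  dimnames(z) <- dimnames(rho) <- list(colnames(x), colnames(x))
  structure(list(T = z, method = "MLE", n = n, p = p,
                 gene_names = colnames(x), partial_cor = rho),
            class = "ggm_statistics")
}
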