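# Independent oracles and small fixture builders shared across tests.

# Lasso oracle: minimize the convex objective directly via L-BFGS-B on the
# positive/negative split (smooth bound-constrained reformulation), fully
# independent of the coordinate-descent path.
lasso_oracle <- function(gram, xty, lambda) {
  p <- length(xty)
  f <- function(uv) {
    b <- uv[1:p] - uv[(p + 1):(2 * p)]
    0.5 * sum(b * (gram %*% b)) - sum(b * xty) + lambda * sum(uv)
  }
  g <- function(uv) {
    b <- uv[1:p] - uv[(p + 1):(2 * p)]
    gr <- gram %*% b - xty
    c(gr + lambda, -gr + lambda)
  }
  o <- optim(rep(0, 2 * p), f, g, method = "L-BFGS-B", lower = 0,
             control = list(maxit = 5000, factr = 10))
  o$par[1:p] - o$par[(p + 1):(2 * p)]
}

# Brute-force FDR threshold: exhaustive scan over all jump points.
brute_fdr_threshold <- function(T, alpha) {
  p <- ncol(T)
  m <- p * (p - 1) / 2
  a <- abs(T[upper.tri(T)])
  cand <- sort(unique(c(0, a[a <= sqrt(2 * log(p))])))
  f <- vapply(cand, function(t) 2 * pnorm(-t) * m / max(sum(a >= t), 1),
              numeric(1))
  ok <- which(f <= alpha)
  t_hat <- if (length(ok)) cand[min(ok)] else 2 * sqrt(log(p))
  fe <- 2 * pnorm(-t_hat) * m / max(sum(a >= t_hat), 1)
  list(threshold = t_hat, fdr_estimate = min(fe, 1))
}

# Partial correlation by the regression-residual definition: correlate the
# residuals of i and j each regressed (OLS) on all remaining variables.
partial_cor_residual_oracle <- function(x) {
  p <- ncol(x)
  out <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- setdiff(seq_len(p), c(i, j))
      ri <- lm.fit(cbind(1, x[, others]), x[, i])$residuals
      rj <- lm.fit(cbind(1, x[, others]), x[, j])$residuals
      out[i, j] <- out[j, i] <- cor(ri, rj)
    }
  }
  out
}

# Gram-form problem from raw (X, y), as the solvers expect.
gram_problem <- function(X, y) {
  n <- nrow(X)
  list(gram = crossprod(X) / n, xty = drop(crossprod(X, y)) / n,
       yty = sum(y^2) / n, n = n)
}

# A random symmetric PD matrix.
random_pd <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) / p + diag(p)
}

upper_vals <- function(M) M[upper.tri(M)]
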