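## Convex solvers shared by all inference engines.  All lasso-type problems
## are handled in Gram ("covariance") form: the second-moment matrices
## G = X'X/n, c = X'y/n, yty = y'y/n are computed once and the coordinate
## descent never touches the raw data again.

#' Solver configuration for the coordinate-descent core
#'
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change per full cyclic sweep.
#' @param max_iter Iteration (sweep) cap for one lasso solve.
#' @param outer_tol Tolerance on the noise-scale change for the scaled-lasso
#'   outer loop.
#' @param outer_max_iter Cap on scaled-lasso outer iterations.
#' @param sigma_floor Smallest admissible noise scale; a fit collapsing below
#'   it is treated as a degenerate (near-perfectly predictable) response.
#' @return A list of class `"ggm_solver_config"`.
#' @export
solver_config <- function(tol = 1e-6, max_iter = 10000, outer_tol = 1e-6,
                          outer_max_iter = 100, sigma_floor = 1e-8) {
  stopifnot(tol > 0, max_iter >= 1, outer_tol > 0, outer_max_iter >= 1)
  structure(list(tol = tol, max_iter = max_iter, outer_tol = outer_tol,
                 outer_max_iter = outer_max_iter, sigma_floor = sigma_floor),
            class = "ggm_solver_config")
}

check_gram <- function(gram, xty, lambda) {
  if (!is.matrix(gram) || nrow(gram) != ncol(gram))
    stop("'gram' must be a square matrix", call. = FALSE)
  if (!all(is.finite(gram)) || !all(is.finite(xty)))
    stop("non-finite values in lasso problem inputs", call. = FALSE)
  if (max(abs(gram - t(gram))) > 1e-8)
    stop("'gram' must be symmetric", call. = FALSE)
  if (length(xty) != ncol(gram))
    stop("length(xty) must equal ncol(gram)", call. = FALSE)
  if (lambda < 0) stop("'lambda' must be non-negative", call. = FALSE)
}

#' Lasso by cyclical coordinate descent with covariance updates
#'
#' Solves `min_b 0.5 * b' G b - b' c + lambda * ||b||_1` for a Gram matrix
#' `G = X'X/n` and moment vector `c = X'y/n`, i.e. the lasso objective
#' `||y - X b||^2 / (2n) + lambda ||b||_1` up to a constant.  Coordinates are
#' visited in fixed ascending order; the fitted inner products are updated
#' incrementally at each coefficient change.
#'
#' @param gram Symmetric positive semi-definite `p x p` matrix `X'X/n`.
#' @param xty Length-`p` vector `X'y/n`.
#' @param lambda Non-negative penalty.
#' @param beta_init Optional warm-start coefficient vector.
#' @param config A [solver_config()].
#' @return Numeric coefficient vector with attributes `iter` and
#'   `converged`; a warning is raised (and the result still returned) when
#'   the iteration cap is hit.
#' @export
lasso_cd <- function(gram, xty, lambda, beta_init = NULL,
                     config = solver_config()) {
  check_gram(gram, xty, lambda)
  p <- ncol(gram)
  if (is.null(beta_init)) beta_init <- numeric(p)
  stopifnot(length(beta_init) == p, all(is.finite(beta_init)))
  fit <- cd_lasso_cpp(gram, as.numeric(xty), lambda, as.numeric(beta_init),
                      config$tol, config$max_iter)
  if (!fit$converged)
    warning("lasso_cd did not converge in ", config$max_iter, " sweeps",
            call. = FALSE)
  structure(as.numeric(fit$beta), iter = fit$iter, converged = fit$converged)
}

#' Scaled lasso: joint estimation of coefficients and noise scale
#'
#' Alternates a lasso solve at effective penalty `lambda0 * sigma_hat` with
#' the update `sigma_hat <- RMS(residual)` until the noise scale stabilises.
#' The returned scale uses denominator `sqrt(n)` (no degrees-of-freedom
#' correction), so that with `lambda0 = 0` and `n > p` the nodewise fits
#' reproduce the inverse sample covariance exactly.
#'
#' @inheritParams lasso_cd
#' @param yty Scalar `y'y/n`.
#' @param lambda0 Scale-free penalty (> 0); the effective lasso penalty is
#'   `lambda0 * sigma_hat`.
#' @return List with `beta`, `sigma_hat`, `lambda_used`, `converged`.
#' @export
scaled_lasso <- function(gram, xty, yty, lambda0, beta_init = NULL,
                         config = solver_config()) {
  check_gram(gram, xty, 0)
  stopifnot(lambda0 > 0, is.finite(yty), yty >= 0)
  p <- ncol(gram)
  beta <- if (is.null(beta_init)) numeric(p) else as.numeric(beta_init)
  sigma <- sqrt(yty)
  if (sigma <= config$sigma_floor)
    stop("degenerate response: noise scale at or below floor", call. = FALSE)
  conv <- FALSE
  lam <- lambda0 * sigma
  for (it in seq_len(config$outer_max_iter)) {
    lam <- lambda0 * sigma
    beta <- lasso_cd(gram, xty, lam, beta_init = beta, config = config)
    rss <- yty - 2 * sum(beta * xty) + drop(crossprod(beta, gram %*% beta))
    sigma_new <- sqrt(max(rss, 0))
    if (sigma_new <= config$sigma_floor)
      stop("degenerate response: noise scale collapsed below floor",
           call. = FALSE)
    done <- abs(sigma_new - sigma) < config$outer_tol
    sigma <- sigma_new
    if (done) { conv <- TRUE; break }
  }
  list(beta = as.numeric(beta), sigma_hat = sigma, lambda_used = lam,
       converged = conv)
}

#' Graphical lasso: L1-penalized precision-matrix estimation
#'
#' Maximizes `log det(Omega) - tr(S Omega) - lambda * ||Omega||_{1,off}` by
#' block coordinate descent: each column of the working covariance is
#' updated by a lasso regression solved with [lasso_cd()].  Only
#' off-diagonal entries are penalized.
#'
#' @param S Symmetric `p x p` sample covariance with positive diagonal.
#' @param lambda Non-negative penalty (`> 0` required when `S` is singular).
#' @param config A [solver_config()].
#' @param gap_tol Duality-gap tolerance used as the outer stopping rule.
#' @param max_outer Cap on outer passes over the columns.
#' @return Symmetric positive-definite precision estimate with attribute
#'   `dual_gap`.
#' @export
graphical_lasso <- function(S, lambda, config = solver_config(),
                            gap_tol = 1e-6, max_outer = 200) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-8) stop("'S' must be symmetric", call. = FALSE)
  if (any(diag(S) <= 0)) stop("'S' must have positive diagonal", call. = FALSE)
  if (lambda < 0) stop("'lambda' must be non-negative", call. = FALSE)
  p <- ncol(S)
  S <- (S + t(S)) / 2

  if (lambda == 0) {
    Omega <- tryCatch(solve(S), error = function(e)
      stop("'S' is singular; a positive 'lambda' is required", call. = FALSE))
    Omega <- (Omega + t(Omega)) / 2
    return(structure(Omega, dual_gap = 0))
  }

  ## working covariance W tracks the dual variable; diagonal unpenalized
  W <- S
  B <- matrix(0, p, p)  # column-wise lasso coefficients
  gap <- Inf
  for (outer in seq_len(max_outer)) {
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      b <- lasso_cd(W11, s12, lambda, beta_init = B[idx, j], config = config)
      B[idx, j] <- as.numeric(b)
      W[idx, j] <- W11 %*% B[idx, j]
      W[j, idx] <- W[idx, j]
    }
    Omega <- w_to_omega(W, B, S)
    gap <- glasso_gap(Omega, S, lambda)
    if (is.finite(gap) && abs(gap) < gap_tol) break
  }
  if (!is.finite(gap) || abs(gap) >= gap_tol)
    warning("graphical_lasso: duality gap ", format(gap),
            " above tolerance after ", max_outer, " passes", call. = FALSE)
  ev <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("graphical_lasso produced a non-PD estimate", call. = FALSE)
  structure(Omega, dual_gap = gap)
}

## recover Omega from the working covariance and the column regressions:
## omega_jj = 1 / (w_jj - w12' b), omega_12 = -b * omega_jj
w_to_omega <- function(W, B, S) {
  p <- ncol(W)
  Omega <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    ojj <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
    Omega[j, j] <- ojj
    Omega[idx, j] <- -B[idx, j] * ojj
  }
  (Omega + t(Omega)) / 2
}

## duality gap of the penalized log-det problem: tr(S Omega) - p +
## lambda * ||Omega||_{1,off}; zero at the optimum.
glasso_gap <- function(Omega, S, lambda) {
  p <- ncol(S)
  sum(S * Omega) - p + lambda * (sum(abs(Omega)) - sum(abs(diag(Omega))))
}

#' Sparsity-aware triple product `t(Theta) %*% Sigma %*% Theta`
#'
#' Iterates only over the non-zero entries of the columns of `Theta`,
#' reducing the `O(p^3)` dense cost to `O(s p^2)` for column sparsity `s`.
#'
#' @param Theta `p x q` matrix, typically a sparse regularized estimate.
#' @param Sigma `p x p` covariance matrix.
#' @return The `q x q` product, equal to the dense evaluation.
#' @export
sparse_quadform <- function(Theta, Sigma) {
  if (!is.matrix(Theta) || !is.matrix(Sigma) ||
      nrow(Sigma) != ncol(Sigma) || nrow(Theta) != nrow(Sigma))
    stop("shape mismatch between 'Theta' and 'Sigma'", call. = FALSE)
  sparse_quadform_cpp(Theta, Sigma)
}
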