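## Global simultaneous inference over all (p^2 - p)/2 gene pairs: the
## statistic-thresholding FDR procedure shared by all methods, and the
## penalty selection for the tuned-lasso variant.

upper_tri_vals <- function(M) M[upper.tri(M)]

#' FDR threshold for a matrix of asymptotically normal statistics
#'
#' Finds the smallest threshold `t` in `[0, sqrt(2 log p)]` such that the
#' estimated false discovery proportion
#' `G(t) * (p^2 - p) / 2 / max(R(t), 1)` is at most `alpha`, where
#' `G(t) = 2 * (1 - pnorm(t))` is the two-sided null tail and `R(t)` counts
#' pairs with `|T_ij| >= t` in the upper triangle.  The search is exact
#' over the finite candidate set `{0}` and the observed `|T_ij|` (the FDP
#' estimate only jumps there).  When no candidate qualifies the
#' Bonferroni-flavoured fallback `2 * sqrt(log p)` is returned.
#'
#' @param T Symmetric `p x p` statistic matrix (or a `"ggm_statistics"`
#'   object).
#' @param alpha Nominal FDR level in (0, 1).
#' @param fallback Threshold used when no candidate qualifies; default
#'   `2 * sqrt(log(p))`.
#' @return List with `threshold` and `fdr_estimate` (capped at 1).
#' @export
fdr_threshold <- function(T, alpha, fallback = NULL) {
  if (inherits(T, "ggm_statistics")) T <- T$T
  stopifnot(is.matrix(T), nrow(T) == ncol(T))
  p <- ncol(T)
  if (p < 3) stop("need p >= 3 for multiplicity control", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  m <- p * (p - 1) / 2
  a <- abs(upper_tri_vals(T))
  cand <- sort(unique(c(0, a[a <= sqrt(2 * log(p))])))
  ## R(t) via one pass over the sorted statistics
  sorted <- sort(a)
  Rt <- function(t) m - findInterval(t, sorted, left.open = TRUE)
  fdp <- function(t) 2 * pnorm(-t) * m / max(Rt(t), 1)
  vals <- vapply(cand, fdp, numeric(1))
  ok <- which(vals <= alpha)
  if (length(ok)) {
    t_hat <- cand[min(ok)]
  } else {
    t_hat <- if (is.null(fallback)) 2 * sqrt(log(p)) else fallback
  }
  list(threshold = t_hat, fdr_estimate = min(fdp(t_hat), 1))
}

#' Global inference: decision matrices with FDR control
#'
#' Applies [fdr_threshold()] at each level in `alphas` and converts the
#' statistic matrix into per-level binary adjacency decisions
#' (`|T_ij| >= t_hat(alpha)`, ties rejected).  With a known true graph the
#' empirical power (correctly identified true edges / total true edges) is
#' reported per level.
#'
#' @param T Symmetric statistic matrix or `"ggm_statistics"` object.
#' @param alphas Ascending FDR levels in (0, 1); default `c(0.05, 0.1)`.
#' @param true_graph Optional `p x p` binary adjacency of the true graph.
#' @return Object of class `"ggm_global"`: `alphas`, `thresholds`
#'   (non-increasing in alpha), `fdr_estimates`, `decisions` (list of
#'   `p x p` 0/1 symmetric matrices, zero diagonal, nested across alphas)
#'   and optionally `power`.
#' @export
globalize <- function(T, alphas = c(0.05, 0.1), true_graph = NULL) {
  gene_names <- NULL
  method <- NULL
  if (inherits(T, "ggm_statistics")) {
    gene_names <- T$gene_names; method <- T$method; T <- T$T
  }
  stopifnot(is.matrix(T), nrow(T) == ncol(T))
  if (any(alphas <= 0 | alphas >= 1))
    stop("alphas must lie in (0, 1)", call. = FALSE)
  alphas <- sort(alphas)
  p <- ncol(T)
  if (!is.null(true_graph)) {
    if (!is.matrix(true_graph) || any(dim(true_graph) != c(p, p)))
      stop("true_graph shape mismatch", call. = FALSE)
  }
  th <- fdr <- pow <- numeric(length(alphas))
  dec <- vector("list", length(alphas))
  names(dec) <- format(alphas, trim = TRUE)
  for (k in seq_along(alphas)) {
    res <- fdr_threshold(T, alphas[k])
    th[k] <- res$threshold
    fdr[k] <- res$fdr_estimate
    D <- (abs(T) >= th[k]) * 1L
    diag(D) <- 0L
    if (!is.null(gene_names)) dimnames(D) <- list(gene_names, gene_names)
    dec[[k]] <- D
    if (!is.null(true_graph)) {
      truth <- upper_tri_vals(true_graph != 0)
      hits <- upper_tri_vals(D == 1) & truth
      pow[k] <- if (sum(truth)) sum(hits) / sum(truth) else NA_real_
    }
  }
  structure(list(method = method, alphas = alphas, thresholds = th,
                 fdr_estimates = fdr, decisions = dec,
                 power = if (is.null(true_graph)) NULL else pow,
                 gene_names = gene_names),
            class = "ggm_global")
}

#' Penalty selection for the tuned-lasso statistics (GFC_L)
#'
#' Runs the lasso nodewise statistics over a decreasing penalty grid
#' (warm-starting each fit from the previous penalty) and selects the
#' penalty whose statistics best match the standard-normal null in the
#' moderate tail: minimize
#' `sum_s (R(q_s) / (G(q_s) * m) - 1)^2`, `s = 1..10`, where
#' `q_s = qnorm(1 - alpha_s)` with
#' `alpha_s = s * (1 - pnorm(sqrt(log(p)))) / 10`, `G(q) = 2 (1 - pnorm(q))`
#' is the expected two-sided null tail and `m = (p^2 - p)/2`.
#'
#' @param x Centered expression matrix.
#' @param lambda_grid Decreasing penalty grid; default
#'   `k/20 * sqrt(log(p)/n)` for `k = 40..1`.
#' @param config A [solver_config()].
#' @return List with `lambda` (selected penalty), `statistics` (the
#'   `"ggm_statistics"` object at that penalty) and `criterion` (per-grid
#'   values).
#' @export
gfc_l_select <- function(x, lambda_grid = NULL, config = solver_config()) {
  n <- nrow(x); p <- ncol(x)
  if (is.null(lambda_grid))
    lambda_grid <- (40:1) / 20 * sqrt(log(p) / n)
  if (!length(lambda_grid)) stop("empty lambda grid", call. = FALSE)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  m <- p * (p - 1) / 2
  alpha_s <- (1:10) * (1 - pnorm(sqrt(log(p)))) / 10
  q_s <- qnorm(1 - alpha_s)
  expected <- 2 * alpha_s * m

  crit <- numeric(length(lambda_grid))
  stats <- vector("list", length(lambda_grid))
  beta_warm <- NULL
  for (k in seq_along(lambda_grid)) {
    st <- gfc_statistics(x, "lasso", lambda = lambda_grid[k],
                         beta_init = beta_warm, config = config)
    beta_warm <- st$beta
    a <- abs(upper_tri_vals(st$T))
    Rq <- vapply(q_s, function(q) sum(a >= q), numeric(1))
    crit[k] <- sum((Rq / expected - 1)^2)
    stats[[k]] <- st
  }
  best <- which.min(crit)
  list(lambda = lambda_grid[best], statistics = stats[[best]],
       criterion = crit, lambda_grid = lambda_grid)
}
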