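#' Statistical inference for a large-scale Gaussian graphical model
#'
#' The main fitting function: takes an `n x p` expression matrix (samples
#' in rows, genes in columns), runs one of five inference methods, and
#' optionally extends it to global simultaneous inference with FDR
#' control.
#'
#' Methods:
#' \describe{
#'   \item{B_NW_SL}{bivariate nodewise scaled lasso — entrywise estimates,
#'     confidence intervals and p-values ([b_nw_sl()]).}
#'   \item{D-S_NW_SL}{de-sparsified nodewise scaled lasso ([ds_nw_sl()]).}
#'   \item{D-S_GL}{de-sparsified graphical lasso ([ds_gl()]).}
#'   \item{GFC_SL}{bias-corrected residual-covariance statistics with
#'     scaled-lasso regressions; statistics and p-values only
#'     ([gfc_statistics()]).}
#'   \item{GFC_L}{the same statistics with plain-lasso regressions and a
#'     null-calibration tuning selection ([gfc_l_select()]).}
#' }
#' All five produce asymptotically standard-normal statistics, so any of
#' them feeds the statistic-thresholding FDR procedure ([globalize()]).
#' GFC_SL / GFC_L are always reported with global decisions; for the other
#' three `global = TRUE` adds them.
#'
#' @param x Numeric `n x p` expression matrix.
#' @param method One of `"B_NW_SL"`, `"D-S_NW_SL"`, `"D-S_GL"`,
#'   `"GFC_SL"`, `"GFC_L"`.
#' @param lambda Penalty: `"auto"` (default) uses `sqrt(2 log(p)/n)` for
#'   the scaled-lasso methods, `sqrt(log(p)/n)` for the graphical lasso,
#'   and the tuning selection for GFC_L; a numeric value overrides.
#' @param global Perform global FDR inference (always on for GFC methods)?
#' @param alpha FDR level sequence, default `c(0.05, 0.1)`.
#' @param true_graph Optional true adjacency matrix for power reporting.
#' @param standardize Standardize columns before fitting (estimates are
#'   returned on the original scale either way)?
#' @param npn Apply the nonparanormal transform first?
#' @param log2 Apply `log2(x + 1)` first (UMI counts)?
#' @param ci_level Confidence level for entrywise intervals.
#' @param config A [solver_config()].
#' @return Object of class `"ggm_infer"` with components `method`, `n`,
#'   `p`, `gene_names`, `individual` (a `"ggm_inference"` object, `NULL`
#'   for GFC methods), `statistics` (a `"ggm_statistics"` object),
#'   `global` (a `"ggm_global"` object or `NULL`) and `lambda`.
#' @examples
#' model <- ggm_graph("band", p = 20, seed = 1)
#' x <- sample_mvn(model, n = 150, seed = 2)
#' fit <- ggm_infer(x, method = "B_NW_SL", global = TRUE,
#'                  true_graph = model$adjacency)
#' fit
#' coef(fit)[1:4, 1:4]
#' @export
ggm_infer <- function(x, method = c("B_NW_SL", "D-S_NW_SL", "D-S_GL",
                                    "GFC_SL", "GFC_L"),
                      lambda = "auto", global = FALSE,
                      alpha = c(0.05, 0.1), true_graph = NULL,
                      standardize = FALSE, npn = FALSE, log2 = FALSE,
                      ci_level = 0.95, config = solver_config()) {
  method <- match.arg(method)
  x <- as_expression_matrix(x)
  if (log2) x <- log2p1(x)
  if (npn) x <- npn_transform(x)
  xc <- preprocess(x, standardize = standardize)
  n <- nrow(xc); p <- ncol(xc)
  lam <- if (identical(lambda, "auto")) NULL else lambda

  individual <- NULL
  stats <- NULL
  lambda_used <- NA_real_

  if (method == "B_NW_SL") {
    individual <- b_nw_sl(xc, lambda0 = lam, ci_level = ci_level,
                          config = config)
    lambda_used <- if (is.null(lam)) sqrt(2 * log(p) / n) else lam
    stats <- structure(list(T = individual$z_score, method = method,
                            n = n, p = p,
                            gene_names = individual$gene_names),
                       class = "ggm_statistics")
  } else if (method == "D-S_NW_SL") {
    individual <- ds_nw_sl(xc, lambda0 = lam, ci_level = ci_level,
                           config = config)
    lambda_used <- if (is.null(lam)) sqrt(2 * log(p) / n) else lam
    stats <- structure(list(T = individual$z_score, method = method,
                            n = n, p = p,
                            gene_names = individual$gene_names),
                       class = "ggm_statistics")
  } else if (method == "D-S_GL") {
    individual <- ds_gl(xc, lambda = if (is.null(lam)) "auto" else lam,
                        ci_level = ci_level, config = config)
    lambda_used <- individual$lambda_used
    stats <- structure(list(T = individual$z_score, method = method,
                            n = n, p = p,
                            gene_names = individual$gene_names),
                       class = "ggm_statistics")
  } else if (method == "GFC_SL") {
    stats <- gfc_statistics(xc, "scaled_lasso", lambda = lam,
                            config = config)
    lambda_used <- if (is.null(lam)) sqrt(2 * log(p) / n) else lam
    global <- TRUE
  } else {
    if (is.null(lam)) {
      sel <- gfc_l_select(xc, config = config)
      stats <- sel$statistics
      lambda_used <- sel$lambda
    } else {
      stats <- gfc_statistics(xc, "lasso", lambda = lam, config = config)
      lambda_used <- lam
    }
    global <- TRUE
  }

  glob <- if (global) globalize(stats, alphas = alpha,
                                true_graph = true_graph) else NULL

  structure(list(method = method, n = n, p = p,
                 gene_names = colnames(xc), individual = individual,
                 statistics = stats, global = glob, lambda = lambda_used,
                 ci_level = ci_level),
            class = "ggm_infer")
}

#' @export
print.ggm_infer <- function(x, ...) {
  cat("Gaussian graphical model inference (", x$method, ")\n", sep = "")
  cat("  n =", x$n, " genes =", x$p, " pairs =", x$p * (x$p - 1) / 2, "\n")
  cat("  penalty used:", format(x$lambda, digits = 4), "\n")
  if (!is.null(x$individual))
    cat("  individual inference:", round(100 * x$ci_level), "% CIs,",
        "two-sided p-values\n")
  if (!is.null(x$global)) {
    cat("  global FDR inference:\n")
    for (k in seq_along(x$global$alphas))
      cat(sprintf("    alpha = %-5s threshold = %-8.4g est. FDR = %-8.4g edges = %d\n",
                  format(x$global$alphas[k]), x$global$thresholds[k],
                  x$global$fdr_estimates[k],
                  sum(x$global$decisions[[k]]) / 2))
  }
  invisible(x)
}

#' @export
summary.ggm_infer <- function(object, n_top = 10, ...) {
  tab <- edge_table(if (!is.null(object$individual)) object$individual
                    else object$statistics,
                    global = object$global, sort_by_significance = TRUE)
  out <- list(fit = object, top_pairs = utils::head(tab, n_top))
  class(out) <- "summary.ggm_infer"
  out
}

#' @export
print.summary.ggm_infer <- function(x, ...) {
  print(x$fit)
  cat("\nTop gene pairs by |statistic|:\n")
  print(x$top_pairs, digits = 4)
  invisible(x)
}

#' @export
coef.ggm_infer <- function(object, ...) {
  if (!is.null(object$individual)) object$individual$estimate
  else object$statistics$T
}

#' @export
confint.ggm_infer <- function(object, parm, level, ...) {
  if (is.null(object$individual))
    stop(object$method, " provides no confidence intervals", call. = FALSE)
  list(ci_low = object$individual$ci_low,
       ci_high = object$individual$ci_high,
       level = object$individual$ci_level)
}

#' Plot method: log2-log2 degree-distribution diagnostic
#'
#' For a fit with global decisions, plots the empirical degree
#' distribution of the inferred network at the first FDR level on the
#' log2-log2 scale; a roughly linear decreasing trend indicates the
#' power-law (scale-free) behaviour expected of biological networks.
#'
#' @param x A `"ggm_infer"` object with global results.
#' @param alpha Which FDR level's decisions to plot (default the first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ggm_infer <- function(x, alpha = NULL, ...) {
  if (is.null(x$global))
    stop("no global decisions to plot; refit with global = TRUE",
         call. = FALSE)
  k <- if (is.null(alpha)) 1 else match(alpha, x$global$alphas)
  if (is.na(k)) stop("alpha not among the fitted levels", call. = FALSE)
  dd <- degree_diagnostic(x$global$decisions[[k]])
  if (dd$empty) stop("inferred network has no edges", call. = FALSE)
  pos <- dd$m >= 1
  graphics::plot(log2(dd$m[pos]), log2(dd$prob[pos]),
                 xlab = "log2 degree", ylab = "log2 p(degree)",
                 main = paste0(x$method, " network, alpha = ",
                               format(x$global$alphas[k])), ...)
  if (sum(pos) >= 3)
    graphics::lines(lowess(log2(dd$m[pos]), log2(dd$prob[pos])), col = 4)
  invisible(dd)
}

#' @export
as.data.frame.ggm_infer <- function(x, row.names = NULL, optional = FALSE,
                                    sort_by_significance = FALSE, ...) {
  edge_table(if (!is.null(x$individual)) x$individual else x$statistics,
             global = x$global, sort_by_significance = sort_by_significance)
}
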