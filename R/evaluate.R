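## Accuracy metrics on the upper triangle of the pair space: type I/II
## error, confidence-interval coverage, Matthews correlation, and the
## power-law degree diagnostic used to judge inferred networks.
## Undefined quantities (empty null set, degenerate degree distribution)
## are reported as NA, never silently as 0.

ut <- function(M) M[upper.tri(M)]

#' Empirical type I and type II error of entrywise p-values
#'
#' @param p_values Symmetric `p x p` p-value matrix.
#' @param true_graph `p x p` binary adjacency of the true graph.
#' @param level Nominal test level in (0, 1).
#' @return List with `type_I` (fraction of true-zero pairs with
#'   `p < level`) and `type_II` (fraction of true-edge pairs with
#'   `p >= level`); `NA` when the corresponding pair set is empty.
#' @export
error_rates <- function(p_values, true_graph, level = 0.05) {
  stopifnot(all(dim(p_values) == dim(true_graph)), level > 0, level < 1)
  pv <- ut(p_values)
  edge <- ut(true_graph != 0)
  type_I <- if (any(!edge)) mean(pv[!edge] < level) else NA_real_
  type_II <- if (any(edge)) mean(pv[edge] >= level) else NA_real_
  list(type_I = type_I, type_II = type_II)
}

#' Empirical coverage of entrywise confidence intervals
#'
#' @param result A `"ggm_inference"` object.
#' @param model A `"ggm_graph"` truth object (or a `p x p` true precision
#'   matrix).
#' @return List with `coverage_nonzero` and `coverage_zero`: the fraction
#'   of pairs in the non-zero / zero partial-correlation sets whose
#'   interval contains the true `omega_ij`.
#' @export
ci_coverage <- function(result, model) {
  stopifnot(inherits(result, "ggm_inference"))
  Omega <- if (inherits(model, "ggm_graph")) model$Omega else model
  stopifnot(all(dim(Omega) == dim(result$estimate)))
  truth <- ut(Omega)
  lo <- ut(result$ci_low); hi <- ut(result$ci_high)
  inside <- lo <= truth & truth <= hi
  edge <- truth != 0
  list(coverage_nonzero = if (any(edge)) mean(inside[edge]) else NA_real_,
       coverage_zero = if (any(!edge)) mean(inside[!edge]) else NA_real_)
}

#' Matthews correlation coefficient of edge recovery
#'
#' Computed over upper-triangle edge indicators; returns 0 when any
#' factor of the denominator vanishes.
#'
#' @param decisions `p x p` binary decision matrix.
#' @param true_graph `p x p` binary true adjacency.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(decisions, true_graph) {
  stopifnot(all(dim(decisions) == dim(true_graph)))
  d <- ut(decisions != 0); g <- ut(true_graph != 0)
  tp <- sum(d & g); tn <- sum(!d & !g)
  fp <- sum(d & !g); fn <- sum(!d & g)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Degree-distribution diagnostic with power-law slope
#'
#' Computes node degrees of a decision adjacency, the empirical
#' probability `p(m)` of each observed degree, and the least-squares slope
#' of `log2 p(m)` on `log2 m` over degrees `m >= 1`.  A scale-free network
#' has `p(m)` proportional to `m^-lambda`, i.e. a negative linear
#' log-log relationship.
#'
#' @param decisions Symmetric binary adjacency matrix.
#' @return Object of class `"ggm_degree"`: list with `degrees` (per-node),
#'   `m` (observed degree values), `prob` (empirical probabilities summing
#'   to 1) and `slope` (`NA` when fewer than two distinct positive degrees
#'   exist).
#' @export
degree_diagnostic <- function(decisions) {
  stopifnot(is.matrix(decisions), nrow(decisions) == ncol(decisions))
  if (max(abs(decisions - t(decisions))) != 0)
    stop("'decisions' must be symmetric", call. = FALSE)
  deg <- colSums(decisions != 0)
  if (all(deg == 0)) {
    return(structure(list(degrees = deg, m = integer(0), prob = numeric(0),
                          slope = NA_real_, empty = TRUE),
                     class = "ggm_degree"))
  }
  tab <- table(deg)
  m <- as.integer(names(tab))
  prob <- as.numeric(tab) / length(deg)
  pos <- m >= 1
  slope <- NA_real_
  if (sum(pos) >= 2) {
    fit <- stats::lm.fit(cbind(1, log2(m[pos])), log2(prob[pos]))
    slope <- fit$coefficients[2]
  }
  structure(list(degrees = deg, m = m, prob = prob,
                 slope = unname(slope), empty = FALSE),
            class = "ggm_degree")
}

#' Flat metric report for a method/setting/replicate
#'
#' Convenience assembler of all metrics into a one-row data frame,
#' suitable for row-binding across methods, settings and seeds and saving
#' as CSV.
#'
#' @param method Method label.
#' @param setting Setting label (e.g. graph structure).
#' @param seed Replicate seed.
#' @param result Optional `"ggm_inference"` object (for coverage).
#' @param decisions Optional decision adjacency (for MCC/FDP).
#' @param model The `"ggm_graph"` truth.
#' @param level Test level for the error rates.
#' @return One-row `data.frame`.
#' @export
metric_report <- function(method, setting, seed, model, result = NULL,
                          decisions = NULL, level = 0.05) {
  out <- data.frame(method = method, setting = setting, seed = seed,
                    stringsAsFactors = FALSE)
  if (!is.null(result)) {
    er <- error_rates(result$p_value, model$adjacency, level)
    cov <- ci_coverage(result, model)
    out$type_I <- er$type_I; out$type_II <- er$type_II
    out$coverage_nonzero <- cov$coverage_nonzero
    out$coverage_zero <- cov$coverage_zero
  }
  if (!is.null(decisions)) {
    d <- ut(decisions != 0); g <- ut(model$adjacency != 0)
    out$mcc <- mcc(decisions, model$adjacency)
    out$fdp <- if (sum(d)) sum(d & !g) / sum(d) else 0
    out$power <- if (sum(g)) sum(d & g) / sum(g) else NA_real_
  }
  out
}
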