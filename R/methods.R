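#' @export
print.ggm_inference <- function(x, ...) {
  cat("Entrywise GGM inference (", x$method, "): p = ", x$p,
      ", n = ", x$n, "\n", sep = "")
  off <- x$p_value[upper.tri(x$p_value)]
  cat("  pairs with p < 0.05:", sum(off < 0.05), "of", length(off), "\n")
  invisible(x)
}

#' @export
print.ggm_statistics <- function(x, ...) {
  cat("GGM test statistics (", x$method, "): p = ", x$p,
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @export
print.ggm_global <- function(x, ...) {
  cat("Global GGM inference with FDR control",
      if (!is.null(x$method)) paste0(" (", x$method, ")"), "\n", sep = "")
  for (k in seq_along(x$alphas))
    cat(sprintf("  alpha = %-5s t_hat = %-8.4g est. FDR = %-8.4g edges = %d%s\n",
                format(x$alphas[k]), x$thresholds[k], x$fdr_estimates[k],
                sum(x$decisions[[k]]) / 2,
                if (!is.null(x$power))
                  sprintf("  power = %.3f", x$power[k]) else ""))
  invisible(x)
}

#' Residuals of the nodewise regressions
#'
#' @param object A `"ggm_nodewise"` fit from [fit_all_nodewise()].
#' @param ... Unused.
#' @return The `n x p` residual matrix (column `i` = residuals of the
#'   regression of gene `i` on the others).
#' @export
residuals.ggm_nodewise <- function(object, ...) object$residuals

#' @export
print.ggm_nodewise <- function(x, ...) {
  cat("Nodewise ", x$regression, " fits: ", length(x$sigma_hat),
      " regressions, n = ", x$n, "\n", sep = "")
  invisible(x)
}
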