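## Delimited-text readers and writers: expression matrices in, result
## matrices and the Cytoscape-compatible edge table out.

#' Read an expression matrix from delimited text
#'
#' @param path File path.
#' @param delimiter Field delimiter; `","` or `"\t"`.
#' @param genes_in_columns If `TRUE` (default) the file is samples x genes
#'   with a header row of gene names; if `FALSE` the file is genes x
#'   samples with gene names in the first column, and is transposed on
#'   read.
#' @return Validated expression matrix (samples x genes).
#' @export
read_expression <- function(path, delimiter = ",", genes_in_columns = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.table(path, sep = delimiter, header = genes_in_columns,
               check.names = FALSE, stringsAsFactors = FALSE,
               row.names = if (genes_in_columns) NULL else 1),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  nonnum <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(nonnum))
    stop("non-numeric column(s) in ", path, ": ",
         paste(nonnum, collapse = ", "), call. = FALSE)
  x <- as.matrix(df)
  if (!genes_in_columns) {
    x <- t(x)
    colnames(x) <- rownames(df)
  }
  rownames(x) <- NULL
  as_expression_matrix(x)
}

#' Write result matrices as delimited text
#'
#' Writes one tab-separated `p x p` matrix file per output surface of the
#' result (gene names as header and row names, symmetric, zero diagonal).
#' Individual-inference results produce `estimate`, `std_err`, `z_score`,
#' `p_value`, `ci_low`, `ci_high`; statistic objects produce
#' `test_statistic`; global results produce one `decision_<alpha>` file
#' per level plus a `global_summary` file of thresholds and estimated FDR.
#'
#' @param result A `"ggm_inference"`, `"ggm_statistics"` or `"ggm_global"`
#'   object.
#' @param dir Output directory (created if absent).
#' @param prefix Optional file-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_matrices <- function(result, dir, prefix = "") {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create directory: ", dir, call. = FALSE)
  wm <- function(M, name) {
    path <- file.path(dir, paste0(prefix, name, ".tsv"))
    write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
    path
  }
  paths <- character(0)
  if (inherits(result, "ggm_inference")) {
    surfaces <- c("estimate", "std_err", "z_score", "p_value",
                  "ci_low", "ci_high")
    for (s in surfaces) paths <- c(paths, wm(result[[s]], s))
  } else if (inherits(result, "ggm_statistics")) {
    paths <- c(paths, wm(result$T, "test_statistic"))
  } else if (inherits(result, "ggm_global")) {
    for (k in seq_along(result$alphas)) {
      paths <- c(paths, wm(result$decisions[[k]],
                           paste0("decision_",
                                  format(result$alphas[k], trim = TRUE))))
    }
    summ <- data.frame(alpha = result$alphas,
                       threshold = result$thresholds,
                       fdr_estimate = result$fdr_estimates)
    if (!is.null(result$power)) summ$power <- result$power
    path <- file.path(dir, paste0(prefix, "global_summary.tsv"))
    write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  } else stop("unsupported result type", call. = FALSE)
  invisible(paths)
}

## assemble the per-pair table shared by write_edge_table and
## as.data.frame methods
edge_table <- function(results, alphas = NULL, global = NULL,
                       sort_by_significance = FALSE) {
  primary <- if (inherits(results, "ggm_inference") ||
                 inherits(results, "ggm_statistics")) results
             else results[[1]]
  p <- primary$p
  genes <- primary$gene_names
  if (is.null(genes)) genes <- paste0("g", seq_len(p))
  iu <- which(upper.tri(diag(p)), arr.ind = TRUE)
  tab <- data.frame(`gene 1` = genes[iu[, 1]], `gene 2` = genes[iu[, 2]],
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (inherits(primary, "ggm_inference")) {
    tab$estimate <- primary$estimate[iu]
    tab$ci_low <- primary$ci_low[iu]
    tab$ci_high <- primary$ci_high[iu]
    tab$z_score <- primary$z_score[iu]
    tab$p_value <- primary$p_value[iu]
    stat_col <- "z_score"
  } else {
    tab$test_statistic <- primary$T[iu]
    stat_col <- "test_statistic"
  }
  if (!is.null(global)) {
    for (k in seq_along(global$alphas)) {
      nm <- paste0("global_decision_",
                   format(global$alphas[k], trim = TRUE))
      tab[[nm]] <- as.integer(global$decisions[[k]][iu])
    }
  }
  if (sort_by_significance)
    tab <- tab[order(-abs(tab[[stat_col]])), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write the Cytoscape-compatible edge table
#'
#' One row per unordered gene pair: columns `"gene 1"`, `"gene 2"`, the
#' method's numeric surfaces (estimate / CI bounds / z / p for individual
#' inference, `test_statistic` for the FDR statistics), and one
#' `global_decision_<alpha>` 0/1 column per level when global results are
#' supplied.  The CSV imports directly into network-visualization
#' platforms.
#'
#' @param results A `"ggm_inference"` or `"ggm_statistics"` object.
#' @param path Output CSV path.
#' @param global Optional `"ggm_global"` object supplying decisions.
#' @param sort_by_significance Order rows by descending absolute test
#'   statistic?
#' @return Invisibly, the written data frame.
#' @export
write_edge_table <- function(results, path, global = NULL,
                             sort_by_significance = FALSE) {
  tab <- edge_table(results, global = global,
                    sort_by_significance = sort_by_significance)
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' @importFrom utils write.csv read.csv
NULL
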