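## Expression-matrix handling and the count-data transform chain used in
## single-cell workflows (log2(count + 1) followed by a nonparanormal
## rank transform).

#' Validate and label an expression matrix
#'
#' @param x Numeric `n x p` matrix, samples in rows and genes in columns.
#' @param gene_names Optional length-`p` character vector of unique gene
#'   labels; defaults to existing column names or `g1..gp`.
#' @return The matrix with column names set and basic invariants checked.
#' @export
as_expression_matrix <- function(x, gene_names = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression data must be numeric", call. = FALSE)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 samples and 2 genes", call. = FALSE)
  if (!all(is.finite(x)))
    stop("expression data contains missing or non-finite entries",
         call. = FALSE)
  if (is.null(gene_names)) gene_names <- colnames(x)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(ncol(x)))
  if (length(gene_names) != ncol(x))
    stop("gene_names length must match the number of columns", call. = FALSE)
  if (anyDuplicated(gene_names))
    stop("duplicate gene names: ",
         paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "),
         call. = FALSE)
  colnames(x) <- gene_names
  x
}

#' Center (and optionally standardize) an expression matrix
#'
#' Columns are centered to mean zero; with `standardize = TRUE` they are
#' also scaled to unit sample variance.  The column means and scale factors
#' are retained as attributes so downstream estimates can be reported on
#' the original scale.
#'
#' @param x Expression matrix (samples x genes).
#' @param standardize Scale columns to unit sample variance?
#' @return Centered matrix with attributes `center`, `scale` and
#'   `standardized`.
#' @export
preprocess <- function(x, standardize = FALSE) {
  x <- as_expression_matrix(x)
  ctr <- colMeans(x)
  x <- sweep(x, 2, ctr, "-")
  scl <- rep(1, ncol(x))
  if (standardize) {
    scl <- apply(x, 2, sd)
    bad <- which(scl <= 0 | !is.finite(scl))
    if (length(bad))
      stop("zero-variance gene(s): ",
           paste(colnames(x)[bad], collapse = ", "), call. = FALSE)
    x <- sweep(x, 2, scl, "/")
  }
  structure(x, center = ctr, scale = scl, standardized = standardize)
}

## map a p x p estimate obtained on the standardized scale back to the
## original scale: omega_orig[i, j] = omega_std[i, j] / (s_i * s_j)
rescale_precision <- function(M, scale) {
  sweep(sweep(M, 1, scale, "/"), 2, scale, "/")
}

#' log2(x + 1) transform for UMI count matrices
#'
#' @param counts Non-negative numeric matrix of UMI counts.
#' @return Elementwise `log2(counts + 1)`.
#' @export
log2p1 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative and finite", call. = FALSE)
  log2(counts + 1)
}

#' Nonparanormal (rank-based Gaussianization) transform
#'
#' Maps each column to normal scores `qnorm(rank / (n + 1))` (average ranks
#' for ties), then centers and scales to unit sample variance.  Monotone
#' transformations of a column leave the result unchanged, so the
#' dependence (copula) structure — and hence the network — is preserved
#' while marginals become Gaussian.
#'
#' @param x Numeric matrix, samples in rows.
#' @return Transformed matrix of the same shape, each column with mean 0
#'   and sample variance 1.
#' @export
npn_transform <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite entries", call. = FALSE)
  const <- which(apply(x, 2, function(v) max(v) == min(v)))
  if (length(const))
    stop("constant column(s): ",
         paste(if (is.null(colnames(x))) const else colnames(x)[const],
               collapse = ", "), call. = FALSE)
  out <- apply(x, 2, function(v) {
    z <- qnorm(rank(v, ties.method = "average") / (n + 1))
    z <- z - mean(z)  # exact zero mean even with tied ranks
    z / sd(z)
  })
  dimnames(out) <- dimnames(x)
  out
}
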