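## Synthetic truth for validation: four sparse precision-matrix topologies
## commonly used in gene-network studies, positive-definiteness
## enforcement, and multivariate-normal sampling.

#' Generate a synthetic Gaussian graphical model
#'
#' Constructs a sparse precision matrix with one of four topologies:
#' \describe{
#'   \item{band}{`omega_ii = 1`, first off-diagonal `v1` (default 0.6),
#'     second off-diagonal `v2` (default 0.3).}
#'   \item{hub}{disjoint groups of size `g` (default 10); within each
#'     group the hub node is connected to every member with value `v`
#'     (default 0.3).}
#'   \item{er}{Erdős–Rényi: each pair is an edge independently with
#'     probability `prob` (default `5/p` so the expected node degree is
#'     about 5), value `v` with a random sign.}
#'   \item{scale_free}{preferential-attachment skeleton (each new node
#'     attaches to one existing node with probability proportional to
#'     current degree), edge value `v`.}
#' }
#' If the skeleton is not positive definite, the diagonal is shifted:
#' `Omega <- Omega + (|min eigenvalue| + margin) * I`, which never changes
#' the off-diagonal sparsity pattern.  Alternatively
#' `pd_method = "diag_dominance"` rescales rows to strict diagonal
#' dominance.
#'
#' @param structure One of `"band"`, `"hub"`, `"er"`, `"scale_free"`.
#' @param p Number of nodes (genes), `p >= 4`.
#' @param v1,v2 Band values for the first and second off-diagonals.
#' @param g Hub group size.
#' @param v Edge value for hub / er / scale-free structures.
#' @param prob Erdős–Rényi edge probability; default `5/p`.
#' @param margin Eigenvalue margin for the PD shift.
#' @param pd_method `"eigen_shift"` (default) or `"diag_dominance"`.
#' @param seed Optional integer seed for the random structures.
#' @return Object of class `"ggm_graph"`: list with `structure`, `p`,
#'   `Omega` (true precision), `Sigma` (its inverse), `adjacency` (0/1,
#'   zero diagonal), `max_degree` and `params`.
#' @export
ggm_graph <- function(structure = c("band", "hub", "er", "scale_free"),
                      p, v1 = 0.6, v2 = 0.3, g = 10, v = 0.3, prob = NULL,
                      margin = 0.05, pd_method = c("eigen_shift",
                                                   "diag_dominance"),
                      seed = NULL) {
  structure_lab <- match.arg(structure)
  pd_method <- match.arg(pd_method)
  stopifnot(p >= 4)
  if (!is.null(seed)) set.seed(seed)

  Omega <- diag(p)
  if (structure_lab == "band") {
    for (i in seq_len(p - 1)) Omega[i, i + 1] <- Omega[i + 1, i] <- v1
    for (i in seq_len(p - 2)) Omega[i, i + 2] <- Omega[i + 2, i] <- v2
  } else if (structure_lab == "hub") {
    stopifnot(g >= 2, g <= p)
    starts <- seq(1, p, by = g)
    for (s in starts) {
      if (s >= p) next
      members <- (s + 1):min(s + g - 1, p)
      Omega[s, members] <- Omega[members, s] <- v
    }
  } else if (structure_lab == "er") {
    if (is.null(prob)) prob <- 5 / p
    stopifnot(prob > 0, prob < 1)
    up <- which(upper.tri(Omega))
    edge <- rbinom(length(up), 1, prob) == 1
    sign <- ifelse(runif(length(up)) < 0.5, -1, 1)
    vals <- numeric(length(up))
    vals[edge] <- v * sign[edge]
    Omega[up] <- vals
    Omega <- Omega + t(Omega) - diag(diag(Omega))
    diag(Omega) <- 1
  } else {
    ## Barabási–Albert skeleton: start from an edge, attach each new node
    ## to one existing node chosen proportionally to its degree
    deg <- integer(p)
    Omega[1, 2] <- Omega[2, 1] <- v
    deg[1:2] <- 1L
    for (i in 3:p) {
      target <- sample.int(i - 1, 1, prob = deg[1:(i - 1)])
      Omega[i, target] <- Omega[target, i] <- v
      deg[i] <- deg[i] + 1L
      deg[target] <- deg[target] + 1L
    }
  }

  adj <- (Omega != 0) * 1L
  diag(adj) <- 0L

  ev_min <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    if (pd_method == "eigen_shift") {
      Omega <- Omega + (abs(ev_min) + margin) * diag(p)
    } else {
      rs <- rowSums(abs(Omega)) - abs(diag(Omega))
      diag(Omega) <- pmax(diag(Omega), rs + margin)
    }
  }

  Sigma <- solve(Omega)
  Sigma <- (Sigma + t(Sigma)) / 2
  params <- list(v1 = v1, v2 = v2, g = g, v = v, prob = prob,
                 margin = margin, pd_method = pd_method)
  structure(list(structure = structure_lab, p = p, Omega = Omega,
                 Sigma = Sigma, adjacency = adj,
                 max_degree = max(colSums(adj)), params = params),
            class = "ggm_graph")
}

#' @export
print.ggm_graph <- function(x, ...) {
  cat("Gaussian graphical model truth (", x$structure, " graph)\n", sep = "")
  cat("  p =", x$p, " edges =", sum(x$adjacency) / 2,
      " max degree =", x$max_degree, "\n")
  invisible(x)
}

#' Sample multivariate-normal expression data from a graph model
#'
#' Draws `n` i.i.d. rows from `N(0, Sigma)` with `Sigma` the inverse of the
#' model's precision matrix, via the Cholesky factor.
#'
#' @param model A `"ggm_graph"` object.
#' @param n Number of samples, `n >= 2`.
#' @param seed Optional integer seed.
#' @return `n x p` expression matrix with gene names `g1..gp`.
#' @export
sample_mvn <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "ggm_graph"), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  R <- chol(model$Sigma)
  x <- matrix(rnorm(n * model$p), n, model$p) %*% R
  colnames(x) <- paste0("g", seq_len(model$p))
  x
}

#' @rdname sample_mvn
#' @param object A `"ggm_graph"` object.
#' @param nsim Number of data sets to draw.
#' @param ... Unused.
#' @param n Number of samples per data set.
#' @return For `simulate()`: a list of `nsim` expression matrices.
#' @export
simulate.ggm_graph <- function(object, nsim = 1, seed = NULL, n = 100, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, sample_mvn(object, n), simplify = FALSE)
}

#' Write / read a graph model's matrices as delimited text
#'
#' The adjacency and precision matrices are written as tab-separated files
#' (`<prefix>_adjacency.tsv`, `<prefix>_omega.tsv`) for use as a
#' `--true-graph` input.
#'
#' @param model A `"ggm_graph"` object.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_graph <- function(model, prefix) {
  stopifnot(inherits(model, "ggm_graph"))
  paths <- paste0(prefix, c("_adjacency.tsv", "_omega.tsv"))
  write.table(model$adjacency, paths[1], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(model$Omega, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' @rdname write_graph
#' @param path Path to a delimited adjacency (or precision) matrix file.
#' @return For `read_graph()`: the 0/1 adjacency matrix.
#' @export
read_graph <- function(path) {
  M <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(M) <- NULL
  if (nrow(M) != ncol(M)) stop("true-graph file is not square", call. = FALSE)
  A <- (M != 0) * 1L
  diag(A) <- 0L
  A
}
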