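#' Construct a protein-interaction network
#'
#' Undirected, unweighted graph from a two-column edge table. Self-loops and
#' duplicate edges (in either orientation) are dropped.
#'
#' @param edges Two-column character matrix or data.frame of gene symbol
#'   pairs.
#' @param nodes Optional character vector of node symbols; defaults to the
#'   union of edge endpoints. Extra isolated nodes are allowed.
#' @return Object of class `ppi_network` with elements `nodes` and `edges`
#'   (two-column character matrix, endpoints sorted within a row).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(edges) <- "character"
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]  # no self-loops
  if (nrow(edges)) {
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, 2:1]
    edges <- unique(edges)
  }
  endpoint <- unique(as.vector(edges))
  nodes <- if (is.null(nodes)) endpoint else
    unique(c(as.character(nodes), endpoint))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Adjacency matrix of a network
#' @param network A [ppi_network()].
#' @return Symmetric 0/1 numeric matrix with node dimnames.
#' @export
adjacency_matrix <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  n <- length(network$nodes)
  A <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  if (nrow(network$edges)) {
    i <- match(network$edges[, 1L], network$nodes)
    j <- match(network$edges[, 2L], network$nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Truncated network communicability
#'
#' Communicability between two nodes sums the number of walks connecting
#' them, down-weighting long walks by the reciprocal factorial of their
#' length: `G = sum_{k=1..max_len} A^k / k!`. The series is the truncation
#' of `expm(A) - I` at walk length `max_len`; the identity (`k = 0`) term is
#' excluded since self-communicability carries no cross-node information.
#'
#' @param network A [ppi_network()].
#' @param max_len Maximum walk length retained (default 6).
#' @return Symmetric nonnegative matrix with node dimnames; `0 x 0` for an
#'   empty network.
#' @export
truncated_communicability <- function(network, max_len = 6L) {
  stopifnot(max_len >= 1L)
  A <- adjacency_matrix(network)
  if (nrow(A) == 0L) return(A)
  G <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  P <- diag(nrow(A))
  kfact <- 1
  for (k in seq_len(max_len)) {
    P <- P %*% A
    kfact <- kfact * k
    G <- G + P / kfact
  }
  G
}

#' Communicability of genes to the training set
#'
#' For each gene, sums the communicability entries between the gene's node
#' and every training-gene node present in the network, excluding the gene
#' itself when it is a training gene (no self-inflation). Genes that are not
#' network nodes score `NA` (missing).
#'
#' @param genes Character vector of genes to score.
#' @param G Communicability matrix from [truncated_communicability()].
#' @param training Character vector of training gene symbols.
#' @return Named numeric vector over `genes`.
#' @export
communicability_scores <- function(genes, G, training) {
  genes <- as.character(genes)
  out <- stats::setNames(rep(NA_real_, length(genes)), genes)
  if (nrow(G) == 0L) return(out)
  tr <- intersect(unique(as.character(training)), rownames(G))
  present <- genes %in% rownames(G)
  if (!any(present)) return(out)
  if (length(tr) == 0L) {
    out[present] <- 0
    return(out)
  }
  sub <- G[genes[present], tr, drop = FALSE]
  total <- rowSums(sub)
  # remove the gene's own column when it is a training gene
  self <- intersect(genes[present], tr)
  if (length(self))
    total[self] <- total[self] - G[cbind(self, self)]
  out[present] <- total
  out
}
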