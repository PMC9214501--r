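#' Ground-truth network graph
#'
#' Directed weighted connectivity with the same orientation convention as
#' the estimators: entry \code{(i, j)} of \code{W} is the weight of the
#' edge j -> i.
#'
#' @param W square numeric matrix of edge weights.
#' @param metadata optional named list (motif kind, sparsity, strength, ...).
#' @return An object of class \code{ddc_network} with fields \code{W},
#'   \code{n_nodes} and \code{metadata}.
#' @export
ddc_network <- function(W, metadata = list()) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("`W` must be square")
  if (!all(is.finite(W))) stop("`W` contains non-finite entries")
  dimnames(W) <- NULL
  structure(list(W = W, n_nodes = nrow(W), metadata = metadata),
            class = "ddc_network")
}

#' @export
print.ddc_network <- function(x, ...) {
  ne <- sum(x$W != 0 & row(x$W) != col(x$W))
  cat(sprintf("<ddc_network> %d nodes, %d directed edges\n", x$n_nodes, ne))
  if (length(x$metadata))
    cat("  ", paste(names(x$metadata), unlist(x$metadata), sep = "=",
                    collapse = ", "), "\n")
  invisible(x)
}

#' Off-diagonal edge indicator of a graph
#' @param g a \code{\link{ddc_network}}.
#' @return logical matrix, TRUE where a directed edge exists (diagonal FALSE).
#' @export
edge_mask <- function(g) {
  stopifnot(inherits(g, "ddc_network"))
  g$W != 0 & row(g$W) != col(g$W)
}

#' Three-node false-positive motifs
#'
#' The two canonical structures on which covariance methods report spurious
#' connections: the chain (1 -> 2 -> 3; nodes 1 and 3 are unconnected but
#' correlated) and the confounder (1 -> 2, 1 -> 3; the two driven nodes are
#' unconnected but share the common driver).  All nodes carry decaying
#' self-dynamics (diagonal -1) and the true edges carry a common, by
#' default inhibitory, strength.
#'
#' @param kind \code{"chain"} or \code{"confounder"}.
#' @param strength weight of the true edges (default -0.5).
#' @return A \code{\link{ddc_network}}; the false-positive pair is recorded
#'   in \code{metadata$false_positive_pair} as (row, col) of the missing
#'   edge between the correlated-but-unconnected nodes.
#' @export
motif_graph <- function(kind = c("chain", "confounder"), strength = -0.5) {
  kind <- match.arg(kind)
  W <- diag(-1, 3)
  if (kind == "chain") {        # 1 -> 2 and 2 -> 3
    W[2, 1] <- strength
    W[3, 2] <- strength
    fp <- c(3L, 1L)
  } else {                      # 1 -> 2 and 1 -> 3
    W[2, 1] <- strength
    W[3, 1] <- strength
    fp <- c(3L, 2L)
  }
  ddc_network(W, metadata = list(motif = kind, strength = strength,
                                 false_positive_pair = fp))
}

#' Erdos-Renyi directed random graph
#'
#' Every ordered off-diagonal pair carries an edge of the given uniform
#' strength independently with probability \code{sparsity}; self-loops are
#' excluded (decay terms, where the dynamics need them, live in the
#' simulator, not the graph).
#'
#' @param n number of nodes.
#' @param sparsity connection probability in \code{[0, 1]}.
#' @param strength uniform edge weight.
#' @param seed optional RNG seed for reproducibility.
#' @return A \code{\link{ddc_network}}.
#' @export
er_graph <- function(n, sparsity, strength = -0.5, seed = NULL) {
  if (sparsity < 0 || sparsity > 1) stop("`sparsity` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  off <- row(W) != col(W)
  W[off] <- strength * (stats::runif(sum(off)) < sparsity)
  ddc_network(W, metadata = list(kind = "erdos_renyi", sparsity = sparsity,
                                 strength = strength))
}

#' Degree-preserving randomization
#'
#' Rewires a directed graph by repeated double-edge swaps, preserving every
#' node's in-degree and out-degree while destroying the specific edge
#' placement; used as a structured chance-level control.  Swaps that would
#' create self-loops or duplicate edges are rejected.  Edge weights are
#' reset to the graph's uniform strength (or 1 when weights are not
#' uniform).
#'
#' @param g a \code{\link{ddc_network}} with binary or binarizable edges.
#' @param n_swaps number of attempted swaps (default 10 per edge).
#' @param seed optional RNG seed.
#' @return A rewired \code{\link{ddc_network}}.
#' @export
degree_preserving_randomize <- function(g, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(g, "ddc_network"))
  if (!is.null(seed)) set.seed(seed)
  A <- edge_mask(g)
  ne <- sum(A)
  if (ne < 2L) {
    warning("graph has fewer than 2 edges; returning it unchanged")
    return(g)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * ne
  if (n_swaps == 0L) return(g)
  vals <- g$W[A]
  strength <- if (length(unique(vals)) == 1L) vals[1] else 1
  ig <- igraph::graph_from_adjacency_matrix(t(A) * 1, mode = "directed")
  rg <- igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE,
                                                  niter = n_swaps))
  Anew <- t(as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE)))
  ddc_network(Anew * strength,
              metadata = c(g$metadata, list(randomized = TRUE,
                                            n_swaps = n_swaps)))
}

#' In- and out-degree sequences
#' @param g a \code{\link{ddc_network}}.
#' @return list with integer vectors \code{in_degree} (edges received,
#'   row sums of the edge mask) and \code{out_degree} (edges sent).
#' @export
degree_sequences <- function(g) {
  A <- edge_mask(g)
  list(in_degree = rowSums(A), out_degree = colSums(A))
}
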