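#' Tree graph over the channel set
#'
#' An unweighted, undirected spanning tree: exactly `n_nodes - 1` edges,
#' connected and acyclic, with a binary symmetric adjacency matrix.
#'
#' @param edges two-column matrix of node-index pairs (1-based).
#' @param n_nodes number of nodes.
#' @param channel_labels node names.
#' @return An object of class `tree_graph` with canonicalized edges
#'   (`from < to`, sorted), the adjacency matrix, and labels.
#' @export
tree_graph <- function(edges, n_nodes, channel_labels = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (!is_spanning_tree(edges, n_nodes))
    stop_invalid("edges do not form a spanning tree on ", n_nodes, " nodes ",
                 "(need ", n_nodes - 1L, " edges, connected, acyclic)")
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  colnames(edges) <- c("from", "to")
  channel_labels <- channel_labels %||% default_channel_labels(n_nodes)
  if (length(channel_labels) != n_nodes)
    stop_invalid("channel_labels length does not match n_nodes")
  adj <- matrix(0L, n_nodes, n_nodes,
                dimnames = list(channel_labels, channel_labels))
  adj[edges] <- 1L
  adj <- adj + t(adj)
  structure(
    list(n_nodes = as.integer(n_nodes), edges = edges, adjacency = adj,
         channel_labels = channel_labels),
    class = "tree_graph"
  )
}

#' @export
print.tree_graph <- function(x, ...) {
  cat("<tree_graph> ", x$n_nodes, " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Would adding an edge close a cycle?
#'
#' Depth-first search cycle detection on the forest `tree_so_far` augmented
#' with the candidate edge: starting from one candidate endpoint, if a
#' visited node has an adjacent node that is already visited and is not its
#' parent, a cycle has formed. Equivalently, the candidate closes a cycle iff
#' its endpoints are already connected.
#'
#' @param tree_so_far two-column matrix of accepted edges (may have 0 rows).
#' @param candidate length-2 vector, the edge to test.
#' @param n_nodes number of nodes in the graph.
#' @return `TRUE` if adding `candidate` would create a cycle.
#' @export
has_cycle_after_adding <- function(tree_so_far, candidate, n_nodes) {
  candidate <- as.integer(candidate)
  if (length(candidate) != 2L || any(candidate < 1L | candidate > n_nodes) ||
      candidate[1L] == candidate[2L])
    stop_invalid("candidate endpoints out of range")
  tree_so_far <- matrix(as.integer(tree_so_far), ncol = 2L)
  if (nrow(tree_so_far)) {
    dup <- tree_so_far[, 1L] == candidate[1L] & tree_so_far[, 2L] == candidate[2L] |
      tree_so_far[, 1L] == candidate[2L] & tree_so_far[, 2L] == candidate[1L]
    if (any(dup)) return(TRUE)
  }
  edges <- rbind(tree_so_far, candidate)
  adj <- lapply(seq_len(n_nodes), function(i) integer(0))
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  visited <- logical(n_nodes)
  # iterative DFS with explicit parent tracking
  stack_node <- candidate[1L]
  stack_parent <- 0L
  while (length(stack_node)) {
    v <- stack_node[length(stack_node)]
    p <- stack_parent[length(stack_parent)]
    stack_node <- stack_node[-length(stack_node)]
    stack_parent <- stack_parent[-length(stack_parent)]
    if (visited[v]) next
    visited[v] <- TRUE
    for (nb in adj[[v]]) {
      if (visited[nb] && nb != p) return(TRUE)
      if (!visited[nb]) {
        stack_node <- c(stack_node, nb)
        stack_parent <- c(stack_parent, v)
      }
    }
  }
  FALSE
}

#' Maximum-connectivity spanning tree (Kruskal)
#'
#' Extracts the spanning tree of maximal total tPLV from the complete
#' weighted graph of a connectivity matrix. Edges are sorted by decreasing
#' weight (ties broken lexicographically by node-index pair, making the
#' result deterministic and the order-invariance under monotone weight
#' transforms exact) and greedily accepted unless adding one would close a
#' cycle, detected by depth-first search. Because only the order of the
#' weights matters, negative zPLV-derived weights need no special handling.
#'
#' @param conn a [connectivity_matrix()].
#' @return A [tree_graph()].
#' @export
kruskal_max_tree <- function(conn) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  n <- nrow(conn$matrix)
  if (n < 2L) stop_invalid("need at least 2 nodes")
  if (any(!is.finite(conn$matrix)))
    stop_invalid("non-finite weight in the connectivity matrix")
  pairs <- t(combn(n, 2L))
  w <- conn$matrix[pairs]
  ord <- order(-w, pairs[, 1L], pairs[, 2L])
  chosen <- matrix(integer(0), ncol = 2L)
  for (r in ord) {
    cand <- pairs[r, ]
    if (!has_cycle_after_adding(chosen, cand, n)) {
      chosen <- rbind(chosen, cand)
      if (nrow(chosen) == n - 1L) break
    }
  }
  tree_graph(chosen, n, channel_labels = conn$channel_labels)
}

#' Group-level spanning tree
#'
#' Averages the tPLV matrices of a group element-wise and extracts the
#' maximum spanning tree of the averaged matrix.
#'
#' @param matrices list of [connectivity_matrix()] objects over the same
#'   channel set.
#' @return A [tree_graph()].
#' @export
group_tree <- function(matrices) {
  if (!length(matrices)) stop_invalid("need at least one matrix")
  labels <- matrices[[1L]]$channel_labels
  for (m in matrices) {
    stopifnot(inherits(m, "connectivity_matrix"))
    if (!identical(m$channel_labels, labels))
      stop_invalid("channel labels differ between matrices")
  }
  avg <- Reduce(`+`, lapply(matrices, `[[`, "matrix")) / length(matrices)
  kruskal_max_tree(connectivity_matrix(avg, channel_labels = labels,
                                       M = matrices[[1L]]$M))
}
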