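# hop-distance matrix of a tree by breadth-first search from every node
tree_distances <- function(tree) {
  n <- tree$n_nodes
  adj <- lapply(seq_len(n), function(i) which(tree$adjacency[i, ] == 1L))
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (nb in adj[[v]]) {
        if (is.na(dist[nb])) {
          dist[nb] <- dist[v] + 1L
          queue <- c(queue, nb)
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

#' Nodal topology metrics of a spanning tree
#'
#' Per node: degree `k`, betweenness centrality and eccentricity.
#' Betweenness counts, over all pairs of other nodes, the fraction of
#' shortest paths passing through the node, normalized by
#' `(N - 1)(N - 2)` pairs (ordered-pair convention), so a leaf scores 0 and
#' the hub of a star scores 1. In a tree each pair has a unique shortest
#' path, so the count is obtained exactly from the sizes of the components
#' left when the node is removed. Eccentricity is the longest hop distance
#' from the node to any other node.
#'
#' @param tree a [tree_graph()] with at least 3 nodes.
#' @return data frame with columns `node`, `label`, `degree`, `betweenness`,
#'   `eccentricity`.
#' @export
nodal_metrics <- function(tree) {
  stopifnot(inherits(tree, "tree_graph"))
  n <- tree$n_nodes
  if (n < 3L)
    stop_invalid("nodal betweenness is undefined for fewer than 3 nodes")
  adj <- lapply(seq_len(n), function(i) which(tree$adjacency[i, ] == 1L))
  degree <- vapply(adj, length, integer(1))
  bc <- numeric(n)
  for (r in seq_len(n)) {
    # component sizes after deleting r: one BFS per neighbor, r blocked
    sizes <- integer(0)
    for (start in adj[[r]]) {
      seen <- logical(n)
      seen[r] <- TRUE
      seen[start] <- TRUE
      queue <- start
      count <- 1L
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        for (nb in adj[[v]]) {
          if (!seen[nb]) {
            seen[nb] <- TRUE
            count <- count + 1L
            queue <- c(queue, nb)
          }
        }
      }
      sizes <- c(sizes, count)
    }
    pairs_through <- (sum(sizes)^2 - sum(sizes^2)) / 2
    bc[r] <- 2 * pairs_through / ((n - 1) * (n - 2))
  }
  d <- tree_distances(tree)
  data.frame(
    node = seq_len(n), label = tree$channel_labels, degree = degree,
    betweenness = bc, eccentricity = apply(d, 1L, max),
    stringsAsFactors = FALSE
  )
}

#' Global topology metrics of a spanning tree
#'
#' Summarizes a tree by: leaf count `L` and leaf fraction `L / (N - 1)`;
#' maximum degree; maximum betweenness centrality; global eccentricity
#' (by default the range, largest minus smallest nodal eccentricity; the
#' `"max"` variant reports the largest nodal eccentricity instead); degree
#' divergence `kappa = sum(k^2) / sum(k)`; diameter, the longest shortest
#' path in hops normalized by `N - 1`; and tree hierarchy
#' `T_H = L / (2 (N - 1) BC_max)`, which is 0.5 for a star and tends to 0
#' for a line as `N` grows.
#'
#' @param tree a [tree_graph()] with at least 3 nodes.
#' @param ecc_variant `"range"` (max minus min nodal eccentricity, the
#'   default) or `"max"`.
#' @param gplv optional subject-level global PLV carried along for reporting.
#' @return An object of class `global_metrics` (a named list); see
#'   [as.data.frame.global_metrics()].
#' @export
global_metrics <- function(tree, ecc_variant = c("range", "max"),
                           gplv = NA_real_) {
  stopifnot(inherits(tree, "tree_graph"))
  ecc_variant <- match.arg(ecc_variant)
  nodal <- nodal_metrics(tree)
  n <- tree$n_nodes
  leaves <- sum(nodal$degree == 1L)
  bc_max <- max(nodal$betweenness)
  ecc <- switch(ecc_variant,
                range = max(nodal$eccentricity) - min(nodal$eccentricity),
                max = max(nodal$eccentricity))
  out <- list(
    gplv = gplv,
    leaf_count = leaves,
    leaf_fraction = leaves / (n - 1),
    k_max = max(nodal$degree),
    bc_max = bc_max,
    eccentricity = ecc,
    kappa = sum(nodal$degree^2) / sum(nodal$degree),
    diameter = max(nodal$eccentricity) / (n - 1),
    tree_hierarchy = leaves / (2 * (n - 1) * bc_max),
    n_nodes = n,
    ecc_variant = ecc_variant
  )
  class(out) <- "global_metrics"
  out
}

#' @export
print.global_metrics <- function(x, ...) {
  cat("<global_metrics> N =", x$n_nodes, "\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' One-row data frame of global metrics
#'
#' @param x a `global_metrics` object.
#' @param ... unused.
#' @return data frame with one row.
#' @export
as.data.frame.global_metrics <- function(x, ...) {
  data.frame(
    gplv = x$gplv, leaf_count = x$leaf_count,
    leaf_fraction = x$leaf_fraction, k_max = x$k_max, bc_max = x$bc_max,
    eccentricity = x$eccentricity, kappa = x$kappa, diameter = x$diameter,
    tree_hierarchy = x$tree_hierarchy
  )
}

#' Hub and edge occurrence across individual trees
#'
#' For a set of individual spanning trees over the same channels, reports the
#' fraction of subjects in which each node is a hub (degree > 1) and the
#' fraction of trees containing each observed edge. Edges occurring in more
#' than `threshold` of the trees are flagged for display.
#'
#' @param trees list of [tree_graph()] objects with identical channel sets.
#' @param threshold display threshold on the edge occurrence fraction.
#' @return An object of class `occurrence_table`: data frames `hubs`
#'   (`label`, `occurrence`) and `edges` (`from`, `to`, `occurrence`,
#'   `displayed`).
#' @export
occurrence <- function(trees, threshold = 0.25) {
  if (!length(trees)) stop_invalid("need at least one tree")
  labels <- trees[[1L]]$channel_labels
  for (tr in trees) {
    stopifnot(inherits(tr, "tree_graph"))
    if (!identical(tr$channel_labels, labels))
      stop_invalid("channel labels differ between trees")
  }
  n <- trees[[1L]]$n_nodes
  n_subj <- length(trees)
  hub_counts <- Reduce(`+`, lapply(trees, function(tr)
    as.integer(rowSums(tr$adjacency) > 1L)))
  edge_counts <- Reduce(`+`, lapply(trees, function(tr) tr$adjacency))
  keys <- which(upper.tri(edge_counts) & edge_counts > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = labels[keys[, 1L]], to = labels[keys[, 2L]],
    occurrence = edge_counts[keys] / n_subj,
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-edges$occurrence, edges$from, edges$to), ]
  rownames(edges) <- NULL
  edges$displayed <- edges$occurrence > threshold
  structure(
    list(hubs = data.frame(label = labels,
                           occurrence = hub_counts / n_subj,
                           stringsAsFactors = FALSE),
         edges = edges, n_subjects = n_subj, threshold = threshold),
    class = "occurrence_table"
  )
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("<occurrence_table> over", x$n_subjects, "subjects\n")
  cat("top hubs:\n")
  h <- x$hubs[order(-x$hubs$occurrence), ]
  print(utils::head(h, 5L), row.names = FALSE)
  invisible(x)
}

#' Edge overlap with a reference tree
#'
#' Fraction of a tree's edges shared with a reference tree (typically the
#' group tree of the healthy controls), `shared / (N - 1)`.
#'
#' @param tree,reference [tree_graph()] objects on the same channel set.
#' @return An object of class `similarity_result` with `shared_edges`,
#'   `overlap_fraction` and `overlap_percent`.
#' @export
overlap <- function(tree, reference) {
  stopifnot(inherits(tree, "tree_graph"), inherits(reference, "tree_graph"))
  if (tree$n_nodes != reference$n_nodes)
    stop_invalid("trees have different numbers of nodes")
  key <- function(e) paste(e[, 1L], e[, 2L])
  shared <- sum(key(tree$edges) %in% key(reference$edges))
  structure(
    list(shared_edges = shared,
         overlap_fraction = shared / (tree$n_nodes - 1L),
         overlap_percent = 100 * shared / (tree$n_nodes - 1L)),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("<similarity_result> ", x$shared_edges, " shared edges (",
      sprintf("%.2f", x$overlap_percent), "%)\n", sep = "")
  invisible(x)
}

# decode a Pruefer sequence into a tree edge list
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(NA_integer_, n - 1L, 2L)
  ptr <- 0L
  for (s in seq) {
    leaf <- which(degree == 1L)[1L]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, s)
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

#' Uniform random spanning tree
#'
#' Samples a labeled tree uniformly at random via a Pruefer sequence; useful
#' as a null model for topology metrics.
#'
#' @param n_nodes number of nodes (at least 2).
#' @param channel_labels optional node names.
#' @return A [tree_graph()].
#' @export
random_tree <- function(n_nodes, channel_labels = NULL) {
  if (n_nodes < 2L) stop_invalid("need at least 2 nodes")
  edges <- if (n_nodes == 2L) matrix(c(1L, 2L), 1L) else
    prufer_decode(sample.int(n_nodes, n_nodes - 2L, replace = TRUE), n_nodes)
  tree_graph(edges, n_nodes, channel_labels = channel_labels)
}
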