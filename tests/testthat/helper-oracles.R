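# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and each other) where they stand as cross-checks.

# --- exhaustive spanning-tree enumeration (Cayley / Pruefer) ---------------

# decode a Pruefer sequence independently of the package internals
oracle_prufer_decode <- function(seq, n) {
  deg <- rep(1L, n)
  for (s in seq) deg[s] <- deg[s] + 1L
  edges <- matrix(NA_integer_, n - 1L, 2L)
  for (i in seq_along(seq)) {
    leaf <- min(which(deg == 1L))
    edges[i, ] <- c(leaf, seq[i])
    deg[leaf] <- deg[leaf] - 1L
    deg[seq[i]] <- deg[seq[i]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

# all n^(n-2) labeled spanning trees on n nodes, as edge matrices
oracle_all_trees <- function(n) {
  if (n == 2L) return(list(matrix(c(1L, 2L), 1L)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  lapply(seq_len(nrow(seqs)), function(i)
    oracle_prufer_decode(as.integer(seqs[i, ]), n))
}

oracle_tree_weight <- function(edges, w) sum(w[edges])

oracle_max_tree_weight <- function(w, trees) {
  max(vapply(trees, oracle_tree_weight, numeric(1), w = w))
}

# --- brute-force betweenness by path enumeration ---------------------------

# unique path between p and q in a tree (adjacency matrix), by DFS
oracle_tree_path <- function(adj, p, q) {
  n <- nrow(adj)
  parent <- rep(NA_integer_, n)
  visited <- logical(n)
  stack <- p
  visited[p] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v == q) break
    for (nb in which(adj[v, ] == 1)) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        parent[nb] <- v
        stack <- c(stack, nb)
      }
    }
  }
  path <- q
  while (path[1L] != p) path <- c(parent[path[1L]], path)
  path
}

# Eq.-style betweenness: ordered-pair convention over (N-1)(N-2)
oracle_bc <- function(adj) {
  n <- nrow(adj)
  counts <- numeric(n)
  for (p in seq_len(n - 1L)) {
    for (q in seq(p + 1L, n)) {
      inner <- setdiff(oracle_tree_path(adj, p, q), c(p, q))
      counts[inner] <- counts[inner] + 1
    }
  }
  2 * counts / ((n - 1) * (n - 2))
}

# --- connected components (union-find) for cycle detection -----------------

oracle_same_component <- function(edges, a, b, n) {
  comp <- seq_len(n) # component labels, merged per edge
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      ca <- comp[edges[r, 1L]]; cb <- comp[edges[r, 2L]]
      if (ca != cb) comp[comp == ca] <- cb
    }
  }
  comp[a] == comp[b]
}

# --- misc fixtures ---------------------------------------------------------

random_conn <- function(n, weights = NULL) {
  w <- matrix(0, n, n)
  vals <- weights %||% stats::runif(n * (n - 1) / 2, -1, 1)
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  connectivity_matrix(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal hand-built plv_time_series for arithmetic tests
fake_plv <- function(values, fs, t_start, kind = "plv", n_trials = 10L,
                     n_channels = NULL) {
  values <- matrix(values, nrow = if (is.matrix(values)) nrow(values) else 1L)
  n_pairs <- nrow(values)
  if (is.null(n_channels)) {
    n_channels <- 2L
    while (choose(n_channels, 2L) < n_pairs) n_channels <- n_channels + 1L
  }
  pairs <- t(combn(n_channels, 2L))[seq_len(n_pairs), , drop = FALSE]
  structure(
    list(values = values, pairs = pairs, kind = kind, n_trials = n_trials,
         fs = fs, t_start = t_start, window = NULL,
         channel_labels = sprintf("ch%02d", seq_len(n_channels)),
         baseline_mean = NULL, baseline_sd = NULL),
    class = "plv_time_series"
  )
}

# epoch_set filled with a deterministic function of (trial, channel, t)
make_epochs <- function(f, n_trials = 4L, n_channels = 3L, fs = 7.81,
                        window = c(2, 4, 12, 2)) {
  ns <- round(sum(window) * fs)
  t <- -(window[1] + window[2]) + (seq_len(ns) - 1) / fs
  data <- array(NA_real_, c(n_trials, n_channels, ns))
  for (p in seq_len(n_trials))
    for (ch in seq_len(n_channels))
      data[p, ch, ] <- f(p, ch, t)
  epoch_set(data, fs = fs, window = window)
}
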