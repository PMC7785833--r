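# hand-parsed TSV reader with line-number diagnostics
read_tsv_strict <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_invalid("empty file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1L]])
  bad <- which(vapply(cells, length, integer(1)) != width)
  if (length(bad))
    stop_invalid("ragged row in ", path, ": line ", bad[1L] , " has ",
                 length(cells[[bad[1L]]]), " fields, header has ", width)
  cells
}

#' Write / read a labeled connectivity matrix
#'
#' Serializes a [connectivity_matrix()] as a TSV with the channel labels as
#' header row and first column, plus a JSON metadata sidecar (`<path>.json`)
#' holding `M` and the trial count. Reading validates the header, rejects
#' duplicate labels (naming the duplicate), ragged rows (with the line
#' number), and asymmetric matrices.
#'
#' @param conn a [connectivity_matrix()].
#' @param path output TSV path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   [connectivity_matrix()].
#' @export
write_matrix <- function(conn, path) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  df <- data.frame(channel = conn$channel_labels, conn$matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(M = conn$M, n_trials = conn$n_trials),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  cells <- read_tsv_strict(path)
  header <- cells[[1L]][-1L]
  if (anyDuplicated(header))
    stop_invalid("duplicated channel label in header of ", path, ": ",
                 header[duplicated(header)][1L])
  body <- cells[-1L]
  if (length(body) != length(header))
    stop_invalid(path, ": ", length(body), " data rows for ",
                 length(header), " channels")
  rlab <- vapply(body, `[[`, character(1), 1L)
  if (!identical(rlab, header))
    stop_invalid(path, ": row labels do not match the header")
  m <- do.call(rbind, lapply(body, function(r) as.numeric(r[-1L])))
  if (any(is.na(m))) stop_invalid(path, ": non-numeric matrix entry")
  if (max(abs(m - t(m))) > 1e-8)
    stop_invalid(path, ": matrix is not symmetric")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  connectivity_matrix(m, channel_labels = header,
                      M = meta$M %||% NA_integer_,
                      n_trials = meta$n_trials %||% NA_integer_)
}

#' Write / read a spanning tree
#'
#' Trees are stored as an edge-list TSV (`from`, `to` channel labels);
#' `format = "adjacency"` writes the binary adjacency matrix instead, and
#' `format = "graphml"` exports via igraph for external viewers (requires
#' the igraph package). Reading an edge list reconstructs and validates the
#' tree; the node set is the sorted union of the edge labels unless
#' `channel_labels` is supplied.
#'
#' @param tree a [tree_graph()].
#' @param path output path.
#' @param format `"edges"` (default), `"adjacency"`, or `"graphml"`.
#' @return `write_tree` returns `path` invisibly; `read_tree` returns a
#'   [tree_graph()].
#' @export
write_tree <- function(tree, path, format = c("edges", "adjacency", "graphml")) {
  stopifnot(inherits(tree, "tree_graph"))
  format <- match.arg(format)
  if (format == "edges") {
    df <- data.frame(from = tree$channel_labels[tree$edges[, 1L]],
                     to = tree$channel_labels[tree$edges[, 2L]])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "adjacency") {
    df <- data.frame(channel = tree$channel_labels, tree$adjacency,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop_invalid("graphml export requires the igraph package")
    g <- igraph::graph_from_edgelist(
      cbind(tree$channel_labels[tree$edges[, 1L]],
            tree$channel_labels[tree$edges[, 2L]]),
      directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_tree
#' @param channel_labels optional node set (ordered) for `read_tree`.
#' @export
read_tree <- function(path, channel_labels = NULL) {
  cells <- read_tsv_strict(path)
  if (!identical(cells[[1L]], c("from", "to")))
    stop_invalid(path, ": expected header 'from\tto'")
  ef <- vapply(cells[-1L], `[[`, character(1), 1L)
  et <- vapply(cells[-1L], `[[`, character(1), 2L)
  labels <- channel_labels %||% sort(unique(c(ef, et)))
  idx <- cbind(match(ef, labels), match(et, labels))
  if (any(is.na(idx)))
    stop_invalid(path, ": edge label not in the channel set")
  tree_graph(idx, length(labels), channel_labels = labels)
}

#' Write / read an epoch set
#'
#' Epochs are stored as a long TSV (columns `trial`, `t`, then one column
#' per channel) plus a JSON sidecar (`<path>.json`) with the sampling rate,
#' window and channel labels; the round trip restores the array to full
#' stored precision.
#'
#' @param epochs an [epoch_set()].
#' @param path output TSV path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns an
#'   [epoch_set()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  t <- epoch_time(epochs)
  rows <- lapply(seq_len(d[1L]), function(p) {
    m <- t(epochs$data[p, , , drop = TRUE])  # samples x channels
    data.frame(trial = p, t = t, m, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("trial", "t", epochs$channel_labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              qmethod = "double")
  jsonlite::write_json(
    list(fs = epochs$fs, window = epochs$window,
         channel_labels = epochs$channel_labels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop_invalid("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- read.delim(path, check.names = FALSE)
  labels <- meta$channel_labels
  if (!all(labels %in% names(df)))
    stop_invalid(path, ": channel columns do not match the sidecar labels")
  trials <- sort(unique(df$trial))
  ns <- sum(df$trial == trials[1L])
  data <- array(NA_real_, c(length(trials), length(labels), ns))
  for (i in seq_along(trials)) {
    block <- df[df$trial == trials[i], labels, drop = FALSE]
    data[i, , ] <- t(as.matrix(block))
  }
  epoch_set(data, fs = meta$fs, window = meta$window, channel_labels = labels)
}

#' Write / read a synthetic cohort
#'
#' Writes one epoch TSV (plus sidecar) per subject and a `manifest.json`
#' listing each subject's id, group, clinical scores and file, together with
#' an echo of the generating configurations.
#'
#' @param cohort a `nirs_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   `nirs_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nirs_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- lapply(cohort, function(s) {
    file <- paste0(s$record$subject_id, "_epochs.tsv")
    write_epochs(s$epochs, file.path(dir, file))
    c(s$record, list(file = file))
  })
  configs <- attr(cohort, "configs")
  echo <- lapply(configs, function(cfg) {
    cfg <- unclass(cfg)
    cfg$clinical_link <- NULL
    cfg$coupling_template <- apply(cfg$coupling_template, 1L, identity,
                                   simplify = FALSE)
    cfg
  })
  jsonlite::write_json(list(subjects = subjects, configs = echo),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  cohort <- lapply(manifest$subjects, function(s) {
    epochs <- read_epochs(file.path(dir, s$file))
    s$file <- NULL
    list(epochs = epochs, record = s)
  })
  class(cohort) <- "nirs_cohort"
  cohort
}
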