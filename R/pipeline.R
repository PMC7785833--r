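#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end analysis with the
#' study defaults: 0.01-0.15 Hz band, 2/4/12/2 s epoch window, `[-4, -1)` s
#' baseline, `[0, 12)` s post-stimulus average, 25% occurrence display
#' threshold, eccentricity reported as the nodal range.
#'
#' @param band band-pass edges in Hz.
#' @param filter_order Butterworth prototype order.
#' @param window epoch durations in s (margin, pre, post, margin).
#' @param baseline baseline interval in s relative to onset.
#' @param post post-stimulus averaging interval in s.
#' @param occurrence_threshold display threshold for edge occurrence.
#' @param ecc_variant `"range"` or `"max"` global eccentricity.
#' @param group_mst compute group-average trees per group?
#' @param reference_group group whose average matrix defines the reference
#'   tree for the overlap analysis.
#' @param p_adjust multiple-testing adjustment for the statistics table.
#' @param seed integer seed echoed into the provenance record.
#' @return An object of class `run_config`.
#' @export
run_config <- function(band = c(0.01, 0.15), filter_order = 4,
                       window = c(2, 4, 12, 2), baseline = c(-4, -1),
                       post = c(0, 12), occurrence_threshold = 0.25,
                       ecc_variant = c("range", "max"), group_mst = TRUE,
                       reference_group = "control",
                       p_adjust = c("none", "BH"), seed = 1L) {
  structure(
    list(band = as.numeric(band), filter_order = filter_order,
         window = as.numeric(window), baseline = as.numeric(baseline),
         post = as.numeric(post),
         occurrence_threshold = occurrence_threshold,
         ecc_variant = match.arg(ecc_variant),
         group_mst = isTRUE(group_mst),
         reference_group = reference_group,
         p_adjust = match.arg(p_adjust),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Connectivity matrix of one subject's epochs
#'
#' Convenience chain: instantaneous phase, PLV, baseline z-scoring,
#' post-stimulus averaging.
#'
#' @param epochs an [epoch_set()].
#' @param baseline,post intervals in seconds relative to onset.
#' @return A [connectivity_matrix()].
#' @export
epochs_to_tplv <- function(epochs, baseline = c(-4, -1), post = c(0, 12)) {
  tplv_matrix(normalize_plv(plv(analytic_signal(epochs)),
                            baseline = baseline),
              post = post)
}

#' Run the full analysis on a cohort
#'
#' Chains every stage for each subject (phase extraction, PLV, baseline
#' z-scoring, tPLV matrix, maximum spanning tree, topology metrics), then
#' group-level analyses: group-average trees, hub/edge occurrence, a
#' reference tree from the reference group's average matrix with per-subject
#' overlap, the group statistics table, and metric-clinical Spearman
#' correlations over the patients. If `out_dir` is given, a complete bundle
#' is written: per-subject tPLV matrices and tree edge lists, the metrics
#' and statistics tables, occurrence tables, group trees, and a
#' machine-readable provenance record. A failing stage aborts with the stage
#' name and the offending subject.
#'
#' @param cohort a `nirs_cohort` (from [generate_cohort()] or
#'   [read_cohort()]), or a directory path to a written cohort.
#' @param config a [run_config()].
#' @param out_dir optional output directory for the analysis bundle.
#' @return list with `metrics` (per-subject data frame), `stats`
#'   (group comparison table), `group_trees`, `occurrence` (per group),
#'   `reference_tree`, `correlations`, `trees` and `matrices` (per subject).
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "nirs_cohort"), inherits(config, "run_config"))
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e)
      stop_invalid("stage '", name, "' failed for subject ", id, ": ",
                   conditionMessage(e)))
  }
  ids <- vapply(cohort, function(s) s$record$subject_id, character(1))
  groups <- vapply(cohort, function(s) s$record$group, character(1))

  matrices <- list(); trees <- list(); rows <- list()
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    conn <- stage("connectivity", ids[i],
                  epochs_to_tplv(s$epochs, config$baseline, config$post))
    tree <- stage("mst", ids[i], kruskal_max_tree(conn))
    gm <- stage("metrics", ids[i],
                global_metrics(tree, ecc_variant = config$ecc_variant,
                               gplv = gplv(conn)))
    matrices[[ids[i]]] <- conn
    trees[[ids[i]]] <- tree
    rows[[i]] <- cbind(as.data.frame(s$record, stringsAsFactors = FALSE),
                       as.data.frame(gm))
  }
  metrics <- do.call(rbind, rows)

  group_trees <- NULL
  occ <- NULL
  if (config$group_mst) {
    group_trees <- lapply(split(matrices, groups), group_tree)
    occ <- lapply(split(trees, groups), occurrence,
                  threshold = config$occurrence_threshold)
  }
  ref_idx <- groups == config$reference_group
  if (!any(ref_idx))
    stop_invalid("reference group '", config$reference_group,
                 "' has no subjects")
  reference_tree <- group_tree(matrices[ref_idx])
  metrics$overlap <- vapply(trees, function(tr)
    overlap(tr, reference_tree)$overlap_percent, numeric(1))

  stats <- stats_table(metrics, p_adjust = config$p_adjust)
  clinical_fields <- intersect(c("disease_duration", "alsfrs_r"),
                               names(metrics))
  metric_names <- c("gplv", "leaf_fraction", "k_max", "bc_max",
                    "eccentricity", "kappa", "diameter", "tree_hierarchy",
                    "overlap")
  correlations <- NULL
  if (length(clinical_fields) && sum(groups == "patient") >= 4L) {
    grid <- expand.grid(metric = metric_names, clinical = clinical_fields,
                        stringsAsFactors = FALSE)
    correlations <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
      cc <- suppressWarnings(
        correlate_clinical(metrics, grid$metric[r], grid$clinical[r]))
      data.frame(metric = grid$metric[r], clinical = grid$clinical[r],
                 rho = cc$rho, p_value = cc$p_value, n = cc$n)
    }))
  }

  result <- list(metrics = metrics, stats = stats,
                 group_trees = group_trees, occurrence = occ,
                 reference_tree = reference_tree,
                 correlations = correlations,
                 trees = trees, matrices = matrices, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids) {
      write_matrix(matrices[[id]], file.path(out_dir, paste0(id, "_tplv.tsv")))
      write_tree(trees[[id]], file.path(out_dir, paste0(id, "_mst.tsv")))
    }
    write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(stats, file.path(out_dir, "stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(correlations))
      write.table(correlations, file.path(out_dir, "correlations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (config$group_mst) {
      for (g in names(group_trees)) {
        write_tree(group_trees[[g]],
                   file.path(out_dir, paste0("group_mst_", g, ".tsv")))
        write.table(occ[[g]]$hubs,
                    file.path(out_dir, paste0("occurrence_hubs_", g, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(occ[[g]]$edges,
                    file.path(out_dir, paste0("occurrence_edges_", g, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    write_tree(reference_tree, file.path(out_dir, "reference_mst.tsv"))
    provenance <- list(
      package = "nirsmst",
      version = as.character(packageVersion("nirsmst")),
      config = unclass(config),
      n_subjects = length(cohort),
      groups = as.list(table(groups)),
      n_trials = matrices[[1L]]$n_trials,
      M = matrices[[1L]]$M,
      seed = config$seed
    )
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
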