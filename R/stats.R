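#' Between-group comparison of a global metric
#'
#' Two-sided Mann-Whitney U test (Wilcoxon rank-sum) of a metric between the
#' patient and control groups. The exact null distribution is used when the
#' combined sample size is at most 25 and the data are tie-free; otherwise
#' the normal approximation with tie and continuity correction is used. The
#' reported U is the statistic of the patient sample. Being rank-based, the
#' result is invariant to any common monotone transform of the metric.
#'
#' @param records data frame with a `group` column (`"control"` /
#'   `"patient"`) and one column per metric.
#' @param metric name of the metric column to compare.
#' @return list with `U`, `p_value`, `method`, and per-group `n`, `mean`,
#'   `sd`.
#' @export
compare_groups <- function(records, metric) {
  stopifnot(is.data.frame(records), metric %in% names(records),
            "group" %in% names(records))
  x <- records[[metric]][records$group == "patient"]
  y <- records[[metric]][records$group == "control"]
  if (length(x) < 2L || length(y) < 2L)
    stop_invalid("each group needs at least 2 subjects")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 25L) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact)
  )
  list(
    U = unname(ht$statistic),
    p_value = ht$p.value,
    method = if (exact) "exact" else "normal approximation",
    n = c(patient = length(x), control = length(y)),
    mean = c(patient = mean(x), control = mean(y)),
    sd = c(patient = sd(x), control = sd(y))
  )
}

#' Group summary table of global metrics
#'
#' Means, standard deviations and Mann-Whitney p-values per metric,
#' mirroring the usual groupwise reporting layout. Per-metric p-values are
#' reported without multiple-testing correction by default; a
#' Benjamini-Hochberg adjusted column can be added.
#'
#' @param records data frame with `group` and metric columns.
#' @param metrics metric column names to summarize; defaults to every
#'   numeric column except bookkeeping fields.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data frame with one row per metric.
#' @export
stats_table <- function(records, metrics = NULL,
                        p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(metrics)) {
    skip <- c("subject_id", "group", "coupling_kappa", "disease_duration",
              "alsfrs_r", "leaf_count")
    metrics <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                       skip)
  }
  rows <- lapply(metrics, function(m) {
    r <- compare_groups(records, m)
    data.frame(metric = m,
               mean_control = r$mean[["control"]],
               sd_control = r$sd[["control"]],
               mean_patient = r$mean[["patient"]],
               sd_patient = r$sd[["patient"]],
               U = r$U, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_adjusted <- p.adjust(out$p_value, "BH")
  out
}

#' Correlation of a metric with a clinical score in patients
#'
#' Spearman rank correlation (average ranks for ties, two-sided p-value)
#' between a global network metric and a clinical score, over the patient
#' subset of the records.
#'
#' @param records data frame with `group`, metric and clinical columns.
#' @param metric metric column name.
#' @param clinical clinical score column name (e.g. `"disease_duration"` or
#'   `"alsfrs_r"`).
#' @return list with `rho`, `p_value` and `n`; `rho` is `NA` (with a
#'   warning) when either variable has zero variance.
#' @export
correlate_clinical <- function(records, metric, clinical) {
  stopifnot(is.data.frame(records), metric %in% names(records),
            clinical %in% names(records))
  pat <- records[records$group == "patient", , drop = FALSE]
  x <- pat[[metric]]
  y <- pat[[clinical]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L)
    stop_invalid("need at least 4 patients with both values")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in `", if (sd(x) == 0) metric else clinical,
            "`; Spearman rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ht <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided"))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
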