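# discrete analytic signal via the frequency-domain Hilbert transform:
# positive frequencies doubled, negative zeroed, DC (and Nyquist, if present)
# kept as is
analytic_1d <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of every epoch
#'
#' Computes the analytic signal of each trial/channel epoch with the discrete
#' Hilbert transform and returns the quadrant-correct instantaneous phase
#' `atan2(imag, real)`, wrapped to `(-pi, pi]`. The phase is computed over the
#' full epoch including its margins, which absorb the transform's edge
#' effects and are discarded later by the baseline and post-stimulus
#' averaging. Trials containing an all-zero channel epoch (undefined phase)
#' are dropped for all channels, with a warning, so every channel pair sees
#' the same trial set.
#'
#' @param epochs an [epoch_set()].
#' @return An object of class `phase_epochs`: phases
#'   (`trial x channel x sample`, radians), plus timing metadata.
#' @export
analytic_signal <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  zero_tc <- apply(epochs$data, c(1L, 2L), function(v) all(v == 0))
  bad_trials <- which(apply(zero_tc, 1L, any))
  keep <- setdiff(seq_len(d[1L]), bad_trials)
  if (length(bad_trials))
    warning("dropping ", length(bad_trials),
            " trial(s) with an all-zero channel epoch (undefined phase): ",
            paste(bad_trials, collapse = ", "), call. = FALSE)
  if (length(keep) < 1L)
    stop_invalid("no trials with a defined phase remain")
  phases <- array(NA_real_, c(length(keep), d[2L], d[3L]))
  for (i in seq_along(keep)) {
    for (ch in seq_len(d[2L])) {
      xa <- analytic_1d(epochs$data[keep[i], ch, ])
      phases[i, ch, ] <- wrap_angle(atan2(Im(xa), Re(xa)))
    }
  }
  structure(
    list(phases = phases, fs = epochs$fs, t_start = epochs$t_start,
         window = epochs$window, channel_labels = epochs$channel_labels,
         dropped_trials = bad_trials),
    class = "phase_epochs"
  )
}

#' Phase-locking value per channel pair and time point
#'
#' For every unordered channel pair \eqn{\{k, l\}} and sample \eqn{n}, the PLV
#' is the modulus of the trial-averaged unit phasor of the phase difference:
#' \deqn{PLV_{kl}[n] = \left| \frac{1}{N} \sum_{p=1}^{N}
#'   e^{j(\varphi_k[p,n] - \varphi_l[p,n])} \right|}
#' Values lie in `[0, 1]`; at least two trials are required (with a single
#' trial the PLV is identically 1).
#'
#' @param phases a `phase_epochs` object from [analytic_signal()].
#' @return An object of class `plv_time_series` with `kind = "plv"`: a
#'   `pair x sample` value matrix, the pair index (`k < l`), trial count and
#'   timing metadata.
#' @export
plv <- function(phases) {
  stopifnot(inherits(phases, "phase_epochs"))
  d <- dim(phases$phases)
  if (d[1L] < 2L)
    stop_invalid("PLV requires at least 2 trials (degenerate at 1 for a ",
                 "single trial)")
  pairs <- t(combn(d[2L], 2L))
  phasor <- exp(1i * phases$phases)
  values <- matrix(NA_real_, nrow(pairs), d[3L])
  for (r in seq_len(nrow(pairs))) {
    zk <- matrix(phasor[, pairs[r, 1L], ], nrow = d[1L])
    zl <- matrix(phasor[, pairs[r, 2L], ], nrow = d[1L])
    values[r, ] <- Mod(colMeans(zk * Conj(zl)))
  }
  structure(
    list(values = values, pairs = pairs, kind = "plv",
         n_trials = d[1L], fs = phases$fs, t_start = phases$t_start,
         window = phases$window, channel_labels = phases$channel_labels,
         baseline_mean = NULL, baseline_sd = NULL),
    class = "plv_time_series"
  )
}

#' Baseline z-scoring of the PLV (zPLV)
#'
#' Normalizes each pair's PLV time course against its own pre-stimulus
#' baseline (default `[-4, -1)` s relative to onset):
#' \deqn{zPLV_{kl}[n] = (PLV_{kl}[n] - \mu_{kl}) / \sigma_{kl}}
#' where \eqn{\mu_{kl}} and \eqn{\sigma_{kl}} are the mean and population
#' standard deviation of that pair's PLV over the baseline samples. This
#' cancels stationary, task-unrelated phase synchronization. A pair with a
#' constant baseline (\eqn{\sigma_{kl} = 0}) is set to zero with a warning.
#'
#' @param x a `plv_time_series` with `kind = "plv"`.
#' @param baseline half-open baseline interval in seconds relative to onset.
#' @return A `plv_time_series` with `kind = "zplv"` and the per-pair baseline
#'   statistics stored.
#' @export
normalize_plv <- function(x, baseline = c(-4, -1)) {
  stopifnot(inherits(x, "plv_time_series"))
  if (x$kind != "plv")
    stop_invalid("input must be a raw PLV series (kind \"plv\"), not ", x$kind)
  t <- epoch_time(x)
  idx <- which(t >= baseline[1L] & t < baseline[2L])
  if (length(idx) < 2L)
    stop_invalid("baseline window [", baseline[1L], ", ", baseline[2L],
                 ") s maps to fewer than 2 samples")
  base <- x$values[, idx, drop = FALSE]
  mu <- rowMeans(base)
  sigma <- row_pop_sd(base)
  degenerate <- sigma == 0
  z <- (x$values - mu) / ifelse(degenerate, 1, sigma)
  if (any(degenerate)) {
    z[degenerate, ] <- 0
    warning(sum(degenerate), " pair(s) with constant baseline PLV ",
            "(sigma = 0); their zPLV is set to 0", call. = FALSE)
  }
  x$values <- z
  x$kind <- "zplv"
  x$baseline_mean <- mu
  x$baseline_sd <- sigma
  x$baseline <- as.numeric(baseline)
  x
}

#' Post-stimulus average: the tPLV adjacency matrix
#'
#' Averages each pair's zPLV over the `M = round(post_duration * fs)` samples
#' of the post-stimulus window (default `[0, 12)` s; `M = 94` at 7.81 Hz) and
#' arranges the result as a symmetric `channel x channel` matrix with a zero
#' diagonal (self-connections are excluded from analysis).
#'
#' @param x a `plv_time_series` with `kind = "zplv"`.
#' @param post post-stimulus interval in seconds relative to onset.
#' @return An object of class `connectivity_matrix`: the tPLV matrix,
#'   channel labels, the number of averaged samples `M`, and the trial count.
#' @export
tplv_matrix <- function(x, post = c(0, 12)) {
  stopifnot(inherits(x, "plv_time_series"))
  if (x$kind != "zplv")
    stop_invalid("input must be baseline-normalized (kind \"zplv\"); ",
                 "call normalize_plv() first")
  t <- epoch_time(x)
  i0 <- which(t >= post[1L])[1L]
  m <- round((post[2L] - post[1L]) * x$fs)
  if (is.na(i0) || m < 1L)
    stop_invalid("empty post-stimulus window")
  if (i0 + m - 1L > ncol(x$values))
    stop_invalid("post-stimulus window extends past the epoch end")
  tplv <- rowMeans(x$values[, i0 + seq_len(m) - 1L, drop = FALSE])
  n <- length(x$channel_labels)
  mat <- matrix(0, n, n, dimnames = list(x$channel_labels, x$channel_labels))
  mat[x$pairs] <- tplv
  mat <- mat + t(mat)
  connectivity_matrix(mat, channel_labels = x$channel_labels,
                      M = m, n_trials = x$n_trials)
}

#' Connectivity (tPLV adjacency) matrix
#'
#' Symmetric `channel x channel` matrix of post-stimulus-averaged normalized
#' phase-locking values, with a fixed zero diagonal.
#'
#' @param matrix symmetric numeric matrix; its diagonal is forced to 0.
#' @param channel_labels channel names.
#' @param M number of post-stimulus samples averaged (metadata).
#' @param n_trials number of trials behind the estimate (metadata).
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(matrix, channel_labels = NULL,
                                M = NA_integer_, n_trials = NA_integer_) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop_invalid("connectivity matrix must be square")
  if (any(!is.finite(m))) stop_invalid("connectivity matrix has non-finite entries")
  if (max(abs(m - t(m))) > 1e-8)
    stop_invalid("connectivity matrix must be symmetric")
  diag(m) <- 0
  channel_labels <- channel_labels %||% rownames(m) %||%
    default_channel_labels(nrow(m))
  if (anyDuplicated(channel_labels))
    stop_invalid("duplicated channel label: ",
                 channel_labels[duplicated(channel_labels)][1L])
  dimnames(m) <- list(channel_labels, channel_labels)
  structure(
    list(matrix = m, channel_labels = channel_labels, M = M,
         n_trials = n_trials),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x$matrix), " x ", ncol(x$matrix),
      " tPLV (M = ", x$M, ", trials = ", x$n_trials, ")\n", sep = "")
  invisible(x)
}

#' Global PLV
#'
#' Subject-level synchronization summary: the mean of the tPLV matrix over
#' all unordered channel pairs (the strictly upper triangular entries; 91
#' pairs for 14 channels).
#'
#' @param conn a [connectivity_matrix()].
#' @return scalar gPLV.
#' @export
gplv <- function(conn) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  mean(conn$matrix[upper.tri(conn$matrix)])
}
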