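#' Edge list of a named coupling template
#'
#' Builds the spanning-tree edge list used to plant phase coupling across
#' channels: `"star"` (channel 1 is the hub), `"line"` (channels chained in
#' order), or a user-supplied two-column edge matrix, which is validated as a
#' spanning tree over the channel set.
#'
#' @param template `"star"`, `"line"`, or a two-column integer matrix of
#'   channel-index pairs.
#' @param n_channels number of channels.
#' @return Integer matrix with two columns (`from`, `to`) and
#'   `n_channels - 1` rows.
#' @export
template_edges <- function(template, n_channels) {
  if (is.character(template) && length(template) == 1L) {
    edges <- switch(template,
      star = cbind(1L, seq(2L, n_channels)),
      line = cbind(seq_len(n_channels - 1L), seq(2L, n_channels)),
      stop_invalid("unknown template '", template, "' (use \"star\", \"line\" ",
                   "or an explicit edge matrix)")
    )
  } else {
    edges <- matrix(as.integer(template), ncol = 2L)
  }
  if (!is_spanning_tree(edges, n_channels))
    stop_invalid("coupling_template is not a spanning tree over ", n_channels,
                 " channels: it must have ", n_channels - 1L,
                 " edges, be connected, and be acyclic")
  colnames(edges) <- c("from", "to")
  edges
}

# spanning-tree check: n-1 edges, valid endpoints, single connected component
# (which for n-1 edges also implies acyclicity)
is_spanning_tree <- function(edges, n) {
  if (!is.matrix(edges) || ncol(edges) != 2L) return(FALSE)
  if (nrow(edges) != n - 1L) return(FALSE)
  if (any(edges < 1L | edges > n) || any(edges[, 1L] == edges[, 2L]))
    return(FALSE)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Von Mises random angles
#'
#' Rejection sampler (Best & Fisher 1979) for the von Mises distribution with
#' mean direction 0 and concentration `kappa`; `kappa = 0` reduces to the
#' circular uniform.
#'
#' @param n number of draws.
#' @param kappa concentration parameter, `>= 0`.
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 0) stop_invalid("`kappa` must be >= 0")
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(keep)
    if (k > 0L) {
      theta <- sign(runif(k) - 0.5) * acos(pmin(pmax(f[keep], -1), 1))
      out[got + seq_len(k)] <- theta
      got <- got + k
    }
  }
  out
}

#' Configuration of the synthetic fNIRS cohort generator
#'
#' Describes one group of simulated subjects. Each trial epoch is a
#' narrowband carrier inside the hemodynamic pass band plus white Gaussian
#' noise; phase coupling is planted on the edges of a spanning-tree template:
#' per trial, a root phase is drawn uniformly and propagated along template
#' edges with independent von Mises increments of concentration
#' `coupling_kappa`, so channels joined by an edge share the trial phase up
#' to jitter, and phase similarity decays with tree distance. Before
#' stimulus onset every channel instead carries an independent uniform trial
#' phase, so baseline z-scoring of the phase-locking value removes
#' task-unrelated synchronization. Defaults mirror the study geometry:
#' 14 channels at 7.81 Hz, 28 target trials, epochs of 2+4+12+2 s.
#'
#' @param n_subjects_per_group subjects simulated per call to
#'   [generate_cohort()].
#' @param n_trials trials (epochs) per subject.
#' @param n_channels number of channels.
#' @param fs sampling rate in Hz.
#' @param window epoch durations in s (leading margin, pre, post, trailing
#'   margin).
#' @param carrier_freq carrier frequency in Hz; must lie strictly inside the
#'   0.01-0.15 Hz analysis band.
#' @param coupling_template `"star"`, `"line"`, or an explicit edge matrix
#'   (see [template_edges()]).
#' @param coupling_kappa von Mises concentration of the per-edge phase
#'   jitter; 0 plants no coupling.
#' @param kappa_spread log-normal spread of the per-subject realized
#'   concentration (`kappa_i = coupling_kappa * exp(N(0, kappa_spread^2))`);
#'   0 gives every subject the nominal value.
#' @param noise_sd standard deviation of the additive white noise, in units
#'   of the (unit) carrier amplitude.
#' @param baseline_drift_sd Wiener phase-diffusion rate of the uncoupled
#'   (pre-stimulus) oscillation, in rad per square-root second, independent
#'   per trial and channel. Spontaneous low-frequency oscillations are only
#'   weakly coherent; the default 1.0 lets the inter-channel phase
#'   configuration turn over several times within the 3-s baseline, so the
#'   baseline standard deviation used for z-scoring reflects genuine
#'   synchronization variability rather than additive noise alone.
#' @param locking_rate post-stimulus phase-relaxation rate in 1/s: after
#'   onset each channel's phase relaxes exponentially (Ornstein-Uhlenbeck)
#'   onto its coupled target, reaching lock within ~1/`locking_rate` s.
#' @param locked_drift_sd residual phase-diffusion rate (rad per square-root
#'   second) around the locked target after onset; with `locking_rate`
#'   \eqn{\lambda} the stationary fluctuation is
#'   `locked_drift_sd / sqrt(2 * locking_rate)` rad.
#' @param hrf_envelope if `TRUE`, the post-stimulus carrier is amplitude-
#'   modulated by a canonical-shaped hemodynamic envelope; off by default
#'   (phase analysis is amplitude-invariant).
#' @param clinical_link function mapping a subject's realized
#'   `coupling_kappa` to a named list of synthetic clinical scores; the
#'   default yields a disease duration (years, increasing in coupling) and an
#'   ALSFRS-R-like score (0-48, decreasing in coupling).
#' @param channel_labels channel names.
#' @param seed integer root seed; subject `i` uses the derived stream
#'   `seed + i`.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects_per_group = 10L,
                             n_trials = 28L,
                             n_channels = 14L,
                             fs = 7.81,
                             window = c(2, 4, 12, 2),
                             carrier_freq = 0.05,
                             coupling_template = "star",
                             coupling_kappa = 2,
                             kappa_spread = 0.25,
                             noise_sd = 0.3,
                             baseline_drift_sd = 1.0,
                             locking_rate = 1.5,
                             locked_drift_sd = 0.3,
                             hrf_envelope = FALSE,
                             clinical_link = default_clinical_link,
                             channel_labels = NULL,
                             seed = 1L) {
  if (n_subjects_per_group < 1L || n_trials < 1L || n_channels < 2L)
    stop_invalid("subject, trial and channel counts must be positive")
  if (!(carrier_freq > 0.01 && carrier_freq < 0.15))
    stop_invalid("`carrier_freq` must lie strictly inside (0.01, 0.15) Hz")
  if (coupling_kappa < 0) stop_invalid("`coupling_kappa` must be >= 0")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (baseline_drift_sd < 0 || locked_drift_sd < 0 || locking_rate < 0)
    stop_invalid("phase-dynamics rates must be >= 0")
  edges <- template_edges(coupling_template, n_channels)
  cfg <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_trials = as.integer(n_trials),
    n_channels = as.integer(n_channels),
    fs = fs, window = as.numeric(window),
    carrier_freq = carrier_freq,
    coupling_template = edges,
    coupling_kappa = coupling_kappa,
    kappa_spread = kappa_spread,
    noise_sd = noise_sd,
    baseline_drift_sd = baseline_drift_sd,
    locking_rate = locking_rate,
    locked_drift_sd = locked_drift_sd,
    hrf_envelope = isTRUE(hrf_envelope),
    clinical_link = clinical_link,
    channel_labels = channel_labels %||% default_channel_labels(n_channels),
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default link from planted coupling strength to clinical scores
#'
#' Strictly monotone map used by [generate_cohort()]: disease duration
#' (years) increases and the ALSFRS-R-like disability score decreases with
#' the subject's realized coupling concentration, so rank-correlation
#' recovery is testable in both directions.
#'
#' @param kappa realized coupling concentration of a subject.
#' @return named list with `disease_duration` (years) and `alsfrs_r` (0-48).
#' @export
default_clinical_link <- function(kappa) {
  list(
    disease_duration = 12 * kappa / (kappa + 2),
    alsfrs_r = as.integer(round(48 / (1 + kappa)))
  )
}

# double-gamma amplitude envelope peaking ~6 s post-onset, normalized to 1
hrf_weight <- function(t) {
  w <- ifelse(t > 0,
              (t / 6)^5 * exp(-(t - 6) / 1) -
                0.35 * (t / 12)^10 * exp(-(t - 12) / 1.2),
              0)
  w / max(w, 1e-12)
}

#' Generate one synthetic subject
#'
#' Simulates a full `epoch_set` for one subject: `n_trials x n_channels x
#' round(total_window * fs)` samples of noisy phase oscillators. Before
#' stimulus onset each channel's phase performs an independent Wiener
#' diffusion (rate `baseline_drift_sd`) from a uniform start, so
#' inter-channel synchronization is at chance and its level fluctuates
#' within the baseline window. At onset each channel's phase relaxes
#' (Ornstein-Uhlenbeck, rate `locking_rate`) onto a trial-specific coupled
#' target: a root phase drawn uniformly per trial and propagated along the
#' template edges with independent von Mises increments of concentration
#' `coupling_kappa`, so channels joined by an edge share the trial phase up
#' to jitter and phase similarity decays with tree distance. Output is
#' deterministic given `(config$seed, subject_index)`.
#'
#' @param config a [synthetic_config()].
#' @param subject_index non-negative integer selecting the subject's
#'   reproducible random stream.
#' @return An [epoch_set()].
#' @export
generate_subject <- function(config, subject_index = 0L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (subject_index < 0L) stop_invalid("`subject_index` must be >= 0")
  with_seed(config$seed + as.integer(subject_index), {
    fs <- config$fs
    nt <- config$n_trials
    nch <- config$n_channels
    ns <- round(sum(config$window) * fs)
    t <- -(config$window[1L] + config$window[2L]) + (seq_len(ns) - 1L) / fs

    # coupled post-stimulus target phases: root phase propagated along the
    # template in breadth-first order with von Mises edge increments
    edges <- config$coupling_template
    order_edges <- bfs_edge_order(edges, nch)
    target <- matrix(NA_real_, nt, nch)
    target[, order_edges$root] <- runif(nt, -pi, pi)
    for (r in seq_len(nrow(order_edges$edges))) {
      par <- order_edges$edges[r, 1L]
      child <- order_edges$edges[r, 2L]
      target[, child] <- wrap_angle(target[, par] +
                                      rvonmises(nt, config$coupling_kappa))
    }

    amp <- if (config$hrf_envelope) {
      a <- hrf_weight(t)
      pmax(a, 0.15) # keep a phase-defined carrier throughout the epoch
    } else rep(1, ns)

    dt <- 1 / fs
    step_base <- config$baseline_drift_sd * sqrt(dt)
    step_lock <- config$locked_drift_sd * sqrt(dt)
    decay <- exp(-config$locking_rate * dt)
    carrier <- 2 * pi * config$carrier_freq * t
    post <- t >= 0
    data <- array(NA_real_, c(nt, nch, ns))
    for (ch in seq_len(nch)) {
      psi <- matrix(NA_real_, nt, ns)
      psi[, 1L] <- runif(nt, -pi, pi)
      dev <- NULL # deviation from the coupled target, once locked
      for (n in seq(2L, ns)) {
        if (!post[n]) {
          psi[, n] <- psi[, n - 1L] + rnorm(nt, sd = step_base)
        } else {
          if (is.null(dev)) dev <- wrap_angle(psi[, n - 1L] - target[, ch])
          dev <- dev * decay + rnorm(nt, sd = step_lock)
          psi[, n] <- target[, ch] + dev
        }
      }
      phase <- sweep(psi, 2L, carrier, "+")
      data[, ch, ] <- rep(amp, each = nt) * cos(phase) +
        matrix(rnorm(nt * ns, sd = config$noise_sd), nt, ns)
    }
    epoch_set(data, fs = fs, window = config$window,
              channel_labels = config$channel_labels)
  })
}

# orient tree edges parent -> child in BFS order from node 1
bfs_edge_order <- function(edges, n) {
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  seen[1L] <- TRUE
  queue <- 1L
  out <- matrix(integer(0), ncol = 2L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[v]]) {
      if (!seen[nb]) {
        seen[nb] <- TRUE
        out <- rbind(out, c(v, nb))
        queue <- c(queue, nb)
      }
    }
  }
  list(root = 1L, edges = out)
}

#' Generate a labeled two-group cohort
#'
#' Simulates `n_subjects_per_group` subjects per configuration. Each
#' subject's realized coupling concentration is drawn log-normally around the
#' group's `coupling_kappa` (spread `kappa_spread`), the epochs are generated
#' with that realized value, and the clinical scores are produced by the
#' group's `clinical_link` applied to the same realized value, so
#' rank-correlation between pipeline outputs and scores is recoverable by
#' construction. Both configurations must share the epoch geometry
#' (`fs`, `window`, `n_channels`).
#'
#' @param config_hc configuration of the control group.
#' @param config_patient configuration of the patient group.
#' @return An object of class `nirs_cohort`: a list of subjects, each a list
#'   with elements `epochs` (an [epoch_set()]) and `record` (subject id,
#'   group label, realized `coupling_kappa`, and the clinical scores).
#' @export
generate_cohort <- function(config_hc, config_patient) {
  stopifnot(inherits(config_hc, "synthetic_config"),
            inherits(config_patient, "synthetic_config"))
  same <- isTRUE(all.equal(config_hc$fs, config_patient$fs)) &&
    isTRUE(all.equal(config_hc$window, config_patient$window)) &&
    config_hc$n_channels == config_patient$n_channels
  if (!same)
    stop_invalid("group configurations disagree on epoch geometry ",
                 "(fs, window, n_channels)")
  build_group <- function(config, group, prefix) {
    lapply(seq_len(config$n_subjects_per_group), function(i) {
      kappa_i <- with_seed(config$seed + 100000L + i,
        config$coupling_kappa * exp(rnorm(1L, 0, config$kappa_spread)))
      cfg_i <- config
      cfg_i$coupling_kappa <- kappa_i
      epochs <- generate_subject(cfg_i, i)
      scores <- config$clinical_link(kappa_i)
      record <- c(list(subject_id = sprintf("%s-%02d", prefix, i),
                       group = group, coupling_kappa = kappa_i),
                  scores)
      list(epochs = epochs, record = record)
    })
  }
  cohort <- c(build_group(config_hc, "control", "HC"),
              build_group(config_patient, "patient", "ALS"))
  attr(cohort, "configs") <- list(control = config_hc,
                                  patient = config_patient)
  class(cohort) <- "nirs_cohort"
  cohort
}

#' @export
print.nirs_cohort <- function(x, ...) {
  groups <- vapply(x, function(s) s$record$group, character(1))
  cat("<nirs_cohort> ", length(x), " subjects (",
      sum(groups == "control"), " control, ",
      sum(groups == "patient"), " patient)\n", sep = "")
  invisible(x)
}

#' Cohort records as a data frame
#'
#' @param x a `nirs_cohort`.
#' @param ... unused.
#' @return data frame with one row per subject.
#' @export
cohort_records <- function(x, ...) {
  stopifnot(inherits(x, "nirs_cohort"))
  do.call(rbind, lapply(x, function(s)
    as.data.frame(s$record, stringsAsFactors = FALSE)))
}
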