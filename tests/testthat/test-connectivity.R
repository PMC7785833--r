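test_that("instantaneous phase of a cosine is its argument, away from edges", {
  fs <- 7.81
  f0 <- 2 * fs / 156 # two full cycles per 156-sample epoch (~0.1 Hz)
  ep <- make_epochs(function(p, ch, t) cos(2 * pi * f0 * t),
                    n_trials = 2, n_channels = 2)
  ph <- analytic_signal(ep)
  t <- epoch_time(ep)
  central <- t >= -4 & t < 12
  expected <- atan2(sin(2 * pi * f0 * t), cos(2 * pi * f0 * t))
  err <- abs(atan2(sin(ph$phases[1, 1, ] - expected),
                   cos(ph$phases[1, 1, ] - expected)))
  expect_lt(max(err[central]), 0.05)
  expect_true(all(ph$phases > -pi & ph$phases <= pi))
})

test_that("phase is quadrature-sensitive but amplitude-invariant", {
  fs <- 7.81; f0 <- 0.08
  ep <- make_epochs(function(p, ch, t)
    if (ch == 1) cos(2 * pi * f0 * t) else sin(2 * pi * f0 * t),
    n_trials = 2, n_channels = 2)
  ph <- analytic_signal(ep)
  t <- epoch_time(ep)
  central <- which(t >= -2 & t < 10)
  dphi <- ph$phases[1, 1, central] - ph$phases[1, 2, central]
  dphi <- atan2(sin(dphi), cos(dphi))
  expect_equal(mean(dphi), pi / 2, tolerance = 0.05)

  ep3 <- make_epochs(function(p, ch, t) 3 * cos(2 * pi * f0 * t),
                     n_trials = 2, n_channels = 2)
  ph3 <- analytic_signal(ep3)
  ep1 <- make_epochs(function(p, ch, t) cos(2 * pi * f0 * t),
                     n_trials = 2, n_channels = 2)
  ph1 <- analytic_signal(ep1)
  expect_equal(ph3$phases, ph1$phases, tolerance = 1e-10)
})

test_that("all-zero epochs are flagged and dropped consistently", {
  ep <- make_epochs(function(p, ch, t)
    if (p == 2 && ch == 1) 0 * t else cos(0.3 * t + p + ch),
    n_trials = 3, n_channels = 2)
  expect_warning(ph <- analytic_signal(ep), "all-zero")
  expect_equal(dim(ph$phases)[1], 2L)
  expect_equal(ph$dropped_trials, 2L)
})

test_that("PLV degenerate and antipodal cases", {
  # identical phases in both channels, every trial -> PLV = 1 everywhere
  ph <- structure(list(
    phases = array(rep(seq(-3, 3, length.out = 24), each = 2 * 2),
                   c(2, 2, 24)),
    fs = 2, t_start = -6, window = c(2, 4, 4, 2),
    channel_labels = c("a", "b")), class = "phase_epochs")
  v <- plv(ph)
  expect_equal(v$values, matrix(1, 1, 24), tolerance = 1e-12)

  # two trials with phase differences 0 and pi -> PLV = 0 there
  phases <- array(0, c(2, 2, 3))
  phases[2, 1, 2] <- pi # trial 2, channel 1, sample 2
  ph2 <- structure(list(phases = phases, fs = 1, t_start = 0,
                        window = c(0, 0, 3, 0),
                        channel_labels = c("a", "b")),
                   class = "phase_epochs")
  v2 <- plv(ph2)
  expect_equal(v2$values[1, 2], 0, tolerance = 1e-12)
  expect_equal(v2$values[1, 1], 1, tolerance = 1e-12)

  # a single trial is rejected as degenerate
  ph1 <- structure(list(phases = array(0, c(1, 2, 5)), fs = 1, t_start = 0,
                        window = c(0, 0, 5, 0),
                        channel_labels = c("a", "b")),
                   class = "phase_epochs")
  expect_error(plv(ph1), "2 trials")
})

test_that("PLV of independent uniform phases matches the Rayleigh mean", {
  set.seed(5)
  n_tr <- 28
  ph <- structure(list(
    phases = array(runif(n_tr * 21 * 40, -pi, pi), c(n_tr, 21, 40)),
    fs = 1, t_start = 0, window = c(0, 0, 40, 0),
    channel_labels = sprintf("c%02d", 1:21)), class = "phase_epochs")
  v <- plv(ph) # 210 pairs x 40 samples
  # sqrt(pi/(4N)) is the large-N Rayleigh mean; at N = 28 the exact mean sits
  # ~0.5% above it, so the band covers Monte-Carlo error plus that bias
  expect_equal(mean(v$values), sqrt(pi / (4 * n_tr)), tolerance = 0.02)
  expect_true(all(v$values >= 0 & v$values <= 1))
})

test_that("PLV is invariant to a per-trial common phase shift", {
  set.seed(8)
  base <- array(runif(6 * 3 * 20, -pi, pi), c(6, 3, 20))
  shifts <- runif(6, -pi, pi)
  shifted <- base + array(shifts, c(6, 3, 20)) # same shift for all channels
  mk <- function(a) structure(list(phases = a, fs = 1, t_start = 0,
                                   window = c(0, 0, 20, 0),
                                   channel_labels = c("a", "b", "c")),
                              class = "phase_epochs")
  expect_equal(plv(mk(base))$values, plv(mk(shifted))$values,
               tolerance = 1e-12)
})

test_that("baseline z-scoring: direct arithmetic and invariances", {
  # baseline [-4,-1) at fs 0.5 starting at -4: exactly samples 1 and 2
  x <- fake_plv(c(0.4, 0.6, 0.7, 0.7), fs = 0.5, t_start = -4)
  z <- normalize_plv(x)
  expect_equal(z$baseline_mean, 0.5)
  expect_equal(z$baseline_sd, 0.1)
  expect_equal(z$values[1, 3], 2.0) # (0.7 - 0.5) / 0.1
  expect_equal(z$kind, "zplv")

  # location invariance: shifting the pair's PLV leaves zPLV unchanged
  x2 <- fake_plv(c(0.4, 0.6, 0.7, 0.7) + 0.2, fs = 0.5, t_start = -4)
  expect_equal(normalize_plv(x2)$values, z$values, tolerance = 1e-12)

  # constant baseline: sigma guard sets the pair to zero with a warning
  xc <- fake_plv(c(0.5, 0.5, 0.5, 0.9), fs = 0.5, t_start = -4)
  expect_warning(zc <- normalize_plv(xc), "constant baseline")
  expect_true(all(zc$values == 0))

  # a zPLV input cannot be normalized again
  expect_error(normalize_plv(z), "raw PLV")
})

test_that("tPLV averaging: M = 94 at 7.81 Hz and a naive-sum oracle", {
  fs <- 7.81; ns <- 156
  set.seed(13)
  vals <- matrix(runif(3 * ns), 3, ns)
  z <- fake_plv(vals, fs = fs, t_start = -6, kind = "zplv", n_channels = 3)
  conn <- tplv_matrix(z)
  expect_equal(conn$M, 94L)
  t <- -6 + (seq_len(ns) - 1) / fs
  idx <- which(t >= 0)[1] + 0:93
  for (r in 1:3) {
    s <- 0
    for (i in idx) s <- s + vals[r, i]
    expect_equal(conn$matrix[z$pairs[r, 1], z$pairs[r, 2]], s / 94,
                 tolerance = 1e-12)
  }
  expect_equal(conn$matrix, t(conn$matrix))
  expect_true(all(diag(conn$matrix) == 0))

  zc <- fake_plv(matrix(1.5, 1, ns), fs = fs, t_start = -6, kind = "zplv")
  expect_equal(tplv_matrix(zc)$matrix[1, 2], 1.5)

  expect_error(tplv_matrix(fake_plv(vals, fs, -6, kind = "plv",
                                    n_channels = 3)), "normalized")
  short <- fake_plv(matrix(1, 1, 60), fs = fs, t_start = -6, kind = "zplv")
  expect_error(tplv_matrix(short), "past the epoch end")
  all_pre <- fake_plv(matrix(1, 1, 10), fs = fs, t_start = -6, kind = "zplv")
  expect_error(tplv_matrix(all_pre), "empty post-stimulus")
})

test_that("gPLV is the mean over unordered pairs and permutation-invariant", {
  m <- matrix(0, 14, 14)
  m[upper.tri(m)] <- 1:91
  m <- m + t(m)
  conn <- connectivity_matrix(m)
  expect_equal(gplv(conn), 46) # mean of 1..91
  perm <- sample(14)
  conn_p <- connectivity_matrix(m[perm, perm],
                                channel_labels = conn$channel_labels[perm])
  expect_equal(gplv(conn_p), 46)

  ones <- matrix(1, 5, 5); diag(ones) <- 0
  expect_equal(gplv(connectivity_matrix(ones)), 1)
})

test_that("baseline z-scoring cancels stationary synchronization up to its ratio bias", {
  # Under an uncoupled cohort the raw PLV is stationary across the epoch
  # (the Eq.-5 numerator is unbiased); the z-scored average retains only the
  # small positive ratio bias of dividing by a 24-sample baseline SD, an
  # order of magnitude below the across-pair spread.
  cfg <- synthetic_config(coupling_kappa = 0, kappa_spread = 0, seed = 505)
  raw_profile <- 0
  tplvs <- c()
  n_subj <- 20
  for (i in seq_len(n_subj)) {
    p <- plv(analytic_signal(generate_subject(cfg, i)))
    raw_profile <- raw_profile + colMeans(p$values) / n_subj
    conn <- tplv_matrix(normalize_plv(p))
    tplvs <- c(tplvs, conn$matrix[upper.tri(conn$matrix)])
  }
  t <- -6 + (0:155) / 7.81
  base_level <- mean(raw_profile[t >= -4 & t < -1])
  post_level <- mean(raw_profile[t >= 0 & t < 12])
  expect_equal(post_level, base_level, tolerance = 0.02)
  expect_equal(base_level, sqrt(pi / (4 * 28)), tolerance = 0.05)
  expect_lt(abs(mean(tplvs)), 0.15)
  expect_gt(sd(tplvs), 0.5) # bias is small relative to the pair spread
})

test_that("margins absorb analytic-signal edge effects", {
  fs <- 7.81; f0 <- 0.06
  set.seed(21)
  thetas <- runif(8, -pi, pi)
  mk <- function(window) {
    make_epochs(function(p, ch, t)
      cos(2 * pi * f0 * t + thetas[p]) + 0.05 * sin(37 * t + p * ch),
      n_trials = 8, n_channels = 2, window = window)
  }
  full <- plv(analytic_signal(mk(c(2, 4, 12, 2))))
  trim <- plv(analytic_signal(mk(c(0, 4, 12, 0))))
  t_full <- epoch_time(full)
  keep <- t_full >= -4 & t_full < 12
  a <- full$values[1, keep]
  b <- trim$values[1, ]
  n <- min(length(a), length(b))
  d <- abs(a[seq_len(n)] - b[seq_len(n)])
  edge <- mean(d[c(1:5, (n - 4):n)])
  center <- mean(d[(n %/% 2 - 10):(n %/% 2 + 10)])
  expect_gt(edge, center)
})
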