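---
title: "Phase-locking connectivity and spanning-tree topology for fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking connectivity and spanning-tree topology for fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(nirsmst)
```

## The analysis in one paragraph

`nirsmst` quantifies how the functional organization of a small optode
montage (typically 14 frontal fNIRS channels) changes during a task, and
whether that organization differs between a patient group and controls.
Trial epochs of HbO2 are reduced to a channel-by-channel synchronization
matrix with the phase-locking value (PLV), z-scored against each pair's own
pre-stimulus baseline so that stationary, task-unrelated synchronization
cancels. The matrix is then collapsed to its maximum-connectivity spanning
tree — an acyclic backbone whose shape depends only on the *order* of the
connection weights, which makes tree-shape statistics comparable across
subjects and studies without arbitrary density thresholds. Tree topology is
summarized by nodal metrics (degree, betweenness centrality, eccentricity)
and global metrics (leaf fraction, maximum degree, degree divergence,
diameter, tree hierarchy, reference-tree overlap), compared between groups
with rank-sum tests, and correlated with clinical scores by Spearman rank
correlation.

## Signal model and processing conventions

**Epoch geometry.** Epochs span `[-6, 14)` s around each stimulus onset at
`fs = 7.81` Hz: a 4-s pre-stimulus segment supporting the baseline, a 12-s
post-stimulus window, and 2-s margins at both edges whose only purpose is to
absorb edge effects of the analytic-signal computation — they are never
averaged. Each epoch therefore has `round(20 * fs) = 156` samples.
Time-to-sample maps use `floor(t * fs)` with half-open windows `[start,
end)`; the baseline is `[-4, -1)` s and the post-stimulus average runs over
`M = round(12 * fs) = 94` samples from the first sample at `t >= 0`.

**Filtering.** Continuous recordings are band-limited to 0.01–0.15 Hz with a
4th-order Butterworth filter applied forward and backward
(`signal::filtfilt`), so instantaneous phase is not biased by filter delay.
The band edges are the task-related hemodynamic band; the realization (family
and order) is a package choice, validated to hold mid-band gain within 5%
and attenuate the respiratory band (0.3 Hz) by more than 20 dB at this
sampling rate. Filtering twice changes a mid-band sinusoid by well under 10%,
so the operation is idempotent for practical purposes.

**Beer–Lambert step.** When raw two-wavelength (760/850 nm) optical-density
changes are supplied, `beer_lambert()` solves the 2×2 extinction system per
channel and sample and returns HbO2 only. The extinction coefficients are
tabulated Gratzer/Cope-derived values and the differential pathlength factor
defaults to 6.0 at both wavelengths; acquisition software rarely reports its
constants, so all of them are arguments, and a pipeline that starts from
exported HbO2 (the normal case) skips this step entirely.

**Phase and PLV.** The analytic signal is computed by the discrete Hilbert
transform (positive frequencies doubled, negative zeroed in the DFT), and
the instantaneous phase is the quadrant-correct `atan2(imag, real)`. For
channels $k,l$ and sample $n$, over $N$ trials,

$$PLV_{kl}[n] = \left|\tfrac1N \sum_{p=1}^{N}
  e^{j(\varphi_k[p,n]-\varphi_l[p,n])}\right| \in [0,1],$$

$$zPLV_{kl}[n] = \frac{PLV_{kl}[n]-\mu_{kl}}{\sigma_{kl}}, \qquad
tPLV_{kl} = \tfrac1M \sum_{n \in \text{post}} zPLV_{kl}[n],$$

with $\mu_{kl}, \sigma_{kl}$ the mean and *population* (divide-by-$n$)
standard deviation of that pair's baseline PLV — the population form is a
declared convention, as is the half-open baseline window. Degenerate cases
are guarded explicitly: a single trial is rejected (PLV would be identically
1); an all-zero trial/channel epoch has no phase and drops that trial for
*all* pairs, keeping the trial set pairwise-consistent; a constant baseline
($\sigma_{kl}=0$) sets that pair's zPLV to zero with a warning. The
subject-level global PLV (gPLV) is the mean of the tPLV matrix over all
91 unordered pairs.

**Spanning tree.** The maximum-connectivity tree of the complete weighted
graph is built by Kruskal's algorithm: edges sorted by descending tPLV and
accepted greedily unless a depth-first search finds that the candidate
closes a cycle. Ties — measure-zero with continuous weights — are broken
lexicographically by node-index pair, which makes the output deterministic
and the invariance under monotone weight transforms exact. Because only the
weight order matters, negative zPLV-derived weights need no special
treatment. No pre-thresholding is applied; thresholded graphs are a display
device only.

**Topology metrics.** In a tree every pair of nodes has exactly one shortest
path, so betweenness centrality reduces to counting, for each node, the
pairs separated by its removal; it is normalized over $(N-1)(N-2)$
*ordered* pairs so that a leaf scores 0 and the hub of a star scores 1
(with unordered pairs a star hub would score only 1/2, contradicting the
star convention). Global metrics follow their standard tree forms:
$L_f = L/(N-1)$, $\kappa = \sum k^2 / \sum k$, $D = \text{diam}/(N-1)$,
$T_H = L / (2 (N-1) BC_{max})$. One genuine ambiguity is the global
eccentricity: "difference between the largest and smallest nodal
eccentricity" (a range) and the largest nodal eccentricity (a diameter-style
summary) are both defensible readings, so both are implemented
(`ecc_variant = "range"` is the default, `"max"` the alternative). A caution
for property-minded users: $T_H = 0.5$ does *not* characterize the star —
the 4-node line also attains exactly 0.5, as do many larger non-star trees —
although every star does score 0.5. $D = 1$, by contrast, characterizes the
line exactly.

**Group statistics.** Between-group differences use the two-sided
Mann–Whitney U test, exact when the combined sample is at most 25 and
tie-free, normal approximation with tie/continuity correction otherwise.
Clinical associations use Spearman rank correlation with average ranks for
ties. Per-metric p-values are reported uncorrected by default, with an
optional Benjamini–Hochberg column, and sidedness is two-sided throughout.

## The synthetic cohort generator

Real recordings of this kind are restricted, so the package ships a
first-class generator whose defaults mirror the study geometry: 14 channels
at 7.81 Hz, 28 target trials per subject, 2+4+12+2-s epochs, a 0.05 Hz
carrier inside the analysis band.

**Mechanism.** Each trial/channel is a noisy phase oscillator
$x(t) = \cos(2\pi f_c t + \psi(t)) + \varepsilon(t)$ with white Gaussian
$\varepsilon$. Before onset, $\psi$ performs an independent Wiener diffusion
from a uniform start (`baseline_drift_sd`, default 1.0 rad/√s), so baseline
synchronization is at chance *and its level fluctuates within the window* —
spontaneous low-frequency oscillations are only weakly coherent, and a
phase-frozen baseline would make the z-scoring denominator degenerate. At
onset each channel's phase relaxes exponentially (`locking_rate`, default
1.5 /s) onto a trial-specific coupled target and then fluctuates around it
(`locked_drift_sd`, default 0.3 rad/√s). The targets carry the planted
topology: a root phase drawn uniformly per trial is propagated along the
edges of a spanning-tree template ("star", "line", or explicit edge list)
with independent von Mises increments of concentration `coupling_kappa`.
Channels joined by a template edge therefore share the trial phase up to
jitter, and phase similarity decays with tree distance, which is what makes
the template recoverable by the full pipeline. An optional canonical-shaped
amplitude envelope (`hrf_envelope`) is off by default — phase analysis is
amplitude-invariant, and the envelope only matters when testing
amplitude-related behavior.

**Cohorts and clinical scores.** `generate_cohort()` draws each subject's
realized concentration log-normally around the group value (`kappa_spread`,
default 0.25) and produces clinical scores by a deterministic monotone
`clinical_link` of that realized value (by default a disease duration
increasing, and an ALSFRS-R-like 0–48 score decreasing, in coupling), so
rank-correlation recovery has a known ground truth. Subject streams derive
from `seed + subject_index`, making every array reproducible bit-for-bit.

**The identifiability window.** Template recovery is *not* monotone in
`coupling_kappa` over its whole range: as $\kappa \to \infty$ every channel
converges to the same phase, all 91 pairs synchronize equally, and the tree
is decided by ties and sampling noise; as the noise and jitter vanish the
baseline PLV freezes and the z-scoring denominator degenerates. Recovery
peaks at moderate concentrations ($\kappa \approx 1\text{–}2$), where phase
similarity still decays appreciably per tree hop. The defaults
(`coupling_kappa = 2`, `noise_sd = 0.3`) sit in this window, and the
recovery tests probe it deliberately: exact 13/13 group-level recovery at
$\kappa = 1$ over 12 subjects, and a monotone-recovery grid that stops at
$\kappa = 1$, before the non-monotone region.

**What passing tests do and do not show.** The generator emulates phase
structure only. It contains no hemodynamic amplitude dynamics (unless
enabled), no motion artifacts, no systemic physiology beyond white noise, no
optode geometry, and no trial rejection (all 28 trials are retained).
Pipeline results on synthetic cohorts demonstrate that the implementation
recovers planted phase topology and calibrated statistics — not that the
biological claims of any particular study generalize.

## A caveat: small-sample bias of baseline z-scoring

Baseline z-scoring is designed to cancel stationary synchronization, and its
numerator does: under an uncoupled cohort the raw PLV is stationary across
the epoch at the chance level $\sqrt{\pi/(4N)} \approx 0.167$ for $N = 28$
trials (the suite verifies this). The *ratio*, however, is not exactly
unbiased: over a 24-sample baseline the sample mean and sample SD of PLV are
positively correlated (resultant lengths are right-skewed), so
$E[(X-\hat\mu)/\hat\sigma] = -\mathrm{Cov}(\hat\mu, 1/\hat\sigma) > 0$, and
because consecutive baseline PLV samples are strongly autocorrelated at
7.81 Hz the effect does not average away within the window. The resulting
mean null tPLV is a small positive offset — an order of magnitude below the
across-pair spread (the suite bounds it at |mean| < 0.15 against a spread
above 0.5) — that is shared by both groups and therefore cancels from every
between-group contrast. It is visible only to tests that demand the null
mean be zero to within a standard error of a large cohort; analyses that
interpret the absolute level of tPLV or gPLV should keep it in mind.

## Problem sizes used by the test suite

The suite sizes its simulations to what the statistics require rather than
to the study's full scale: oracle equivalence uses exhaustive enumeration of
all 1296 spanning trees on 6 nodes (100 random matrices) and brute-force
path counting on 8-node trees (200 replicates); group-contrast recovery uses
10 subjects per group over 10 seeds; clinical-link recovery uses 20 patients
over 10 seeds; type-I calibration uses 1000 null cohort pairs on
precomputed metrics; the null-connectivity check uses 100 subjects.

## Known limitations

* Weighted-graph analyses (clustering coefficient, weighted path length)
  are deliberately out of scope; the tree is unweighted by construction.
* The Beer–Lambert constants are literature defaults, not device values.
* The global-eccentricity definition is ambiguous in the field; both
  variants are computed, and cross-study comparisons should state which one
  they use.
* `compare_groups()` reports per-metric p-values without multiplicity
  correction by default, mirroring common practice in small clinical
  cohorts; use `p_adjust = "BH"` when many metrics are screened.
* The null-bias caveat above applies to any baseline-z-scored
  synchronization measure with short baselines, not only to this package.
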