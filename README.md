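# nirsmst

Spanning-tree topology of fNIRS phase-locking networks.

`nirsmst` is an R package for activity-based functional-network analysis of
multi-channel fNIRS hemodynamic recordings, aimed at studies that compare
the *shape* of a small cortical network (typically a 14-channel frontal
montage) between a patient group and controls, and relate it to clinical
scores. Conventional graph analysis of connectivity matrices requires
density or weight thresholds that bias cross-study comparison; collapsing
each subject's connectivity matrix to its maximum-connectivity spanning
tree removes that choice, because the tree depends only on the *order* of
the connection weights.

## Method

For each subject, trial epochs of HbO2 (band-limited to 0.01–0.15 Hz,
segmented to `[-6, 14)` s around stimulus onset at 7.81 Hz) are reduced to a
channel-pair synchronization matrix:

- instantaneous phase φ[n] from the discrete Hilbert transform of each
  epoch (2-s margins absorb edge effects and are discarded);
- phase-locking value per pair and sample, over N trials:
  PLV_kl[n] = |(1/N) Σ_p exp(j(φ_k[p,n] − φ_l[p,n]))| ∈ [0, 1];
- baseline z-scoring against the pair's own `[-4, -1)` s pre-stimulus
  statistics: zPLV = (PLV − μ_kl)/σ_kl, cancelling stationary,
  task-unrelated synchronization;
- post-stimulus average over `[0, 12)` s (M = 94 samples):
  tPLV_kl, a symmetric 14 × 14 matrix; its mean over all 91 pairs is the
  subject's global PLV (gPLV).

Kruskal's algorithm (greedy descending-weight edge selection with
depth-first-search cycle detection) extracts the maximum spanning tree,
which is summarized by nodal metrics — degree k, betweenness centrality
BC(r) = (1/((N−1)(N−2))) Σ n_pq(r)/N_pq (0 for leaves, 1 for a star hub),
eccentricity — and global metrics: leaf fraction L/(N−1), maximum degree,
degree divergence κ = Σk²/Σk, diameter, tree hierarchy
T_H = L/(2(N−1)·BC_max), and edge overlap with a reference tree built from
the control-group average matrix. Groups are compared with two-sided
Mann–Whitney U tests (exact for small tie-free samples) and metrics are
correlated with clinical scores by Spearman rank correlation.

Because recordings of this kind are typically restricted, the package
includes a first-class synthetic cohort generator: noisy phase oscillators
whose post-stimulus phases lock onto a planted spanning-tree coupling
topology (von Mises jitter with concentration κ propagated along template
edges), with clinical scores tied monotonically to each subject's realized
coupling strength. Every downstream stage is testable against this ground
truth. See the methods vignette (`vignettes/mst-network-analysis.Rmd`) for
model details, conventions, and caveats.

## Worked example

Simulate a control group with line-like coupling and a smaller patient
group with star-like (centralized) coupling, run the full pipeline, and
compare topologies:

```r
library(nirsmst)

hc  <- synthetic_config(n_subjects_per_group = 10, coupling_template = "line", seed = 1)
als <- synthetic_config(n_subjects_per_group = 9,  coupling_template = "star", seed = 5001)
cohort <- generate_cohort(hc, als)

res <- run_pipeline(cohort, run_config(seed = 1), out_dir = "out")
subset(res$stats, metric %in% c("gplv", "leaf_fraction", "k_max",
                                "kappa", "diameter", "overlap"))
```

```
        metric mean_control mean_patient  p_value
          gplv        1.620        3.350 0.000260
 leaf_fraction        0.354        0.632 0.000371
         k_max        3.200        5.330 0.000188
         kappa        2.140        2.780 0.000299
      diameter        0.746        0.427 0.000399
       overlap       73.100       12.800 0.000227
```

The star-coupled "patients" show the centralization signature: higher leaf
fraction, maximum degree and degree divergence, smaller diameter, and much
lower edge overlap with the control-derived reference tree. The patient
group tree recovers the planted hub exactly:

```r
global_metrics(res$group_trees$patient)
#> patient group tree: leaf fraction 1   k_max 13   T_H 0.5
```

Clinical-score recovery — scores were generated monotone in each subject's
coupling strength, and the pipeline's gPLV finds them again:

```r
subset(res$correlations, metric == "gplv")
#>  metric         clinical        rho    p_value n
#>    gplv disease_duration  0.7500000 0.02549052 9
#>    gplv         alsfrs_r -0.6937819 0.03817301 9
```

`run_pipeline()` also writes a complete analysis bundle (per-subject tPLV
matrices and tree edge lists, metrics and statistics tables, occurrence
tables, group trees, and a provenance record) to `out_dir`.

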