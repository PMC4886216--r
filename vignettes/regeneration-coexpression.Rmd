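---
title: "Dynamic co-expression network analysis of regeneration time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic co-expression network analysis of regeneration time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenet)
```

# The analysis and its assumptions

`regenet` implements a complete co-expression analysis for an
injury/regeneration time course: a control group and six post-injury time
points (4 hours; 1, 3, 7, 14 and 90 days), three biological replicates
each, measured on a log2 expression scale. The chain is: moderated
differential expression → gene selection → weighted network → module
detection (two algorithms) → permutation hub test → enrichment,
conservation and miR-target interpretation. The stages are exposed as
plain functions; `run_pipeline()` wires them together and records the full
parameter trail.

The statistical assumptions, stage by stage:

* **Moderated t.** Expression is approximately Gaussian within each
  condition group with gene-specific variance; gene-wise variances follow
  a scaled inverse chi-square (equivalently, scaled-F marginal for
  *s²*), which justifies shrinking them towards a common prior. The
  hyperparameters (*d₀*, *s₀²*) come from closed-form moment matching on
  log *s²*: with *e_g = log s_g² − ψ(d/2) + log(d/2)*, *d₀* solves
  *ψ′(d₀/2) = var(e) − ψ′(d/2)* (trigamma inverse by Newton iteration) and
  *s₀² = exp(mean(e) + ψ(d₀/2) − log(d₀/2))*. This estimator is fully
  deterministic; no iterative model fit is involved. When the observed
  log-variance dispersion does not exceed its sampling noise the prior df
  is infinite and every gene receives *s₀²*. Setting `prior_df = 0`
  recovers the ordinary pooled-variance t-test; `prior_df = Inf` with a
  fixed `prior_var` is the full-shrinkage limit. The test suite verifies
  both limits and cross-checks the estimator against `limma::eBayes`.
* **Selection contrast.** The "injured vs healthier" contrast pools
  4 hpi–14 dpi against controls plus the fully regenerated 90 dpi hearts.
  Pooling five time points on one side means a gene's *temporal profile
  within the injured phase counts as residual variance*; genes with a
  sustained injury response are favoured over sharply transient ones.
  This is a property of the design being reproduced, not of the
  implementation, and it shapes several generator choices below.
* **Network.** Unsigned soft thresholding, *a_ij = |r_ij|^β*: positively
  and negatively co-expressed gene pairs are treated alike, because edge
  filtering is defined on the absolute correlation. β = 6 is the fixed
  default; `sweep_soft_threshold()` reports scale-free fit, median
  connectivity and Louvain modularity across β = 1…12 but never chooses
  for you. The default edge filter keeps weights ≥ τ = 0.26, the printed
  two-decimal weight of |r| = 0.8 at β = 6. Note 0.26 < 0.8⁶ = 0.262144,
  so the weight rule is marginally more permissive than |r| ≥ 0.8;
  `filter_on = "correlation"` switches to the exact |r| rule.
* **Hubs.** The null reassigns the multiset of retained edge weights to
  the fixed edge set. This isolates *weight concentration*: a node is a
  hub when its incident edges carry systematically more weight than a
  random draw of the same number of edges from the network's weight pool.
  Degree alone does not make a hub under this null; a degree-preserving
  rewiring null is available via `null = "degree-rewire"` for users who
  want topology randomized instead. The test is one-sided (excess
  connectivity only), the empirical p honours the add-one floor
  1/(B + 1), and hubs are flagged at BH-adjusted p < 0.05.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fdr_select` | 0.005 | BH threshold (strict `<`) of the selection contrast; selected genes form the network |
| `fdr_pertime` | 0.001 | BH threshold of the per-time DEG counts |
| `beta` | 6 | soft-threshold power (unsigned) |
| `tau` | 0.26 | edge weight filter; boundary kept |
| `hier$min_size` | 30 | minimum hierarchical module size |
| `hier$merge_threshold` | 0.85 | eigengene correlation above which modules merge |
| `hier$kme_prune` | 0.7 | minimum gene–eigengene correlation to stay in a module |
| `cohesive$penalty` | 2 | size penalty *p* of the cohesiveness score |
| `cohesive$min_size`, `min_density` | 5, 0.3 | cluster filters |
| `cohesive$overlap_merge` | 0.8 | overlap score (squared intersection over size product) for merging |
| `cohesive$alpha` | 0.05 | BH-adjusted Mann–Whitney cluster significance |
| `hub_B` | 1000 | hub-test permutations |
| `alpha_enrich` | 0.05 | enrichment / conservation significance |

All thresholds that the analysis reports ("FDR < x", "adjusted-P < x")
use strict inequalities.

# Design choices where the design was genuinely open

* **Static cut with adaptive height.** Hierarchical modules come from an
  average-linkage tree of 1 − TOM cut at a single height. A fixed height
  or height quantile is fragile: when the network is dominated by a few
  clean modules, any quantile-based cut lands among the inter-module join
  heights and fuses modules. The default therefore scans the midpoints
  between consecutive merge heights and keeps the *largest* height at
  which the number of clusters of size ≥ `min_size` is maximal — a
  deterministic, dendrogram-intrinsic rule. A numeric `cut_height`
  overrides it.
* **Membership pruning (kME).** Under average linkage, genes that
  correlate moderately with a module (for example, injury-responsive
  background genes whose realized profiles happen to align with a module
  trajectory) chain onto it near the cut height. After cutting, genes
  whose correlation with their module's eigengene falls below
  `kme_prune = 0.7` are returned to the unassigned pool — the standard
  module-membership filter of the weighted co-expression tradition.
* **Merge threshold 0.85.** In an unsigned network built from an injury
  time course, all injury-responsive modules share the injured-vs-healthy
  axis, so distinct modules' eigengenes routinely correlate 0.6–0.75.
  Merging at 0.75 therefore fuses biologically distinct response
  programs; 0.85 only merges near-duplicates. The merge uses *signed*
  correlation, so up- and down-regulated programs never merge.
* **Cohesiveness defaults.** Seeds grow in decreasing weighted-connectivity
  order (ties broken lexicographically by gene id) with single add/remove
  steps; accepted steps strictly increase the cohesiveness, which the step
  log kept in the result makes assertable. `min_density = 0.3` follows the
  convention of the cohesiveness algorithm family; at β = 6 a genuine
  module of |r| ≈ 0.9 genes has mean internal weight near 0.53, which a
  0.5 density floor would discard on unlucky draws.
* **Cluster significance.** One-sided Mann–Whitney comparing members'
  in-cluster versus out-of-cluster weight sums, normal approximation
  (weight sums are continuous, ties are not an issue), BH across clusters.
* **Probe collapsing.** The max-variance rule is the default (keeps the
  most informative probe); `mean` and `max-mean` are selectable. Ties
  break deterministically by probe id.
* **Conservation.** A gene with at least one ortholog record counts as
  conserved regardless of how many sources agree; the provenance column is
  carried but not tested. Pearson chi-square without continuity correction
  (a `correct` flag restores Yates).

# The synthetic generator

`simulate_timecourse()` generates the study conditions the analysis
assumes, with planted ground truth:

* **Design.** 2,000 genes, 7 groups × 3 replicates, five planted modules
  of 60 genes, 20 planted hubs, 20 % of genes injury-responsive —
  large enough for a meaningful network, small enough for seconds-scale
  runs.
* **Modules as latent factors.** Each module has one latent trajectory;
  member expression is `baseline + loading × latent + noise` with the
  loading set so the expected pairwise member correlation equals
  `within_module_correlation` (default 0.9, comfortably above the |r| = 0.8
  edge filter). This matches the eigengene concept: the first principal
  component of a noise-free module recovers its latent exactly, which the
  test suite asserts.
* **Latent trajectories.** A latent mixes a group-level injury response
  (share 0.95 of its variance) with per-sample variation. The group-level
  part is a shared injured-mean profile — mildly tilted towards the early
  time points (tilt 0.3 of the decay profile) — plus a module-specific
  peak-time contrast (centered peak-group indicator, weight 0.42).
  The contrast structure is the resolution of a real tension: the pooled
  selection contrast punishes within-injured-phase variation, while module
  separability requires it. Centered indicator contrasts have pairwise
  correlation −1/(R−1) over R responding groups, the most mutually
  distinct choice available, and the weight 0.42 leaves members selectable
  (moderated |t| ≈ 5 at the default scale) while keeping between-module
  latent correlations near 0.6 — separable by topological overlap and
  below the 0.85 merge threshold. Signs alternate across modules
  (up- and down-regulated programs).
* **Injury-responsive background.** Background responders shift by
  `effect_size × effect_decay[group]` with random sign — the decaying
  response profile (multipliers 1, 0.9, 0.7, 0.5, 0.25, 0 from 4 hpi to
  90 dpi) that makes per-time DEG counts fall monotonically and vanish at
  90 dpi. Their default effect (1.2 log2 units) makes them prominent in
  the per-time contrasts at FDR < 0.05 but rarely significant at the much
  stricter FDR < 0.005 selection — deliberately so: genes selected purely
  for alignment with the injury axis genuinely co-express with the
  early-response module, and no detector can separate them from it. The
  generator keeps that contamination small instead of pretending a
  detector could remove it.
* **Hubs.** A planted hub is a module gene with almost no idiosyncratic
  noise: variance shares 0.99 on its own module's latent and 0.01 on a
  second module's. Its edges therefore carry systematically larger weights
  (hub–member |r| ≈ 0.94 versus 0.9), which is exactly the signal the
  weight-shuffle null detects; hubness here is shared signal, not
  amplitude. The hub test typically also flags the most strongly
  module-aligned ordinary members — as any connectivity-based definition
  must — so the planted 20 are a subset of the flagged set, and recovery
  is measured as planted-hub recall.
* **Companion tables.** `simulate_annotations()` draws GMT terms with
  configurable odds of coming from a designated module;
  `simulate_crossspecies()` assigns per-species orthologs by Bernoulli
  draws with separate hub/non-hub rates (defaults 0.78–0.79 versus 0.50)
  and builds a miR-target table linking named miRs to hub orthologs with
  validated/predicted evidence flags.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe-level microarray structure (RMA, spatial
artifacts), batch effects, heavy-tailed or count-distributed noise,
correlated background genes outside modules, modules of heterogeneous
internal correlation, and scale-free global topology (a planted-block
network is modular, not scale-free; the scale-free diagnostics are instead
validated on constructed power-law degree sequences). Recovery rates on
this generator are upper bounds for messier real data.

# Numerical choices

* Determinism: every simulation and the hub test run under a locally
  seeded RNG (the caller's RNG state is saved and restored), so identical
  (config, seed) pairs give bitwise-identical outputs and repeated
  pipeline runs serialize byte-identically (`write_bundle()` writes no
  timestamps).
* Permutation connectivities are compared with a 1e-8 tolerance so that
  exact ties (for example, all edge weights equal) are counted as ties
  rather than resolved by floating-point noise.
* Zero-variance genes are dropped with a warning before correlation;
  constant module submatrices make the eigengene error out rather than
  return NaN.
* The scale-free fit bins connectivities into 10 equal-width bins,
  skipping empty bins; all-equal connectivities report R² = 0 with a
  warning, and fewer than 3 non-empty bins is an error.
* Ties in probe collapsing and in the cohesiveness seed order break by
  identifier, never by hash order.

# Problem sizes used by the tests

The suite runs the full pipeline on the default 2,000-gene fixture once
(module recovery and hub recall), uses 300–600-gene fixtures for
stage-level recovery checks, 2,000-gene global-null fixtures for type-I
calibration, 10 × 150-node exchangeable networks for hub-null calibration,
and instances of ≤ 25 nodes for all brute-force oracle comparisons
(topological overlap, BH, hypergeometric, chi-square, network statistics).
These sizes were chosen so the entire suite completes in well under a
minute while keeping every binomial calibration band at three standard
errors or tighter.

# Known limitations

* The moderated t assumes a common design across genes; there is no
  support for covariates or batch terms (use a dedicated linear-model
  framework if you need them).
* Dense matrices throughout: networks beyond ~10,000 selected genes will
  be memory-hungry; the intended scale is the few thousand genes that
  survive a stringent selection contrast.
* The cohesiveness growth is greedy from each uncovered seed; it inherits
  the usual sensitivity of greedy cluster growth to near-tied scores,
  mitigated but not removed by the deterministic seed order.
* The conservation test treats every flagged hub equally; with many
  flagged member genes, planted-hub ortholog enrichment is diluted — an
  honest property of connectivity-defined hub sets, visible in the
  pipeline's own outputs.
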