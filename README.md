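# regenet

Dynamic gene co-expression network analysis of injury/regeneration
expression time courses, modelled on the zebrafish cardiac cryoinjury
design: uninjured controls plus samples at 4 hours and 1, 3, 7, 14 and 90
days post-injury, measured in triplicate. The package takes a normalized
genes × samples log2 expression matrix through the full analysis chain —
differential expression, gene selection, weighted network construction,
module detection by two complementary algorithms, permutation-based hub
identification, and functional / cross-species interpretation — and ships a
synthetic time-course generator with planted ground truth so that every
stage is verifiable without any external data.

## Who it is for

Systems biologists analysing multi-condition expression time courses who
want a reproducible, fully scriptable alternative to stitching together
web tools: every stage is a plain R function with an explicit parameter
record, every run is deterministic given its seed, and the statistical
machinery is validated against brute-force oracles in the test suite.

## The method

1. **Moderated differential expression.** Per-gene two-group comparisons
   use an empirical-Bayes moderated t-statistic: gene-wise residual
   variances *s²* (d residual df) are shrunk towards a prior
   *s₀²* (d₀ prior df) estimated by closed-form moment matching on
   log *s²*, giving the posterior variance
   *s̃² = (d₀ s₀² + d s²)/(d₀ + d)* and a t-statistic on *d + d₀* df.
   Two contrast schemes are first-class: each post-injury time vs control
   (FDR < 0.001), and the "injured group" (4 hpi – 14 dpi) vs the
   "healthier group" (controls + fully regenerated 90 dpi hearts); genes at
   FDR < 0.005 in the latter form the network's gene set. All
   multiple-testing control is Benjamini–Hochberg.
2. **Weighted co-expression network.** Pearson correlations *r_ij* over all
   samples are soft-thresholded into an unsigned weighted adjacency
   *a_ij = |r_ij|^β* with β = 6, so |r| = 0.8 maps to a weight of
   0.262144; edges with weights below τ = 0.26 are then filtered out
   (equivalently, |r| ≥ 0.8 filtering is available). Scale-free fit R²,
   density, heterogeneity and median connectivity diagnostics are reported,
   plus a β sweep that never auto-selects.
3. **Modules, two ways.** (a) Average-linkage hierarchical clustering of
   1 − TOM (topological overlap) with a deterministic static cut, module
   eigengene merging and membership pruning — modules 1A, 2A, … by
   decreasing size; (b) cohesiveness-based overlapping clustering — greedy
   growth of seeds maximizing *f(V) = w_in/(w_in + w_out + p·|V|)*, overlap
   merging, density filtering and a one-sided Mann–Whitney significance
   test — modules 1B, 2B, … The two catalogs are compared by Jaccard
   coefficients.
4. **Hubs.** Per-gene weighted connectivity *k_i = Σ_j a_ij* is tested
   against a permutation null that shuffles the multiset of retained edge
   weights over the fixed topology; empirical p-values
   *(1 + #{k_perm ≥ k_obs})/(B + 1)* are BH-adjusted and genes with
   adjusted p < 0.05 are hubs.
5. **Interpretation against local tables.** Hypergeometric module
   enrichment against GMT annotations, hub-conservation 2×2 chi-square
   tests against an orthology table, and miR–target intersection of hub
   orthologs — no web services, all inputs are plain TSV/GMT files.

## Worked example

```r
library(regenet)

cf  <- sim_config(seed = 1)              # 2000 genes, 7 groups x 3 replicates
sim <- simulate_timecourse(cf)           # expression + ground truth
ann <- simulate_annotations(sim$truth, n_terms = 30, enrichment_odds = 20, seed = 2)
xs  <- simulate_crossspecies(sim$truth, seed = 3)

cfg <- pipeline_config(expr = sim$expr, annotations = ann,
                       orthology = xs$orthology, mir_targets = xs$mir_targets,
                       seed = 1)
bundle <- run_pipeline(cfg)
print(bundle)
```

```
regen_bundle (regenet 0.1.0 )
  input: 2000 genes x 21 samples
  selected genes (injured_vs_healthier, FDR < 0.005): 317
  per-time DEG counts (FDR < 0.001): 4hpi=301, 1dpi=294, 3dpi=263, 7dpi=207, 14dpi=154, 90dpi=0
  network: 317 nodes, 8844 edges at tau = 0.26
  modules: 5 hierarchical, 5 cohesive; best overlap 4A/4B J = 1.000
  hubs: 79 of 317 network genes
  conservation human: chi2 = 2.137 (p = 0.144), hub fraction 0.58
  conservation mouse: chi2 = 2.754 (p = 0.097), hub fraction 0.61
  conservation rat: chi2 = 2.39 (p = 0.122), hub fraction 0.65
  miR interactions: 2 validated, 18 predicted
```

Reading the output: 317 of 2000 genes separate injured from healthier
hearts at FDR < 0.005 and form the network; per-time DEG counts fall
monotonically from 4 hpi and vanish by 90 dpi, the signature of a completed
regeneration time course. Both detectors recover five modules (the
generator planted five, of 60 genes each) and agree perfectly on their
best-matching pair. 79 genes carry significantly concentrated edge weight;
they include all 20 planted hubs plus the most strongly module-aligned
members, and the cross-species stages report their ortholog fractions and
miR interactions from the supplied tables. `write_bundle(bundle, "out/")`
serializes every stage (TSV edge lists, module catalogs, hub table,
`results.json`) byte-identically across repeated seeded runs, and
`write_network(..., format = "graphml")` exports an annotated graph for
Cytoscape-style viewers.

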