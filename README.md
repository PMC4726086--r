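# bacppi

Genome-scale prediction and characterization of bacterial protein–protein
interaction (PPI) networks in R.

Most bacteria — including industrially important strains such as
*Bacillus licheniformis* — have no experimentally mapped interactome.
`bacppi` builds one computationally from two independent evidence channels
and then puts the resulting network through the full battery of analyses a
systems-biology study needs:

* **Interolog transfer.** Orthologs between the target proteome and
  reference organisms with curated interactomes are called from homology
  search hits filtered at E-value ≤ 10⁻⁵, sequence identity ≥ 30% and
  alignment coverage ≥ 60%, keeping only the best-scoring hit per (query,
  organism). Two target proteins are predicted to interact when their
  orthologs in the *same* reference organism have an experimentally
  determined interaction.
* **Domain–domain interaction (DDI) inference.** Pfam-style domains are
  assigned from domain search hits (E-value ≤ 10⁻⁵, bias ≤ 1); proteins X
  and Y are predicted to interact when some domain *m* of X and *n* of Y
  form an experimentally supported interacting domain pair.

The merged non-redundant network is then characterized and validated:

* topology (degree, clustering, path lengths, betweenness, closeness,
  components) with the conventions of the NetworkAnalyzer tool;
* the scale-free degree exponent γ by maximum likelihood
  (γ = 1 + n·[Σ ln(kᵢ/k_min)]⁻¹, with a discrete zeta-likelihood MLE
  reported alongside);
* an **exact minimum dominating set** (MDS) — the smallest node set such
  that every protein is in it or adjacent to it, a standard proxy for
  network controllability — solved as the integer program
  min Σ xᵥ s.t. xᵥ + Σ_{u∈N(v)} xᵤ ≥ 1 by a provably optimal
  branch-and-bound with dual (Lagrangian) bounds;
* a **COG-pair heat map**: with n annotated proteins, fᵢ of them in
  functional class i and N observed interactions, the class-pair count
  A_ij is binomial under the randomized-network null with
  P_ij = fᵢf_j / C(n,2) (i≠j), giving
  Z_ij = (A_ij − N·P_ij)/√(N·P_ij(1−P_ij));
* Fisher's exact COG enrichment (one-sided, BH-adjusted P reported);
* **network validation** against degree-preserving random networks: Wang
  graph-based GO semantic similarity with best-match averaging, and
  Pearson correlation of RPKM transcription profiles, each compared with
  the pooled null by Wilcoxon rank-sum;
* **condition-specific dynamics**: active subnetworks at each time point
  (genes with RPKM < 1 removed), the normalized transcription difference
  D_ij = |RPKM_i − RPKM_j|/(RPKM_i + RPKM_j) per pair group, and
  node-level topology comparisons across conditions;
* **protein complexes** from time-series subnetworks by a fully specified
  greedy density clustering (RPKM threshold 1, λ = 1, minimum size 3),
  scored by functional-category entropy
  H = −Σ_j (F_ij/nᵢ)·log₂(F_ij/nᵢ) and used to annotate uncharacterized
  proteins from complex-level enrichment.

A seeded synthetic-world generator (`generate_world()`) plants a ground
truth — ortholog map, reference interactomes, domain assignments, DDIs,
COG/GO annotations on a generated DAG, correlated expression — so that
every stage is testable end to end without any database download.

## Worked example

```r
library(bacppi)

world <- generate_world(1)            # seeded synthetic study system
dir <- tempfile(); write_fixtures(world, dir)

res <- run_pipeline(pipeline_config(input_dir = dir, n_random = 10,
                                    mds_time_limit = 120, seed = 7))
res
#> <pipeline_result>
#>   channels: interolog 226, ddi 1274, shared 9 -> merged 1491 edges / 270 nodes
#>   topology: <k> = 11.03, L = 2.91, C = 0.10, 1 components
#>   gamma = 1.48; MDS size 42; complexes 107; annotated 22
```

Reading the output: the interolog channel contributed 226 interactions and
the DDI channel 1,274, sharing 9 — the merged non-redundant network has
1,491 edges over 270 proteins (the DDI channel dominating the interolog
channel is typical of this class of pipeline). After removing homomeric
interactions, the network has mean degree 11.0, average shortest-path
length 2.9 over connected pairs, and mean clustering 0.10; its degree
distribution fits a power law with γ ≈ 1.5, and 42 proteins (≈16% of the
network) suffice to dominate it — the provably minimum dominating set. The
greedy clustering finds 107 complexes in the three time-series
subnetworks, and complex-level COG enrichment assigns functions to 22
proteins that had none.

Every intermediate is a tibble or a tidy-friendly object:

```r
glance(res$topology)              # one-row network summary
tidy(res$topology)                # per-node degree/clustering/centralities
glance(res$powerlaw)              # continuous + discrete gamma
autoplot(res$heatmap)             # COG-pair Z-score heat map (ggplot)
autoplot(res$validation$go)       # similarity densities, PPI vs null
res$report                        # the full machine-readable run report
```

Individual stages compose with the pipe, data frame first:

```r
world$homology_hits |>
  filter_homology_hits(min_identity = 30, min_coverage = 60) |>
  best_hit_per_organism() |>
  transfer_interactions(world$reference_edges)
```

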