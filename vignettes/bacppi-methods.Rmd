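---
title: "Models and methods behind bacppi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bacppi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bacppi` predicts a bacterial protein–protein interaction (PPI) network
from homology and domain evidence and characterizes it: topology,
controllability, functional enrichment, validation against randomized
networks, condition-specific dynamics and complex detection. This
vignette explains each model, the parameters that matter, the numerical
conventions, and the design decisions taken where the methods literature
leaves room — in enough detail that every number the package produces can
be re-derived by hand.

## Interaction prediction

### Interolog transfer

Two target proteins are predicted to interact when their orthologs in the
same reference organism interact experimentally. Ortholog calls come from
homology search hits filtered on three thresholds (defaults: E-value
≤ 1e-5, percent identity ≥ 30, alignment coverage ≥ 60%), then reduced to
the single best hit per (query, organism) by bit score — the conservative
rule that trades recall for a lower false-positive rate. Ties are broken
by smaller E-value, then lexicographically smaller subject id, so the map
is deterministic.

Two choices deserve comment:

* **Coverage** is not a single number in a tabular homology hit: we
  require `min(alignment/query_length, alignment/subject_length) ≥ 60%` —
  the stricter symmetric reading, which suppresses transfers through
  partial-domain matches. `coverage_mode = "query"` switches to the
  query-side-only reading. The homology table dialect therefore needs the
  two appended length columns (`qlen`, `slen`); the 12-column core alone
  cannot express a coverage filter.
* **"Highest alignment score"** is read as the bit score (the
  length-normalized, comparable quantity), not the raw score.

Transfer requires both orthologs in the *same* reference organism as the
supporting edge. Homomeric transfers (A = A) are emitted but flagged as
self-loops, because downstream network analysis removes homomeric
interactions.

### Domain–domain interaction (DDI) inference

Domains are assigned from per-domain search hits kept at full-sequence
E-value ≤ 1e-5 and bias ≤ 1 (the bias filter guards against
composition-driven hits). A single experimentally supported interacting
domain pair (m, n) with m on X and n on Y suffices to predict the edge
(X, Y); all supporting domain pairs are recorded in the edge's `sources`
field as an evidence weight, but the count is never used as a filter.
When both interacting domain instances sit on one protein — including
self-pairs (d, d) — the homomeric edge is emitted and flagged.

### Merging

The two channels are unioned into one simple graph with per-edge evidence
provenance; the merge records |A|, |B|, |A∩B| and checks
|A∪B| = |A| + |B| − |A∩B|. Edges are stored canonically (endpoints
sorted), so (A, B) and (B, A) are one interaction everywhere.

## Network characterization

### Topology conventions

`topology_summary()` follows the conventions of the NetworkAnalyzer-style
tools used for this kind of network, which matter on highly fragmented
graphs:

* the **average path length** averages over connected ordered pairs only
  (a disconnected pair contributes nothing, not infinity);
* the **network clustering coefficient** is the mean local clustering of
  nodes with degree ≥ 2; degree-one nodes are excluded by default
  (`include_degree_one = TRUE` counts them as 0);
* **betweenness** is normalized by (n−1)(n−2)/2, **closeness** is
  `reachable / Σ distance` within a node's component.

These choices are oracle-tested against Floyd–Warshall distances and
explicit triangle counting. Self-loops are an error here: the published
workflow computes topology on the homomer-free network, and
`remove_self_loops()` (which also drops nodes stranded without any edge)
is the documented preceding step.

### Degree exponent

The default γ is the continuous-approximation MLE
γ = 1 + n·[Σ ln(kᵢ/k_min)]⁻¹ with k_min = 1 — the closed form whose
parameter-recovery behaviour is easy to verify (the suite recovers
γ = 2.5 within ±0.1 from 10,000 seeded draws). Because degrees are
integers, the discrete MLE — numeric maximization of the zeta likelihood,
with the Hurwitz zeta evaluated by Euler–Maclaurin summation — is
reported alongside; on heavy-tailed degree data the two differ, and
reporting both makes the estimator choice transparent. Degenerate input
(all degrees equal to k_min) is an error, not a number.

### Minimum dominating set

Controllability is proxied by the minimum dominating set: domination is
closed-neighborhood (a node dominates itself), which makes the defining
integer program `x_v + Σ_{u∈N(v)} x_u ≥ 1` satisfiable on isolated nodes
and matches the controllability literature. `solve_mds_ilp()` solves that
program exactly by branch-and-bound: it branches on the closed
neighborhood of the currently hardest-to-dominate vertex, uses a greedy
incumbent improved by local search (redundant-member removal and
two-for-one exchanges), prunes with a covering bound and a dual-ascent /
Lagrangian-subgradient lower bound on the covering LP, and applies the
classic root reductions (a vertex whose closed neighborhood is contained
in another's is never needed as a dominator; a vertex whose neighborhood
contains another's is automatically dominated). The result is provably
optimal unless the time limit is reached, in which case the best incumbent
is returned with `optimal = FALSE`. `solve_mds_exhaustive()` (subset
enumeration, ≤ 20 nodes) is the independent oracle; `greedy_mds()` is the
scalable ln-n-approximation baseline.

An MDS is generally not unique: only the *size* is a well-defined network
property, and downstream enrichment of MDS members is documented as
solution-dependent.

### COG-pair heat map

With n COG-annotated proteins in the network, fᵢ of them in class i, and
N interactions among annotated proteins, a random interaction joins
classes i and j with probability `P_ij = fᵢf_j / T` (i ≠ j) or
`fᵢ(fᵢ−1)/2 / T` (i = j), where `T = n(n−1)/2`. The observed class-pair
count A_ij is then binomial(N, P_ij), giving
`Z_ij = (A_ij − N·P_ij) / sqrt(N·P_ij(1−P_ij))`. This pair-counting
reconstruction is the unique reading consistent with a binomial
interaction count whose variance is N·P_ij(1−P_ij), and it reproduces the
hand-computable toy value Z = 0.9129 asserted in the tests.

Multi-label proteins contribute to every category combination of an edge
(each unordered combination once per edge) and to every fᵢ they carry;
with single-label annotations the upper-triangle counts exactly partition
N, a conservation law the suite checks. Cells with P_ij ∈ {0, 1} have no
defined Z and are reported as missing, never infinite. N counts only
edges between annotated proteins — the assumption is documented here
because the alternative (all edges) changes Z systematically.

### Enrichment, entropy and annotation

Fisher's exact test is one-sided in the enrichment direction; the
`enriched` flag uses the raw P at α (default 0.05) because that is how
such workflows report category enrichment, while Benjamini–Hochberg
adjusted values are always reported alongside for the reader. The
functional-category entropy of a complex uses each member's *primary*
(first-listed) COG category — this keeps Σ F_ij equal to the member count,
without which the entropy is not a distribution — and unannotated members
enter as an explicit `"unknown"` category (a complex of only unannotated
members scores 0 and is flagged rather than silently looking
homogeneous). Uncharacterized proteins (no COG, or only S/R) inherit the
most-enriched category of an enriched complex they belong to; across
complexes the smallest P wins.

## Network validation

GO semantic similarity uses the Wang graph-based measure: each term is
represented by S-values over its ancestors (S = 1 at the term, multiplied
by 0.8 per is_a edge and 0.6 per part_of edge along the best path), and
`sim(A, B) = Σ_{t∈anc(A)∩anc(B)} (S_A(t)+S_B(t)) / (SV(A)+SV(B))`.
Protein-level similarity is the best-match average of the term matrix,
averaged over namespaces where both proteins are annotated; pairs with no
shared annotated namespace are skipped and counted. The cited similarity
pipeline is not fully specified in the source literature; Wang + BMA is
the standard realization and the module keeps the term measure behind one
internal function so a Resnik/Lin variant can be substituted.

The null model is degree-preserving rewiring (repeated double-edge swaps
rejecting self-loops and duplicates, 10·|E| attempts by default) — the
stronger, standard reading of "random networks with the same topology".
The comparison pools all edge values of all rewired networks into one
null sample by default (`mode = "per_network"` reduces each rewiring to
its median first); pooling is the default because per-network medians
discard the within-network spread that the rank-sum test uses. Both GO
similarity and transcription-profile Pearson correlation (PCC) use the
same machinery with alternative "greater".

The Wilcoxon rank-sum implementation is exact (no ties, both samples
together ≤ 12 observations — matching the enumeration oracle in the
tests) and otherwise uses the normal approximation with tie and
continuity correction; the degenerate all-tied case returns P = 1.

PCC over three time points is statistically weak for any single pair —
the validation draws its power from comparing whole edge populations, and
this caveat is stated here because the data shape (three RPKM snapshots)
imposes it.

## Condition-specific dynamics

A gene with RPKM < 1 at a time point is treated as absent and removed
with its edges; genes missing from the expression matrix are treated the
same way (the threshold rule is the only stated mechanism, and silently
keeping unmeasured genes would make the condition networks
incomparable). The normalized transcription difference
`D = |RPKM_i − RPKM_j| / (RPKM_i + RPKM_j)` is symmetric, scale-free
(invariant under joint rescaling — the property that makes it comparable
across libraries) and lives in [0, 1]; both-zero pairs are an error.

Distribution groups: `control` is all unordered pairs of *active* nodes
(subsampled with a fixed seed above 10⁶ pairs — the quadratic set is
otherwise intractable and the source workflows do not state how it was
handled); `all_ppi` is the condition network's edges; `category:X`
requires *both* endpoints to carry COG category X, the reading of
"interacting protein pairs belonging to" a category. Local-topology
comparison runs a two-sided rank-sum test per metric over node-level
values; conditions with fewer than three nodes are excluded with a
warning.

## Complex detection

The time-series complex-detection algorithm this module stands in for is
published only by reference, so `detect_complexes()` specifies its own
greedy density clustering completely — the goal is a reproducible,
testable procedure with the same interface (PPIs + expression in;
parameters RPKM threshold 1, λ = 1, minimum size 3): seed at the
highest-degree unassigned node, repeatedly add the neighbor with the most
links into the cluster, accepting while `links(u, C) ≥ λ·|C|/2` (λ enters
only through this acceptance ratio), close when no candidate qualifies,
keep clusters of at least `min_size`. All ties break lexicographically,
so the output is deterministic and permutation-stable. Across time
points, clusters with overlap score `|A∩B|²/(|A||B|) ≥ 0.8` (the standard
overlap-score convention; a documented free parameter) are merged by
union — but only when the union still induces a connected subgraph in at
least one time-series subnetwork, preserving the invariant that every
reported complex is connected somewhere. Planted-module recovery (dense
modules at intra-density 0.9 over inter-density 0.05, sizes 5–10) is ≥
80% at overlap ≥ 0.5 across 20 seeds in the acceptance suite.

## The synthetic world

`generate_world()` produces a complete, seeded study system: a target
proteome (default 300 proteins), two reference organisms with a planted
one-to-one ortholog map (rates 0.7 / 0.5), curated-style reference
interactomes (~800 interactions: planted transferable pairs, dense
function-coherent complexes forced through the first organism, and noise
edges among unmapped reference proteins), homology hit tables in which
every decoy fails *exactly one* of the three filters (so the filter logic
is exercised edge by edge) and secondary passing hits always score below
the planted ortholog (exercising the best-hit rule), ~150 domains with
200 DDIs, multi-label COG annotations with a transcription-heavy
frequency skew, a generated two-namespace GO DAG (depth 4, random rooted
DAG — real GO is deliberately not sampled, keeping the package
download-free), and three-time-point RPKM profiles in which interacting
modules share a latent log-normal profile with pair noise σ = 0.2 and
~10% of background gene-time points fall below the activity threshold.

The planted truth network is re-derived inside the generator by brute
force (loops over reference edges and over DDIs, independent of the
prediction code paths) and asserted at generation time to equal the
pipeline's output on the world's own tables — the self-consistency
contract the acceptance suite re-checks across 20 seeds through the
on-disk fixture files.

What the generator does *not* emulate: real sequence content (identities
and E-values are drawn, not aligned), realistic Pfam domain
architectures, the true size and redundancy of curated interactome
databases, GO term depth heterogeneity, or biological expression
dynamics beyond module-correlated log-normal noise. Passing tests
therefore demonstrate the correctness and statistical behaviour of the
*methods*, not the biological accuracy of any particular predicted
network.

Scale defaults were chosen so the full pipeline — including the exact
MDS proof — completes in about a minute on a single CPU; the test suite
uses a smaller 80-protein variant of the same world where many replicates
are needed (100-seed type-I-error control, 20-seed self-consistency), and
states those sizes in the test code.

## Determinism and degenerate inputs

Every stochastic step (rewiring, control-pair subsampling, world
generation) runs under an explicit seed and restores the caller's RNG
state. Readers reject malformed rows with the offending line number
rather than coercing. Degenerate cases are contracts, not accidents: an
empty network errors in `topology_summary()`, an all-k_min degree vector
errors in `fit_powerlaw()`, a both-zero RPKM pair errors in
`normalized_difference()`, undefined Z cells and undefined protein
similarities are reported missing and skipped-with-count respectively.

## Known limitations

* The interolog and DDI channels inherit the biases of their reference
  data; the validation machinery quantifies enrichment against a
  topology-preserving null but cannot certify individual edges.
* The exact MDS solver's proof of optimality is instance-dependent; on
  hard instances it returns the best incumbent with `optimal = FALSE`
  within the time limit (the size reported is still a valid upper bound,
  and in practice the incumbent equals the optimum long before the proof
  closes).
* The complex detector is a specified stand-in, not a reimplementation of
  the referenced time-series algorithm; its outputs are comparable in
  kind (dense, condition-supported modules) but not bit-compatible with
  that method.
* GO similarity depends on annotation completeness; proteins without GO
  terms simply drop out of the validation sample, which the reports
  count.
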