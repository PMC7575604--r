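---
title: "Methods: topology and motif analysis of transcriptional regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology and motif analysis of transcriptional regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trntopo)
```

## The data model

A transcriptional regulatory network here is a set of directed TF → target
gene associations curated from the literature. Each association carries:

* **evidence flags** — `has_binding` (at least one publication with a
  TF–DNA binding assay: ChIP-on-chip, ChIP-seq, EMSA, footprinting) and
  `has_expression` (at least one publication showing that perturbing the TF
  changes the target's expression). The two flags are stored orthogonally;
  the familiar evidence sets are derived from them: *B* (any binding
  evidence), *E* (any expression evidence), *B&E* (both), *B|E* (either,
  i.e. the whole network). Stored this way, the set sizes satisfy
  inclusion–exclusion exactly, |B| + |E| − |B&E| = |B|E|, which is how the
  printed size tables of curated yeast collections behave. Associations
  with no evidence annotation at all are dropped at load time with a
  warning (curated databases contain a handful of these).
* **a regulation sign**, derived from expression evidence only (binding
  alone says nothing about direction): `positive` when every publication
  saw activation, `negative` when every publication saw repression, `dual`
  otherwise, and `unknown` when the observed effect had no directionality.
  When publications mix `unknown` with one consistent direction, the
  direction wins — an undirected observation carries no evidence *against*
  a direction. Only conflicting directions (or an explicit dual report)
  produce `dual`. Binding-only associations carry `not_applicable`.
* **condition tags** (free-form, e.g. `"Stress"`, `"Unstressed log-phase
  growth (control)"`) and **reference identifiers**, both sets.

The `(tf, target)` pair is the identity of an association: duplicate rows
(one per publication, as databases export them) are merged on load —
evidence flags OR-ed, reference and condition sets unioned, signs
aggregated by the rule above. Gene identifiers are uppercased and
cross-network comparison is exact string matching; no alias resolution
against genome databases is attempted.

Node, TF and TG sets are always derived from the surviving interactions,
so no operation can produce an isolated node.

## Density

The summary density is the fraction of realized interactions among the
possible ones, with denominator `n_tfs × n_nodes`: each identified TF could
in principle regulate every node, including other TFs and itself (a network
with 152 TFs over 3937 nodes has 152 × 3937 = 598,424 possible
interactions). The alternative `n_tfs × n_tgs` denominator would exclude
TF→TF regulation, which is both real and central to triad structure.
Percentages throughout the package are reported half-even rounded to two
decimals, the convention of the published tables; raw values are kept
internally.

## Degree analysis

In-degree counts the distinct TFs regulating a gene; out-degree counts the
distinct genes a TF regulates (distinct partners, not publications or
conditions, since networks are deduplicated at the pair level).
Auto-regulation contributes one unit to both degrees of its node.

In-degree distributions, following the convention of the yeast-network
literature, by default exclude the unregulated nodes (in-degree 0 — pure
regulators); the number excluded is recorded in the result. Out-degree
distributions are reported for TFs only, in half-open bins `[k·w, (k+1)·w)`
with default width 200, matching the usual TF out-degree histograms; an
optional truncation point drops the extreme tail and reports how many TFs
it held.

TF ranking (`rank_tfs`) selects the k highest or lowest out-degree TFs and
reports the k-th value as the threshold, *including ties*: all TFs whose
out-degree equals the cut value are returned, so the set may exceed k. This
makes the selection a pure function of the degree table, independent of any
internal ordering.

## Chi-squared in-degree binning

To relate regulation intensity to biological function, regulated genes are
grouped into in-degree bins that are as coarse as the data allow. The
merging rule is greedy, left to right over the observed in-degrees: the
accumulated bin's functional-category counts are compared with the next
degree's counts by a chi-squared homogeneity test on the 2 × C contingency
table; the degree joins the bin while the test cannot distinguish them
(p > α) and opens a new bin otherwise. Defaults: α = 0.05, and categories
whose expected count falls below 5 are pooled into an "other" column before
testing (the standard validity guard for the chi-squared approximation). A
degree slice with no genes, or one where no informative 2-column table
survives pooling, merges unconditionally. All three choices (α, the pooling
threshold, the greedy scan) are exposed as configuration; a different
agglomeration policy would yield different — equally defensible — bins, so
the package treats the published three-bin layout (1–4, 5–9, 10–25) as an
input when reproducing published per-bin percentages, not as an output it
promises to rediscover.

Within each bin, `category_distribution` cross-tabulates annotated
regulated genes and reports within-category percentages; genes missing from
the annotation map are listed, never silently dropped. The annotation map
itself is a plain gene → category table: the package consumes curated or
classifier-produced annotations, it does not train a text classifier.

## Triad census and significance profile

Triads are the 13 weakly connected 3-node directed graphs without
self-loops. Auto-regulation is a 1-node motif outside this classification,
so self-loops are stripped before any census. Each induced 3-node subgraph
is encoded as a 6-bit integer over the off-diagonal adjacency cells in
row-major order, and its class is the minimum of that code over the six
node permutations. Display ids follow the convention of triad
significance profile plots — id 7 is the feed-forward loop
{X→Y, X→Z, Y→Z} and id 10 is the mutual dyad regulating a common target
{X↔Y, X→Z, Y→Z} — with the full 1..13 ordering shipped as an editable
mapping (`inst/extdata/triad_classes.tsv`, with the standard M-A-N labels)
rather than hard-coded.

The census enumerates, for every undirected edge (u, v) with u < v, the
third nodes w in N(u) ∪ N(v), counting the triple once via the standard
subquadratic rule (count when v < w, or when u < w < v and w ∉ N(u)). Per
edge pair the classification is vectorized through a precomputed
64-entry code → id lookup. The result provably equals — and is tested
against — both igraph's C triad census and a per-triple isomorphism brute
force.

**Null model.** Significance is assessed against degree-preserving random
networks generated by edge switching: pick two interactions (a→b, c→d),
rewire to (a→d, c→b), reject the move if it would create a self-loop or a
duplicate edge (and optionally if it changes the number of mutual dyads).
Each replicate runs 10 attempted swaps per edge by default — a common
mixing heuristic for this chain — and is deterministically seeded from the
ensemble base seed. Every node's in- and out-degree is exactly preserved.

**Z-scores and profile.** For each class,
`z_i = (N_real_i − mean_i) / sd_i` over the ensemble (population standard
deviation), with two corrections: classes observed fewer than 4 times in
the real network are zeroed (rare-count robustness, applied *before*
normalization), and a zero-variance ensemble class is zeroed as the
conservative choice for a count the null model cannot vary. The triad
significance profile normalizes the Z vector to unit Euclidean length,
`SP_i = Z_i / (Σ_j Z_j²)^{1/2}`, so that networks of very different sizes
are comparable; an all-zero Z vector stays all-zero.

A consequence worth knowing: a *strictly bipartite* TF → TG network (no
TF regulating a TF) only contains fan-out and fan-in triads, and their
counts are fully determined by the degree sequences. The degree-preserving
ensemble then has zero variance and the profile is legitimately all-zero.
Informative profiles require TF→TF edges, which real regulatory networks
have. More generally, exact linear invariants of the null model show up in
profiles: the number of out-pairs Σ_u C(out_u, 2) = N_fanout + N_FFL, of
in-pairs = N_fanin + N_FFL, and of directed 2-paths = N_cascade + N_FFL
are all degree-determined, so in a network realizing only these classes
the Z-scores obey z_fanout = z_fanin = −z_FFL exactly and the profile
components come out at ±1/√k. This is the expected signature of planting
feed-forward loops into a sparse background, not an artifact.

The ensemble size default is 1000 for desk runs (published genome-scale
profiles use 10,000); the package's own statistical checks hold from
R = 200 upward.

## The synthetic generator

`generate_trn` emulates the statistical shape of curated yeast networks so
that every stage is testable without any database download:

* **out-degrees**: each TF gets an activity weight drawn from a discrete
  power law (default exponent α = 2.0), reflecting the well-established
  heavy-tailed number of targets per TF;
* **in-degrees**: each TG draws its number of regulators from a geometric
  law (default p = 0.35, mean 1/p ≈ 2.9), the exponential-like in-degree
  shape reported for reliable yeast subnetworks, then picks that many
  *distinct* TFs with probability proportional to the activity weights.
  In-degrees are therefore realized exactly and no duplicate edges arise;
  out-degrees inherit the heavy tail of the weights. The ledger records
  realized values, and all bookkeeping oracles use realized values;
* **evidence classes** per interaction with default fractions
  (expression-only 0.7687, binding-only 0.1725, both 0.0588) matching the
  published evidence Venn partition of the curated yeast network;
* **signs** for expression-supported interactions (defaults 0.45 positive,
  0.35 negative, 0.10 dual, 0.10 unknown — a realistic activator-leaning
  mix; the published sources quote no global sign fractions);
* **condition tags** independently per tag at configurable rates, and
  **reference sets** of size 1 + Poisson(μ) (default μ = 0.6, giving ≈ 1.6
  references per interaction, the order observed in curated collections).

Every random assignment is recorded in a **ledger**, which fully
determines the emitted network; tests recompute Venn partitions, reference
statistics and condition-filter counts from the ledger and demand exact
agreement. `plant_motifs` adds vertex-disjoint canonical instances of any
triad class on fresh nodes, giving a guaranteed lower bound for
enrichment-recovery tests.

What the generator does **not** emulate: real gene names and aliases, the
condition ontology's structure, correlations between evidence class and
degree, TF→TF regulation in the background wiring (planted motifs provide
it where tests need it), and literature-graph structure. Tests passing on
synthetic data therefore validate the *machinery*, not biological claims
about any particular database release.

## Numerical and design choices

* Percentages: half-even rounding to 2 decimals at the reporting surface.
* Published worked examples are recomputed from the printed input counts
  shipped under `inst/extdata/`; one published overlap percentage (the
  Balaji ∩ B share of B, printed as 24.26%) disagrees with its own printed
  counts (10,909 / 45,209 = 24.13%), and the package reports the
  recomputed value.
* Degree-distribution monotonicity for heavy-tailed samples is asserted
  over occupied bins: empty bins before isolated outliers make the strict
  version almost surely false at realistic sample sizes.
* Seeds are mandatory everywhere randomness occurs (generator, null model,
  pipeline); child seeds derive from the base seed by a fixed affine map
  modulo a < 2³¹ prime, so runs are reproducible and replicates
  independent in practice.
* Determinism: interaction tables are kept sorted by (tf, target); report
  files are written with fixed formatting and ordering, so identical
  configurations yield byte-identical bundles.
* Test and acceptance problem sizes (desk scale, chosen once): oracle
  parity on random digraphs up to 40 nodes; generator-law recovery at
  n = 2000 genes; planted-motif benchmark with a 15 TF / 65 TG background,
  30 planted feed-forward loops, ensembles of R = 200 and 40 replicates.

## Known limitations

* No gene-name alias resolution: overlaps between independently curated
  networks are exact-string overlaps.
* The chi-squared binning is one defensible agglomeration among several;
  its output depends on α and the pooling threshold.
* The edge-switching chain's mixing is heuristic (10 swaps per edge);
  extremely constrained degree sequences (e.g. the 2-edge chain) have no
  valid moves and correctly return the input network.
* Census complexity is fine for curated regulatory networks (sparse, up to
  a few thousand nodes) but the package deliberately implements no g-trie
  style acceleration and no motifs beyond size 3.
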