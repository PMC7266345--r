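---
title: "Methods: consensus clustering and cell-type enrichment in samclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus clustering and cell-type enrichment in samclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samclust)
```

# Scope and model of the data

`samclust` analyses cell-type-specific transcriptomes of the shoot apical
meristem (SAM) downstream of read counting. The experimental design it
models is a combinatorial FACS sort: fluorescent reporters mark the REV and
KAN1 expression domains and an epidermal layer marker (BFP), giving six
sorted populations — three epidermal (REV, KAN1, BFP-only) and three
sub-epidermal (REV, KAN1, all-negative). Differential expression is always
assessed *within* a tissue-layer group, comparing each population against
the other two of its group. A second axis of the design is perturbation:
log2 fold-change matrices describe transcriptional responses to induction
of a regulator across time points (e.g. REV and KAN1 at 6 h and 16 h), and
the package's clustering machinery groups genes by response profile.

The package consumes three tabular inputs: contrast tables
(`gene_id`, `contrast`, `log2fc`, `padj`), genes-by-conditions fold-change
matrices, and GMT gene-set annotations. It never re-implements a
differential-expression model: contrast tables are expected from a
dedicated tool (DESeq2 or similar). The bundled generator produces all
three inputs with planted structure so each downstream stage can be
validated against a known truth.

# Calling cell-type-enriched genes

A gene is *enriched* in population P when, in at least one of P's two
within-group pairwise contrasts, `log2fc > lfc_min` and `padj < padj_max`.
Defaults are `lfc_min = 1` (strict inequality) and `padj_max = 0.05`; both
are arguments, and a `strict = FALSE` flag switches the fold-change
comparison to `>=`, because both conventions are common in published DEG
definitions and the difference matters exactly on boundary genes. `NA`
adjusted p-values never qualify. Missing contrast orientations are derived
by sign flip, and a population lacking one of its two comparisons is
skipped with a warning rather than half-evaluated.

Enriched genes of one group are classified into six exclusive Venn sectors:
three single-population sectors and three pairwise overlaps. Under the
one-vs-each rule a triple membership should not arise; if inconsistent
input produces one, `classify_sectors()` fails naming the gene rather than
silently dropping it, since a silent drop would bias sector counts.

Cluster-level summaries divide each gene's per-population mean expression
by its value in a chosen reference population (so the reference column is
identically 1) and average within clusters. A cluster is called
*preferentially expressed* in P when its summarized value is at least
`fold_cutoff` (default 1.5) times the minimum across populations. The
baseline for the 1.5-fold comparison is a genuine design choice — the
summary values are already reference-relative — and comparing against the
population minimum was chosen because it labels a cluster whenever any
population stands out against the least-expressing one; the cutoff and the
whole predicate are exposed as arguments.

# Consensus clustering

The clustering core is a resampled k-means consensus procedure followed by
graph-based sparsification and community detection.

**Quantile normalization.** Condition columns of the log2 fold-change
matrix are forced to share one value distribution (per-rank across-column
means, ties averaged), via `limma::normalizeQuantiles()`. Missing entries —
genes not significant in some condition — are filled with 0 first: a
non-response is a zero fold change (row-mean fill or dropping are possible
alternatives; zero fill keeps the gene and asserts nothing about it).
Quantile normalization assumes the columns are exchangeable in
distribution. That holds to a good approximation for real multi-condition
response compendia, but it can be violated by design: if one condition has
genuinely more up-regulated mass than another, forcing a common
distribution scrambles ranks among genes with near-identical values and can
fragment true clusters. `consensus_cluster(normalize = FALSE)` is the
escape hatch, and the transient-response validation below uses it for
exactly this reason.

**The ensemble.** Each of `n_iterations` (default 4000) iterations draws a
cluster count k uniformly from `k_min` (default 3) to `floor(sqrt(n))`
(n = the total number of genes, not the subsample), draws a gene subsample
without replacement whose size is uniform between `ceiling(0.8 n)` and `n`,
and runs k-means (Euclidean, 500 maximum iterations, 20 random restarts).
For every gene pair the ensemble counts how often the two were sampled
together and how often they landed in the same cluster; the consensus
similarity is

\[
\mathrm{similarity}(i,j) =
\frac{\#\{\text{iterations where } i,j \text{ co-cluster}\}}
     {\#\{\text{iterations where } i,j \text{ co-sampled}\}},
\]

with similarity 0 by convention for pairs never co-sampled. Two numerical
details: k-means is run on the *unique* rows of the subsample (assignments
are mapped back), so identical profiles can never be separated and k is
implicitly capped at the number of distinct points — this makes noiseless
fixtures well-defined; and per-iteration RNG streams are derived from the
master seed and the iteration index, so results are bit-reproducible and
independent of execution order. Genes are processed in canonical id order
internally, which makes the whole procedure equivariant under permutation
of the input rows.

**Personalized-PageRank sparsification.** Weak consensus links are pruned
by ranking each gene's neighbours with a random walk biased to restart at
that gene (damping 0.85; restart mass entirely on the start gene; scores
from igraph's exact PRPACK solver). For a gene with d positive-similarity
neighbours, the edges to its top `ceiling(retain_frac * d)` neighbours are
retained (default `retain_frac = 0.65`), ties broken by gene id; the
retained directed selections are symmetrized by union, and surviving edges
keep their consensus-similarity weights. At `retain_frac = 1` the graph is
exactly the positive-similarity graph, and lowering the fraction can only
remove edges. An optional `min_similarity` node filter can drop genes whose
strongest link is negligible; it is off by default because edge retention
already handles weak similarity.

**Infomap.** The filtered weighted graph is partitioned by the Infomap
map-equation algorithm (igraph implementation), keeping the best of
`n_trials` randomized trials (default 1000). Isolated genes are labelled
unclustered (`NA`). `map_codelength()` computes the two-level map-equation
description length (bits) of any partition from the walk's stationary
visit rates, which lets tests verify that returned partitions beat the
trivial one-module partition on disconnected graphs.

**Granularity.** Because k ranges up to `sqrt(n)`, the ensemble probes
partitions much finer than any small planted truth whenever n is large
relative to the true cluster count. k-means splits of tight, low-dimensional
clusters can be *stable* across subsamples, in which case the consensus
matrix carries genuine sub-block structure and Infomap reports it. This is
a property of the procedure, not a defect — on real data it is what yields
fine-grained response clusters — but it means planted-recovery experiments
must choose n so that the sampled k range brackets the planted cluster
count.

**Hierarchical clustering.** For time-course matrices where a fixed,
manually chosen number of clusters is wanted, `hierarchical_cluster()`
applies agglomerative clustering (Euclidean distance, average linkage by
default) and cuts the tree to exactly `n_clusters`. It is deterministic and
is cross-checked in the tests against an independent agglomerative
implementation (`cluster::agnes`).

# Term enrichment and overlap tables

`term_enrichment()` is the classic one-sided hypergeometric test per term,
with the reporting filters applied afterwards: raw p below 0.05, at least 5
over-represented genes, at least 5 annotated genes (all arguments). Two
deliberate divergences from common GO tooling: no hierarchy-aware (elim /
weight) down-weighting is performed — the package does not parse the GO
DAG at all — and no multiple-testing correction is applied to the
enrichment p-values, because the filter triple, not an FDR threshold, is
the intended reporting rule; the unfiltered table is attached as an
attribute so users can adjust p-values themselves if they prefer. The
universe defaults to all genes present in the input tables (the
detected-in-tissue analogue), and should be set explicitly when the
annotation covers a different space.

Overlap tables count, for each query gene set, its members in each of a
collection of disjoint categories, as percentages of the query's
categorized members; an `"all"` baseline row is computed from a background
set. Percentages are kept exact throughout; rounding to whole numbers
happens only in `format_overlap_table()`, so downstream arithmetic never
sees rounded values. `coregulation_table()` cross-tabulates two regulators'
shared DEGs into co-induced, co-repressed and oppositely-regulated
fractions, which sum to one by construction.

# The synthetic-data generator

The generator emulates the study design, not any particular dataset.

* **Counts.** Per-gene baseline means are log-normal
  (`meanlog = 4`, `sdlog = 1.5`: median ~55 counts, long right tail);
  counts are negative binomial with dispersion 0.1 by default
  (variance \(\mu + \phi \mu^2\)). A planted fraction of genes is enriched
  in one population or a within-group pair, with expected counts shifted by
  `effect_size` log2 units there. The default of 3 replicates per
  population reflects a typical minimal sorted-population design; the
  bundled demo configuration uses 6 so that the simple stand-in test below
  is well powered.
* **Contrast tables.** `contrasts_from_counts()` is a deliberately simple
  stand-in used only to exercise downstream logic on synthetic counts: a
  Welch t-test on log2(total-count-normalized counts + 1) with
  Benjamini–Hochberg adjustment per contrast, and log2 fold changes of
  pseudocounted group means. It is *not* a negative-binomial
  differential-expression model and should never be used on real data.
* **Fold-change matrices.** Each gene's row is its cluster's profile plus
  i.i.d. Gaussian noise (`fc_noise_sd`, default 0.3). The stock profiles
  include a transient response — up at the early time point, down at the
  late one — alongside sustained up/down profiles.
* **Annotations.** One term equals the planted gene subset exactly;
  background terms are uniform draws with sizes in `term_size_range`.

What the generator does **not** emulate: sorting impurity and doublets,
batch and library-preparation effects, gene–gene correlation, length/GC
biases, and read-level noise. Passing recovery tests therefore demonstrate
the correctness of the algorithms under their stated model, not performance
on real libraries.

# Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` re-derive the package's headline
properties from scratch:

* consensus similarity equals an independent double-loop recount of a
  stored 20-gene, 50-iteration ensemble, exactly;
* five planted response profiles (pairwise separation ≥ 2 log2 units,
  noise sd 0.4, 60 genes each) are recovered with ARI ≥ 0.9 by the full
  procedure at 500 iterations, across three seeds;
* the transient profile (+1.7, −1.4) separates from sustained (+1.7, +1.7)
  and (−1.5, −1.5) profiles at noise sd 0.3. This experiment uses 12 genes
  per cluster (n = 36, so k ranges over 3–6, bracketing the true 3) and
  `normalize = FALSE`: with two conditions whose true value distributions
  differ (two-thirds vs one-third positive mass), quantile normalization
  violates its exchangeability assumption and fragments the planted
  clusters, while the simulated log2 fold changes are already on a common
  scale by construction;
* the six-gene contrast fixture reproduces the hand-evaluated enriched
  sets and sectors exactly, including exclusion of the boundary gene at
  `log2fc = 1.0` under the strict rule;
* quantile normalization leaves all columns with identical sorted values
  and is idempotent to 1e-12 on 100 random matrices;
* hypergeometric p-values match exact combinatorial enumeration on every
  instance with universe ≤ 30, and a planted annotation term ranks first
  whenever it passes the filters;
* PageRank retention is monotone in `retain_frac` and matches the
  hand-derived edge set on a star graph;
* two pipeline runs with the same configuration and seed produce
  byte-identical outputs.

Ensemble sizes in these experiments (50–500 iterations) are far below the
4000-iteration default; they are chosen so each planted-recovery experiment
is comfortably stable at its problem size, which a few hundred iterations
already achieve for n ≤ 300.

# Known limitations

* The stand-in contrast generator has low power at 3 replicates and is not
  a substitute for a real differential-expression model.
* Enrichment ignores the GO hierarchy; parent terms of a truly enriched
  term will often also be reported.
* Consensus clustering granularity depends on n through the k ≤ sqrt(n)
  rule; there is no model-selection layer choosing a cluster number.
* Quantile normalization should be disabled when conditions are known to
  have genuinely different fold-change distributions.
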