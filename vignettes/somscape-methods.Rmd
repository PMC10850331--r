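---
title: "Methods: unsupervised transcriptome landscapes of stem-cell differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised transcriptome landscapes of stem-cell differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

somscape implements an unsupervised workflow for whole-transcriptome bulk
RNA-seq time courses, aimed at experiments that compare stem-cell
differentiation protocols (for example, hiPSC cardiac differentiation run as
a 2D monolayer versus 3D aggregates) across many time points and replicate
experiments. This vignette explains the models and procedures behind each
stage, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical conventions and known
limitations.

## Preprocessing to log-fold-change space

Every downstream stage consumes centred log2 fold changes. From raw read
counts the pipeline:

1. **Filters** lowly expressed genes. A gene is kept iff its
   counts-per-million exceed `t = min_count / median(library sizes) * 1e6`
   in at least `n` samples, where `min_count = 10` reads and `n` is the size
   of the smallest sample class. This is the usual "at least 10 reads, in at
   least as many samples as the smallest group" rule expressed on the CPM
   scale; it is deliberately a simple documented rule rather than a port of
   any particular tool's edge cases, so its behaviour is exactly testable.
2. **Normalises** with TMM (trimmed mean of M-values): per-sample scaling
   factors from doubly trimmed (30% on M, 5% on A) log2 expression ratios
   against a reference sample (the one whose upper-quartile CPM is closest
   to the mean upper quartile), precision-weighted with delta-method
   variances, rescaled to geometric mean 1. Genes with a zero count in
   either member of a pair are excluded from M/A computation, and trim-rank
   ties are resolved by a stable sort on gene identifier so the factor is a
   pure function of the input. An independent naive sort-trim-average oracle
   reproduces the factors to 1e-9 in the test suite, and
   `edgeR::calcNormFactors` agrees to well under 1%.
3. **Transforms** to `log2((y + p) / (N_eff + 2p) * 1e6)` with a fixed
   additive prior `p = 3` and the TMM-effective library size `N_eff`. The
   prior is a constant (some tools scale it by relative library size); a
   fixed prior keeps the formula exact and testable, and the difference is
   negligible at these library sizes.
4. **Centres** each gene on its mean over all samples:
   `Δe = e − ⟨e⟩_{all samples}`. Centring uses all samples, not per-protocol
   subsets, so a gene's Δe is comparable across protocols. Replicate
   averaging (arithmetic mean per `(protocol, day)` condition, with seeding
   samples as their own condition) produces the condition-level matrix used
   for dendrograms and mean portraits.

## Sample hierarchies: nine variants and the lifetime cut

Samples (or condition means) are clustered agglomeratively under all nine
combinations of distance (Euclidean, cosine `1 − cos`, Pearson `1 − r`) and
linkage (single, average, complete). Each dendrogram is cut by the
**lifetime criterion**: with sorted merge heights `d_1 ≤ … ≤ d_{n−1}`, the
cut is placed inside the largest gap `d_{i+1} − d_i`, giving `k = n − i`
clusters. The partition that persists over the widest range of thresholds is
taken as the natural one. Conventions: if no internal gap is positive (all
merges at one height) the single-cluster solution is returned, as it is for
fewer than three items; ties between equal gaps resolve toward the later gap
(the coarser partition).

Each partition with `2 ≤ k ≤ n − 1` is scored by the mean silhouette width
(under the partition's own metric) and the Calinski–Harabasz index
(Euclidean). When one partition is best on both indices it is selected;
otherwise partitions are ranked by each index and the smallest rank sum
wins, ties broken by the higher silhouette. This makes the "pick the densest
and best-separated partition" idea deterministic when the two indices
disagree. Degenerate partitions (`k = 1` or `k = n`) are excluded from
selection.

PCA (sample-wise centring, no scaling) complements the dendrograms; trees
are exported as Newick with leaf depth equal to merge height.

## Self-organising map and metagene portraits

Genes (rows of the Δe matrix) are mapped onto a square grid of
`grid_side² = 40 × 40 = 1600` nodes — about one order of magnitude fewer
nodes than the ~5,000-gene post-filter transcriptome, the usual sizing for
expression portraits. Training is classic online SOM: per step one gene is
presented (a fresh seeded permutation per epoch; one epoch is one full pass
over the genes, and the default is 3 epochs), the Euclidean best-matching
node is found, and the winner and its Gaussian neighbourhood move toward the
gene. The learning schedule is a conventional linear decay — rate 0.5 → 0.05
and radius `grid_side/2` → 1 across all steps — and nodes are initialised at
randomly chosen genes plus a small Gaussian perturbation (sd 0.1), which
stabilises such short trainings. The training loop is compiled (Rcpp); per
epoch the mean squared gene-to-best-node distance (quantization error) is
logged and is checked to be non-increasing.

After training, every gene is assigned to its nearest node and each occupied
node's weight vector is replaced by the mean Δe profile of its genes — the
**metagene**. Empty nodes keep their trained weights so portraits have no
gaps (their occupancy 0 is recorded). Per node, three quality statistics are
reported: the variance of the metagene across samples, the Shannon entropy
of the metagene profile discretised into 10 equal-width bins over its own
range (0 for a constant profile), and the mean Pearson correlation between
member genes and their metagene.

A **portrait** is one sample's (or condition's) metagene values arranged on
the grid and min–max scaled to [0, 1] — a relative scale where each
portrait's extremes are that sample's own lowest and highest metagene
expression — exported as PNG under a blue → green → yellow → red ramp plus a
numeric TSV. Training on all individual samples (default) or on condition
means are both supported; both portrait sets are produced either way.

## Grid segmentation, feature selection and efficiency markers

K-means (Euclidean, k-means++ seeding, 10 restarts, best within-cluster sum
of squares; Lloyd iterations via `stats::kmeans`) partitions the occupied
nodes' metagene profiles into `k = 20` clusters labelled `A`–`T` in order of
decreasing size. Only occupied nodes are clustered — empty-node weights are
interpolations, not data. Contiguity on the grid is emergent, not enforced.

A cluster is **significant** iff the maximum absolute value of its mean
profile reaches 1.0 Δe (a 2-fold change, the smallest conventional
fold-change of interest; exposed as a parameter). The union of genes in
significant clusters is the feature-selection output; the package then
recomputes the selected clustering variant on that subset and reports the
adjusted Rand index and cophenetic correlation against the whole-geneset
hierarchy, which on the synthetic preset returns ARI = 1.

The **efficiency-marker** stage replaces visual inspection with an explicit
statistic: among significant clusters it picks the one whose mean profile
correlates most negatively (Pearson) with replicate differentiation
efficiency across samples at day ≥ 7 (the onset parameter), then ranks that
cluster's genes by their peak Δe over all samples (ties by identifier) and
reports the top 10 with their trajectories. Degenerate inputs (no
efficiency metadata, or all efficiencies equal) are explicit errors.

## Over-representation and bi-clustering

Over-representation of a gene list against a user-supplied GMT collection is
the one-sided Fisher exact test, i.e. the hypergeometric upper tail
`P(X ≥ overlap)`, against an explicit universe (default: the post-filter
gene list — a whole-genome background is not reproducible offline, so the
universe is always explicit). P-values are Benjamini–Hochberg adjusted
across the collection (Bonferroni available); fold enrichment is
`(overlap/|query|) / (|set ∩ universe|/|universe|)`. No gene-set data are
bundled.

Hierarchical bi-clustering builds two independent trees — genes and samples,
Euclidean/complete by default, sharing the linkage-tree implementation of
the sample-clustering stage — and exports the reordered matrix. The heatmap
uses a symmetric diverging scale about 0 Δe (unlike portraits'
per-sample scaling) so samples are comparable; column clustering can be
disabled to keep samples in experimental order. A fixed-depth row cut
(default 5 clusters) isolates coherent gene blocks; on the synthetic preset
the planted contaminant genes land in one such block.

## The synthetic-data generator

The generator is a first-class module that emulates the design of a
two-protocol hiPSC cardiac differentiation study: 2 protocols × 10 time
points (days 0, 1, 3, 5, 7, 9, 12, 15, 18, 20) × 3 replicates, one
condition (2D day 12) in duplicate, plus 3 hiPSC seeding samples — 62
samples in total. Counts are negative binomial: the expected count of gene
g in sample s is `exp(baseline_g + ln 2 · offset_gs) · libsize_s / 1e7`,
with gene-wise dispersions log-uniform in [0.01, 0.5] (the standard bulk
RNA-seq noise assumption) and library sizes log-normal around 1e7 (sdlog
0.3) to force nontrivial TMM factors.

Planted modules (piecewise-linear log2FC offsets in day, per protocol; 40
genes each unless noted):

* **pluripotency** — high (+3) in seeding samples and days ≤ 1, decaying to
  −3 by day 7;
* **mesoderm, transient** — sharp +4 peak at day 3, rapidly shut off (the
  early-wave behaviour of markers like TBXT);
* **mesoderm, sustained** — +3 from day 3, sustained (ROR2-like);
* **cardiac progenitor** — rise at day 7, sustained;
* **cardiomyocyte** — rise from day 9 to +4;
* **translation/ribosome** — +2.5 in seeding and early 2D samples, silent
  in the 3D protocol from day 0;
* **3D-only late maturation** — +3 in 3D days 15–20 only;
* **endoderm contaminant** (10 genes) — active only in replicates whose
  efficiency is below 0.6 and only from day 7 on, peaking at +7 log2FC at
  day 9.

Replicate efficiencies for the preset are fixed constants spanning the
realistic ~45–90% range of terminal cardiomyocyte purity — 2D: 45, 80, 55%;
3D: 70, 90, 75% — making the first and third 2D replicates the
low-efficiency experiments. They are parameters, not measurements.
Amplitudes are desk-scale choices made once; the gene universe defaults to
5,000 genes as a stand-in for a post-filter transcriptome.

What the generator does **not** emulate: real count distributions or gene
identities of any particular accession, batch effects, transcript-length
bias, single-cell structure, or correlated noise between genes outside the
planted modules. Passing tests therefore demonstrate that the
implementation recovers structure it is known to contain under NB noise —
not that the method would behave identically on any real dataset.

## Numerical conventions and degenerate inputs

* Distances: Pearson/cosine distances are clipped at 0 against numerical
  noise; constant (Pearson) or zero (cosine) vectors are errors naming the
  offending item.
* Lifetime ties: later (coarser) gap wins; `n ≤ 2` returns one cluster.
* K-means: seeded k-means++, 10 restarts, Lloyd, best inertia; cluster
  letters assigned by decreasing size for reproducibility.
* SOM: ties in best-matching-unit search go to the lowest node index;
  neighbourhood updates below 1e-6 learning weight are skipped (a pure
  speed cutoff, below any meaningful update).
* Entropy binning: 10 equal-width bins over each node's own range.
* Portraits of a constant grid are flat mid-scale (0.5) with a warning.
* All randomness is funnelled through explicit integer seeds; the pipeline
  derives per-stage seeds from one root seed, and reruns are byte-identical.

## Problem sizes used by the test suite

Unit tests run on a reduced design (2 protocols × 5 days × 2 replicates +
2 seeding samples, 600 genes, 10 × 10 grid, 2 epochs, 12 grid clusters)
chosen so that each planted module's full temporal profile is sampled.
Study-scale checks use the full preset (5,000 genes, 62 samples, 40 × 40
grid, 3 epochs, 20 clusters) and the marker-recovery property is evaluated
over 20 independent simulations.

## Known limitations

* **Cluster-mean dilution.** Significance is judged on the mean profile of
  a K-means cluster. A small planted module whose few nodes are merged into
  a large flat cluster can be diluted below the 1.0 Δe threshold and its
  genes lost from the selection; at the full preset scale this happens to
  the weakest module (3D-only maturation, amplitude 2–3 Δe over 3 of 21
  conditions) in roughly half of the simulation seeds. Larger `k`, a lower
  threshold, or per-node significance would all change this trade-off; the
  defaults follow the documented method.
* **Leaf-order dependence.** Agglomerative leaf orders (heatmap row/column
  arrangements) depend on input order through subtree orientation; merge
  heights and fixed-k partitions are order-invariant and are what the tests
  assert.
* **Portrait scale.** Portraits are per-sample relative scales by design;
  they show where a sample's extremes sit on the grid, not absolute Δe —
  use the bicluster heatmap's symmetric scale for cross-sample magnitude
  comparisons.
* The SOM is a flat (non-toroidal) square grid with Euclidean matching
  only; there is no batch-SOM variant and no bootstrap support for
  dendrogram nodes.
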