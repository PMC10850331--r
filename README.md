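# somscape

Unsupervised whole-transcriptome analysis of stem-cell differentiation time
courses, for experiments that profile two (or more) culture protocols by
bulk RNA-seq over many days and replicates — e.g. hiPSC cardiac
differentiation run as a 2D monolayer versus 3D aggregates. Instead of
restricting attention to a pre-selected gene panel, the workflow portrays
the entire transcriptome and lets the structure of the data pick out the
genes that matter, including markers that predict low differentiation
efficiency.

## The method

Raw counts are filtered (CPM ≥ 10-read equivalent in at least the smallest
class), TMM-normalised, log-transformed with a prior count of 3, and centred
per gene so that every value is a log2 fold change against the gene's
ensemble average:

    Δe = e − ⟨e⟩_all samples

On this matrix the pipeline runs:

* **Sample hierarchies** — agglomerative clustering under all 9 metric ×
  linkage combinations (Euclidean/cosine/Pearson × single/average/complete),
  each dendrogram cut by the *lifetime criterion* (the cut falls in the
  largest gap between consecutive merge heights), validated by silhouette
  and Calinski–Harabasz and one partition selected; plus PCA.
* **SOM expression portraits** — genes mapped onto a 40×40 self-organising
  map (3 epochs, Euclidean matching); each node's gene-average profile is a
  *metagene*, and per-sample min–max-scaled grids are the expression
  portraits.
* **Grid segmentation** — K-means (k = 20, clusters `A`–`T`) on the metagene
  profiles; clusters whose mean profile never reaches |Δe| ≥ 1 are flagged
  non-significant; genes in significant clusters are the selected feature
  set, validated by reconstructing the sample hierarchy (adjusted Rand
  index) from them alone.
* **Efficiency markers** — the significant cluster most negatively
  correlated with replicate differentiation efficiency at late days, its
  genes ranked by peak Δe, top 10 reported with trajectories.
* **Over-representation** — one-sided Fisher (hypergeometric upper tail)
  against user-supplied GMT gene sets with BH correction.
* **Bi-clustering** — independent gene and sample hierarchies
  (Euclidean/complete) with a fixed-depth row cut for heatmap views.

A negative-binomial simulator generates the full two-protocol study design
(2 protocols × 10 days × 3 replicates, one duplicate condition, 3 seeding
samples = 62 samples) with planted stage-specific modules — pluripotency,
transient and sustained mesoderm, cardiac progenitor, cardiomyocyte,
protocol-specific modules, and a low-efficiency endoderm-contaminant module
peaking at 7 log2FC — plus machine-readable ground truth, so every stage of
the pipeline is verifiable without external data.

## Worked example

```r
library(somscape)
res <- run_pipeline(pipeline_config(outdir = "run1", seed = 1))

print(res$hc)
#> hierarchical clustering, 9 variants; indices disagree; rank-sum rule applied
#>      metric  linkage k silhouette calinski_harabasz selected
#> 1 euclidean   single 5  0.2134362          6.208344    FALSE
#> 2 euclidean  average 2  0.3381818         14.291086    FALSE
#> 3 euclidean complete 2  0.3381818         14.291086    FALSE
#> 4    cosine   single 2  0.5392038         14.291086    FALSE
#> 5    cosine  average 2  0.5392038         14.291086    FALSE
#> 6    cosine complete 2  0.5392038         14.291086    FALSE
#> 7   pearson   single 2  0.5394878         14.291086     TRUE
#> 8   pearson  average 2  0.5394878         14.291086    FALSE
#> 9   pearson complete 2  0.5394878         14.291086    FALSE

print(res$segmentation)
#> grid_segmentation: k = 20 clusters over 1295 nodes; 15 significant

print(res$markers)
#> marker_report: cluster Q (efficiency correlation -0.870); 10 top genes:
#>   ENDODERM_CONTAMINANT_g010, ENDODERM_CONTAMINANT_g005, ...

res$reconstruction$ari
#> [1] 1
```

Reading the output: eight of nine clustering variants agree on a 2-cluster
sample partition — the early (day ≤ 5) versus late (day ≥ 7) split of the
time course — and the Pearson/single variant is selected by the rank-sum
rule. Of the 20 grid clusters, 15 carry significant expression; the genes
they contain reconstruct the whole-geneset sample hierarchy exactly
(ARI = 1). The marker stage identifies the cluster anticorrelated with
differentiation efficiency (r = −0.87) and its top-10 genes are exactly the
planted 10-gene endoderm-contaminant module.

All stage outputs (counts, Δe matrix, normalisation report, 9 Newick trees,
variant table, gene positions, segmentation, marker report, bicluster
matrix, `summary.json`) are written under `outdir`.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/somscape.R", package="somscape"))')" \
    simulate --preset paper --seed 1 --out simdir
```

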