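Package: somscape
Title: Self-Organising-Map Expression Portraits for Stem-Cell
    Differentiation Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An unsupervised workflow for whole-transcriptome analysis of
    stem-cell differentiation time courses profiled by bulk RNA-seq under
    multiple culture protocols. Raw read counts are filtered, TMM-normalised
    and transformed to gene-centred log2 fold changes; samples are organised
    by agglomerative clustering across nine metric/linkage variants with
    lifetime-criterion dendrogram cuts and internal validation; genes are
    mapped onto a square self-organising map whose node averages (metagenes)
    yield per-sample expression portraits; the metagene grid is segmented by
    K-means into labelled clusters, non-significant clusters are filtered,
    and candidate markers of differentiation efficiency are extracted;
    gene clusters are tested for over-representation against user-supplied
    GMT gene-set collections; and genes and samples are bi-clustered for
    heatmap views. A negative-binomial simulator generates two-protocol
    differentiation designs with planted stage-specific gene modules and
    ground truth so that every stage of the pipeline can be verified.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    cluster,
    grDevices,
    jsonlite,
    mclust,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
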