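Package: exprkit
Title: Expression Matrix Normalization, Differential Expression, Marker
    Discovery and Gene-Set Enrichment for Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A headless analysis engine for grouped bulk RNA-seq expression
    tables: CPM/RPKM/TPM normalization with log2 transform, group-wise
    differential expression by Welch's t and Wilcoxon rank-sum tests with
    Benjamini-Hochberg FDR, one-vs-rest marker-gene discovery ranking genes by
    maximized fold change and minimized coefficient of variation, pre-ranked
    gene-set enrichment analysis with a permutation null, hypergeometric
    over-representation tests, set-level Wilcoxon expression comparison, and
    sample-space dimensionality reduction (PCA, classical MDS, t-SNE/UMAP).
    Includes a deterministic negative-binomial simulator with planted markers,
    differentially expressed genes and enriched sets, and a command-line
    interface over delimited-text and GMT inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Rtsne,
    uwot
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    cluster,
    jsonlite
Config/testthat/edition: 3
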