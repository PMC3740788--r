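Package: mirpoma
Title: Consensus microRNA Signature Discovery with Outlier Statistics and
    Regulatory-Activity Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for extracting reproducible microRNA
    expression signatures from multiple heterogeneous case/control microarray
    studies. Implements five cancer-outlier detection statistics (pooled t,
    COPA, OS, ORT and MOST) with a consensus-based accuracy benchmark, a
    preprocessing chain (normexp background correction, quantile
    normalization, probe averaging and k-nearest-neighbour imputation), the
    POMA regulatory-activity filter which scores each microRNA by the
    fraction of deregulated target genes it controls exclusively
    (Z = alpha/beta on a miRNA-mRNA bipartite network), cross-dataset
    consensus signature extraction, target consolidation across evidence
    sources, hypergeometric gene-set enrichment with
    Benjamini-Hochberg control, and multi-level reproducibility analysis.
    A synthetic-data generator with planted ground truth emulates the
    heterogeneous outlier-activation regime the method targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
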