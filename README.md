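# mirpoma

Consensus microRNA signature discovery from multiple case/control
expression cohorts, combining outlier statistics for heterogeneously
activated features with a network-based regulatory-activity filter.

## The problem

Differential miRNA lists from independent tumour/normal cohorts overlap
poorly: oncogenic miRNAs are often shifted in only a subset of tumours
(where the t-test loses power), and a detected expression shift says
nothing about regulatory function. `mirpoma` addresses both. It is aimed
at computational biologists integrating several miRNA and mRNA microarray
cohorts of the same disease who want a signature that survives
cross-cohort and functional filtering — and at methodologists who want a
fully testable, simulation-backed implementation of the component
statistics.

## What it implements

* **Five outlier statistics** for two-group designs: pooled t, COPA
  (percentile of median/MAD-standardized tumour values), OS (outlier sum
  above `q75 + IQR` of all samples), ORT (normal-referenced outlier sum
  with a pooled robust scale) and MOST (max over k of the standardized
  sum of the top-k tumour values, `max_k (M_k − μ_k)/σ_k`, with Monte
  Carlo null moments μ_k, σ_k). Two-sided scoring with recorded
  direction; top-5% selection; a consensus benchmark (features selected
  by ≥3 of 5 methods form the putative set; a method's accuracy is the
  median share of its selection that is putative).
* **Regulatory-activity filter**: on a miRNA–mRNA network restricted to
  deregulated genes, each miRNA gets `Z = α/β` — deregulated targets it
  controls exclusively over all its deregulated targets. Active means
  `α ≥ 2`, `β ≥ 2`, `Z ≥ 0.1`; cohort consensus (3-of-4), intersection
  with each differential list, and a 4-of-5 consensus signature.
* **Preprocessing**: normexp background correction (offset 0, per-sample
  MLE via limma), quantile normalization (missing-aware), probe
  averaging, kNN imputation (k = 5), unique-probe gene filtering.
* **Targets and enrichment**: multi-source target consolidation (drop
  single-source predictions; experimental sources exempt), exact
  hypergeometric enrichment with BH-FDR, and a relevance screen
  (ratio > 0.15, p < 1e-4) with volcano-plot coordinates.
* **Consistency analysis**: pairwise Jaccard (or min-denominator) overlap
  across cohorts at miRNA/target/pathway level, with a paired t-test for
  before/after filtration.
* **Synthetic studies**: a generator planting a shared active-miRNA core,
  cohort-specific false signatures, heterogeneous activation shifts,
  missing values and an exact-exclusivity interaction network, with full
  ground truth for evaluation.

## Worked example

Simulate a five-cohort miRNA / four-cohort mRNA study with six truly
active miRNAs and a clear planted signal, then run the whole pipeline:

```r
library(mirpoma)

cfg <- sim_config(n_features_mirna = 300, n_genes = 1000,
                  n_normal = 20, n_tumor = 20,
                  n_true_active_mirna = 6, noise_signature_size = 8,
                  network_coverage = 0.4, targets_per_mirna = 6,
                  exclusive_per_mirna = 3, activation_fraction = 0.6,
                  effect_size = 4, seed = 42)
out <- run_simulated_study(cfg)
out$result
#> Integrative miRNA signature pipeline
#>   differential miRNAs per dataset: 15, 15, 15, 15, 15
#>   consensus-active miRNAs: 6
#>   filtered lists: 5, 3, 5, 4, 6
#>   final signature: 5 miRNA(s)
#>   mean overlap 0.138 -> 0.613 (paired t p = 1.84e-06)
out$result$signature
#>      mirna support
#> 1 mir-0007       5
#> 2 mir-0024       4
#> 3 mir-0048       4
#> 4 mir-0117       4
#> 5 mir-0200       4
unlist(out$evaluation)
#>   jaccard    recall precision
#>      0.83      0.83      1.00
```

Reading the output: each cohort's top-5% outlier list (15 miRNAs) is cut
to the handful with consensus regulatory activity; the mean pairwise
Jaccard overlap between cohort lists jumps from 0.14 to 0.61 after
filtration; and the 4-of-5 consensus signature recovers five of the six
planted active miRNAs with no false positives. At weaker signal
strengths the same machinery yields smaller, lower-recall signatures —
the methods vignette (`vignettes/mirpoma-methods.Rmd`) quantifies this
and documents every modelling choice.

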