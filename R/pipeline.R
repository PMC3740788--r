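#' Run the integrative signature-discovery pipeline
#'
#' Chains the full analysis on an in-memory study: differential (outlier)
#' miRNA detection with MOST on every miRNA dataset; deregulated-gene
#' detection on every mRNA dataset; the regulatory-activity filter
#' (disease-specific subnetwork, Z = alpha/beta, threshold, cross-dataset
#' consensus); cross-matching of the consensus-active set with each
#' differential list; consensus signature extraction; and the
#' before/after consistency analysis.
#'
#' @param mirna_datasets List of preprocessed miRNA
#'   [expression_dataset()]s.
#' @param mrna_datasets List of preprocessed mRNA [expression_dataset()]s.
#' @param network A [target_network()].
#' @param selection_fraction Top fraction for outlier selection
#'   (default 0.05).
#' @param z_threshold Regulatory-activity threshold (default 0.1,
#'   inclusive).
#' @param active_min_datasets Consensus rule for active miRNAs
#'   (default 3, i.e. 3 of 4 mRNA datasets).
#' @param signature_min_support Consensus rule for the final signature
#'   (default 4, i.e. 4 of 5 miRNA datasets).
#' @param overlap_mode `"jaccard"` or `"min"` for the consistency
#'   analysis.
#' @param ... Passed to [score_dataset()] (e.g. `null_B`, `null_seed`).
#'
#' @return A list of class `poma_result` with elements `de_mirna`
#'   (per-dataset differential lists), `dereg` (per-mRNA-dataset
#'   deregulated genes), `zrecords`, `active` (per-mRNA-dataset active
#'   miRNAs), `active_consensus`, `filtered` (per-miRNA-dataset lists
#'   after cross-matching), `signature` (data frame mirna/support),
#'   `consistency` (overlap reports before/after plus paired t when
#'   defined) and `manifest` (parameters and package version).
#' @export
run_pipeline <- function(mirna_datasets, mrna_datasets, network,
                         selection_fraction = 0.05, z_threshold = 0.1,
                         active_min_datasets = 3L,
                         signature_min_support = 4L,
                         overlap_mode = c("jaccard", "min"), ...) {
  overlap_mode <- match.arg(overlap_mode)
  stopifnot(is.list(mirna_datasets), is.list(mrna_datasets),
            inherits(network, "target_network"))

  de_mirna <- lapply(mirna_datasets, function(d)
    sort(selected_features(score_dataset(d, method = "MOST",
                                         selection_fraction =
                                           selection_fraction, ...))))
  names(de_mirna) <- vapply(mirna_datasets, function(d) d$dataset_id, "")

  dereg <- lapply(mrna_datasets, dereg_genes,
                  selection_fraction = selection_fraction, ...)
  names(dereg) <- vapply(mrna_datasets, function(d) d$dataset_id, "")

  zrecords <- lapply(dereg, function(g)
    compute_z(build_subnetwork(network, g)))
  active <- lapply(zrecords, active_mirnas, z_threshold = z_threshold)
  consensus <- active_consensus(active, min_datasets = active_min_datasets)

  filtered <- lapply(de_mirna, cross_match, active = consensus)
  signature <- final_signature(filtered,
                               min_support = signature_min_support)

  before <- pairwise_overlap(de_mirna, mode = overlap_mode,
                             level = "miRNA (pre-filter)")
  after_ok <- all(lengths(filtered) > 0L)
  after <- if (after_ok)
    pairwise_overlap(filtered, mode = overlap_mode,
                     level = "miRNA (post-filter)") else NULL
  ttest <- if (after_ok && stats::sd(after$overlap - before$overlap) > 0)
    paired_ttest(before$overlap, after$overlap) else NULL

  structure(
    list(de_mirna = de_mirna, dereg = dereg, zrecords = zrecords,
         active = active, active_consensus = consensus,
         filtered = filtered, signature = signature,
         consistency = list(before = before, after = after,
                            paired_t = ttest),
         manifest = list(
           selection_fraction = selection_fraction,
           z_threshold = z_threshold,
           active_min_datasets = active_min_datasets,
           signature_min_support = signature_min_support,
           overlap_mode = overlap_mode,
           version = as.character(utils::packageVersion("mirpoma")),
           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "poma_result")
}

#' @export
print.poma_result <- function(x, ...) {
  cat("Integrative miRNA signature pipeline\n")
  cat(sprintf("  differential miRNAs per dataset: %s\n",
              paste(lengths(x$de_mirna), collapse = ", ")))
  cat(sprintf("  consensus-active miRNAs: %d\n",
              length(x$active_consensus)))
  cat(sprintf("  filtered lists: %s\n",
              paste(lengths(x$filtered), collapse = ", ")))
  cat(sprintf("  final signature: %d miRNA(s)\n", nrow(x$signature)))
  if (!is.null(x$consistency$paired_t))
    cat(sprintf("  mean overlap %.3f -> %.3f (paired t p = %.3g)\n",
                attr(x$consistency$before, "mean"),
                attr(x$consistency$after, "mean"),
                x$consistency$paired_t$p))
  invisible(x)
}

#' Simulate a study and run the full pipeline against its ground truth
#'
#' Convenience driver: [simulate_study()], light preprocessing (quantile
#' normalization and kNN imputation; the simulated data is already on a
#' log-like scale, so background correction is skipped), [run_pipeline()],
#' and evaluation of the recovered signature against the planted truth.
#'
#' @param config A [sim_config()].
#' @param preprocess Run quantile normalization + imputation first
#'   (default `TRUE`).
#' @param knn_k Imputation neighbours (default 5).
#' @param ... Passed to [run_pipeline()].
#'
#' @return A list with `study`, `result` (the `poma_result`) and
#'   `evaluation` (signature vs truth: Jaccard, recall, precision).
#' @export
run_simulated_study <- function(config = sim_config(), preprocess = TRUE,
                                knn_k = 5L, ...) {
  study <- simulate_study(config)
  prep <- function(d) {
    if (!preprocess) return(d)
    preprocess_dataset(d, knn_k = knn_k, steps = c("quantile", "impute"))
  }
  mirna <- lapply(study$mirna_datasets, prep)
  mrna <- lapply(study$mrna_datasets, prep)
  result <- run_pipeline(mirna, mrna, study$network, ...)
  sig <- result$signature$mirna
  truth <- study$truth$active_mirnas
  evaluation <- list(
    jaccard = overlap_percentage(sig, truth, mode = "jaccard"),
    recall = length(intersect(sig, truth)) / length(truth),
    precision = if (length(sig))
      length(intersect(sig, truth)) / length(sig) else NA_real_)
  list(study = study, result = result, evaluation = evaluation)
}
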