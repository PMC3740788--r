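#' Simulation configuration
#'
#' Parameters of the synthetic multi-dataset study generator. The generator
#' emulates the statistical structure of a multi-cohort miRNA/mRNA
#' case-control compendium in which true regulators are shared across
#' cohorts but are activated in only a fraction of tumor samples
#' (heterogeneous outlier activation), each cohort carries its own false
#' signature, and a small proportion of entries is missing.
#'
#' @param n_mirna_datasets,n_mrna_datasets Number of miRNA / mRNA cohorts.
#' @param n_features_mirna Number of miRNA features per miRNA dataset.
#' @param n_genes Number of genes per mRNA dataset.
#' @param n_normal,n_tumor Samples per group in every dataset.
#' @param n_true_active_mirna Size of the shared core of truly active
#'   miRNAs planted in all miRNA datasets.
#' @param activation_fraction Fraction of tumor samples carrying the
#'   expression shift of a planted feature, in (0, 1].
#' @param effect_size Size of the planted shift in units of `baseline_sd`.
#' @param baseline_mean,baseline_sd Mean and SD of the Gaussian baseline on
#'   a log2-like scale.
#' @param missing_rate Fraction of entries set missing completely at
#'   random, in [0, 1).
#' @param noise_signature_size Number of dataset-specific false planted
#'   features per dataset (the irreproducible component).
#' @param targets_per_mirna,exclusive_per_mirna Interaction-network profile:
#'   total targets and exclusively-owned targets per covered miRNA.
#' @param network_coverage Fraction of the miRNA universe present in the
#'   interaction network (target databases cover only a minority of
#'   annotated miRNAs); truly active miRNAs are always covered.
#' @param seed Master seed; all randomness derives from it through
#'   per-dataset substreams.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mirna_datasets = 5L, n_mrna_datasets = 4L,
                       n_features_mirna = 800L, n_genes = 2000L,
                       n_normal = 15L, n_tumor = 15L,
                       n_true_active_mirna = 11L,
                       activation_fraction = 0.3, effect_size = 3.0,
                       baseline_mean = 8.0, baseline_sd = 1.0,
                       missing_rate = 0.02, noise_signature_size = 15L,
                       targets_per_mirna = 8L, exclusive_per_mirna = 5L,
                       network_coverage = 0.25, seed = 1L) {
  cfg <- list(
    n_mirna_datasets = as.integer(n_mirna_datasets),
    n_mrna_datasets = as.integer(n_mrna_datasets),
    n_features_mirna = as.integer(n_features_mirna),
    n_genes = as.integer(n_genes),
    n_normal = as.integer(n_normal), n_tumor = as.integer(n_tumor),
    n_true_active_mirna = as.integer(n_true_active_mirna),
    activation_fraction = activation_fraction, effect_size = effect_size,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    missing_rate = missing_rate,
    noise_signature_size = as.integer(noise_signature_size),
    targets_per_mirna = as.integer(targets_per_mirna),
    exclusive_per_mirna = as.integer(exclusive_per_mirna),
    network_coverage = network_coverage,
    seed = as.integer(seed))
  counts <- cfg[c("n_mirna_datasets", "n_mrna_datasets", "n_features_mirna",
                  "n_genes", "n_normal", "n_tumor", "n_true_active_mirna")]
  if (any(unlist(counts) <= 0L))
    stop("all counts must be positive")
  if (cfg$noise_signature_size < 0L)
    stop("'noise_signature_size' must be >= 0")
  if (!(cfg$activation_fraction > 0 && cfg$activation_fraction <= 1))
    stop("'activation_fraction' must be in (0, 1]")
  if (!(cfg$missing_rate >= 0 && cfg$missing_rate < 1))
    stop("'missing_rate' must be in [0, 1)")
  if (cfg$baseline_sd <= 0) stop("'baseline_sd' must be > 0")
  if (cfg$n_true_active_mirna > cfg$n_features_mirna)
    stop("'n_true_active_mirna' cannot exceed 'n_features_mirna'")
  if (cfg$exclusive_per_mirna > cfg$targets_per_mirna)
    stop("'exclusive_per_mirna' cannot exceed 'targets_per_mirna'")
  if (cfg$targets_per_mirna > cfg$n_genes)
    stop("'targets_per_mirna' cannot exceed 'n_genes'")
  if (!(cfg$network_coverage > 0 && cfg$network_coverage <= 1))
    stop("'network_coverage' must be in (0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic substream seeds: the first k draws are identical for any
# two calls sharing `master`, so adding datasets never perturbs earlier ones.
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate one expression dataset with planted heterogeneous outliers
#'
#' Baseline entries are Gaussian; each planted feature receives an additive
#' shift of `effect_size * baseline_sd` (sign drawn Bernoulli(0.5) per
#' feature) in a random subset of `ceiling(activation_fraction * n_tumor)`
#' tumor samples only — the heterogeneous-activation regime in which
#' classical t-statistics lose power. Entries are then masked missing
#' completely at random at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @param planted Character vector of feature ids to plant (subset of
#'   `feature_ids`).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param feature_ids Feature universe; defaults to
#'   `mir-0001 ... mir-<n_features_mirna>`.
#' @param dataset_id Dataset label.
#'
#' @return A list with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (list with `planted`, per-feature shift `directions`, and
#'   `seed`).
#' @export
simulate_expression_dataset <- function(config, planted, seed,
                                        feature_ids = NULL,
                                        dataset_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(feature_ids))
    feature_ids <- sprintf("mir-%04d", seq_len(config$n_features_mirna))
  if (!all(planted %in% feature_ids))
    stop("'planted' must be a subset of the feature universe")
  if (config$activation_fraction * config$n_tumor < 1)
    stop("no activated samples: activation_fraction * n_tumor < 1")
  n_feat <- length(feature_ids)
  n_s <- config$n_normal + config$n_tumor
  groups <- rep(c("normal", "tumor"), c(config$n_normal, config$n_tumor))
  n_act <- ceiling(config$activation_fraction * config$n_tumor)

  with_seed(seed, {
    values <- matrix(
      stats::rnorm(n_feat * n_s, config$baseline_mean, config$baseline_sd),
      nrow = n_feat,
      dimnames = list(feature_ids,
                      sprintf("%s_s%02d", dataset_id, seq_len(n_s))))
    tumor_idx <- which(groups == "tumor")
    directions <- stats::setNames(integer(0), character(0))
    if (length(planted)) {
      directions <- stats::setNames(
        ifelse(stats::runif(length(planted)) < 0.5, -1L, 1L), planted)
      shift <- config$effect_size * config$baseline_sd
      for (f in planted) {
        act <- sample(tumor_idx, n_act)
        values[f, act] <- values[f, act] + directions[[f]] * shift
      }
    }
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(values)) < config$missing_rate
      values[mask] <- NA_real_
    }
    list(dataset = expression_dataset(values, groups, dataset_id),
         truth = list(planted = planted, directions = directions,
                      seed = seed))
  })
}

#' Simulate a bipartite miRNA-target interaction network
#'
#' Constructs an edge set in which every miRNA has exactly the requested
#' number of targets and of *exclusive* targets (genes targeted by no other
#' miRNA). Non-exclusive target slots are filled cyclically from a shared
#' gene pool sized so that every shared gene acquires degree >= 2, making
#' the exclusivity profile exact by construction. Each edge is labelled
#' with 1-3 evidence sources for target-consolidation tests.
#'
#' @param n_mirna,n_gene Universe sizes.
#' @param targets_total Integer vector (length 1 or `n_mirna`): total
#'   targets per miRNA.
#' @param targets_exclusive Integer vector (length 1 or `n_mirna`):
#'   exclusive targets per miRNA.
#' @param seed Integer seed.
#' @param mirna_ids,gene_ids Optional id vectors.
#' @param source_labels Evidence-source label pool.
#'
#' @return A [target_network()].
#' @export
simulate_target_network <- function(n_mirna, n_gene, targets_total,
                                    targets_exclusive, seed,
                                    mirna_ids = NULL, gene_ids = NULL,
                                    source_labels = c("targetscan", "pictar",
                                                      "miranda",
                                                      "mirecords")) {
  if (is.null(mirna_ids)) mirna_ids <- sprintf("mir-%04d", seq_len(n_mirna))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene-%05d", seq_len(n_gene))
  stopifnot(length(mirna_ids) == n_mirna, length(gene_ids) == n_gene)
  tot <- rep_len(as.integer(targets_total), n_mirna)
  exc <- rep_len(as.integer(targets_exclusive), n_mirna)
  if (any(exc < 0L) || any(tot < exc))
    stop("exclusive target count must be between 0 and the total count")
  if (any(tot > n_gene))
    stop("a miRNA cannot have more targets than there are genes")
  if (sum(exc) > n_gene)
    stop("infeasible exclusivity profile: sum of exclusive targets exceeds ",
         "the gene universe")

  shared <- tot - exc
  total_shared <- sum(shared)
  max_shared <- if (total_shared) max(shared) else 0L
  pool_size <- 0L
  if (total_shared > 0L) {
    # every pool gene must be hit >= 2 times, and a miRNA's consecutive
    # slots must map to distinct genes, so max_shared <= pool <= total/2
    pool_size <- min(total_shared %/% 2L, n_gene - sum(exc))
    if (pool_size < max_shared || pool_size < 1L)
      stop("infeasible exclusivity profile: shared-target slots cannot be ",
           "filled with genes of degree >= 2")
  }

  with_seed(seed, {
    perm_genes <- sample(gene_ids)
    excl_genes <- if (sum(exc)) perm_genes[seq_len(sum(exc))] else character(0)
    pool_genes <- if (pool_size)
      perm_genes[sum(exc) + seq_len(pool_size)] else character(0)

    m_col <- rep(mirna_ids, tot)
    g_col <- character(length(m_col))
    # exclusive slots first (per miRNA), then shared slots cyclic over pool
    excl_slot <- unlist(lapply(seq_len(n_mirna),
                               function(i) rep(c(TRUE, FALSE),
                                               c(exc[i], shared[i]))))
    g_col[excl_slot] <- excl_genes
    if (total_shared)
      g_col[!excl_slot] <- pool_genes[((seq_len(total_shared) - 1L) %%
                                         pool_size) + 1L]
    n_src <- sample(1:3, length(m_col), replace = TRUE)
    sources <- lapply(n_src, function(k) sort(sample(source_labels, k)))
    target_network(data.frame(mirna = m_col, gene = g_col,
                              source = vapply(sources, paste, "",
                                              collapse = ";")),
                   mirnas = mirna_ids, genes = gene_ids)
  })
}

#' Simulate a complete multi-cohort study with planted ground truth
#'
#' Generates `n_mirna_datasets` miRNA expression datasets sharing one core
#' of truly active miRNAs (plus dataset-specific false planted features),
#' a miRNA-target network, and `n_mrna_datasets` mRNA datasets in which the
#' targets of the active miRNAs are deregulated (plus per-dataset noise
#' genes) — so the premise that a regulator's activity is visible in its
#' targets' deregulation holds by construction.
#'
#' @param config A [sim_config()].
#'
#' @return A list of class `sim_study` with elements `mirna_datasets`,
#'   `mrna_datasets`, `network`, `truth` (class `synthetic_truth`) and
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  # independent substream blocks: truth / network / miRNA sets / mRNA sets,
  # so adding datasets of either kind never perturbs existing ones
  roots <- derive_seeds(config$seed, 4L)
  mirna_seeds <- derive_seeds(roots[3L], config$n_mirna_datasets)
  mrna_seeds <- derive_seeds(roots[4L], config$n_mrna_datasets)
  mirna_ids <- sprintf("mir-%04d", seq_len(config$n_features_mirna))
  gene_ids <- sprintf("gene-%05d", seq_len(config$n_genes))

  n_cov <- max(config$n_true_active_mirna,
               ceiling(config$network_coverage * config$n_features_mirna))
  sel <- with_seed(roots[1L], {
    active <- sort(sample(mirna_ids, config$n_true_active_mirna))
    covered <- sort(c(active, sample(setdiff(mirna_ids, active),
                                     n_cov - length(active))))
    list(active = active, covered = covered)
  })
  active <- sel$active
  network <- simulate_target_network(
    length(sel$covered), config$n_genes,
    targets_total = config$targets_per_mirna,
    targets_exclusive = config$exclusive_per_mirna,
    seed = roots[2L], mirna_ids = sel$covered, gene_ids = gene_ids)

  active_targets <- sort(unique(
    network$edges$gene[network$edges$mirna %in% active]))

  mirna_datasets <- vector("list", config$n_mirna_datasets)
  planted_mirna <- vector("list", config$n_mirna_datasets)
  for (i in seq_len(config$n_mirna_datasets)) {
    sd_i <- mirna_seeds[i]
    id <- sprintf("mirna_ds%d", i)
    noise <- with_seed(sd_i + 1L, sample(setdiff(mirna_ids, active),
                                         config$noise_signature_size))
    planted <- sort(c(active, noise))
    sim <- simulate_expression_dataset(config, planted, sd_i,
                                       feature_ids = mirna_ids,
                                       dataset_id = id)
    mirna_datasets[[i]] <- sim$dataset
    planted_mirna[[i]] <- planted
    names(mirna_datasets)[i] <- names(planted_mirna)[i] <- id
  }

  mrna_datasets <- vector("list", config$n_mrna_datasets)
  planted_genes <- vector("list", config$n_mrna_datasets)
  for (j in seq_len(config$n_mrna_datasets)) {
    sd_j <- mrna_seeds[j]
    id <- sprintf("mrna_ds%d", j)
    noise <- with_seed(sd_j + 1L, sample(setdiff(gene_ids, active_targets),
                                         config$noise_signature_size))
    planted <- sort(c(active_targets, noise))
    sim <- simulate_expression_dataset(config, planted, sd_j,
                                       feature_ids = gene_ids,
                                       dataset_id = id)
    mrna_datasets[[j]] <- sim$dataset
    planted_genes[[j]] <- planted
    names(mrna_datasets)[j] <- names(planted_genes)[j] <- id
  }

  truth <- structure(
    list(active_mirnas = active,
         planted_mirna_features = planted_mirna,
         planted_dereg_genes = planted_genes,
         active_targets = active_targets,
         seed = config$seed),
    class = "synthetic_truth")
  structure(list(mirna_datasets = mirna_datasets,
                 mrna_datasets = mrna_datasets,
                 network = network, truth = truth, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(paste0("sim_study: %d miRNA datasets, %d mRNA datasets, ",
                     "%d network edges, %d active miRNAs (seed %d)\n"),
              length(x$mirna_datasets), length(x$mrna_datasets),
              nrow(x$network$edges), length(x$truth$active_mirnas),
              x$config$seed))
  invisible(x)
}
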