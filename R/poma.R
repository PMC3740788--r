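#' Bipartite miRNA-target interaction network
#'
#' @param edges Data frame with columns `mirna`, `gene` and optionally
#'   `source` (evidence labels, `;`-separated within a row). Duplicate
#'   (mirna, gene) pairs are collapsed with their source sets merged.
#' @param mirnas,genes Optional universes; default to the ids present in
#'   `edges`.
#'
#' @return A list of class `target_network` with elements `edges` (one row
#'   per unique pair, `source` a `;`-joined sorted label set), `mirnas`,
#'   `genes`.
#' @export
target_network <- function(edges, mirnas = NULL, genes = NULL) {
  if (!is.data.frame(edges) || !all(c("mirna", "gene") %in% names(edges)))
    stop("'edges' must be a data frame with columns mirna, gene")
  if (is.null(edges$source)) edges$source <- "unknown"
  bad <- which(is.na(edges$mirna) | is.na(edges$gene) |
                 edges$mirna == "" | edges$gene == "")
  if (length(bad))
    stop("malformed edge row(s): ", paste(bad, collapse = ", "))
  key <- paste(edges$mirna, edges$gene, sep = "\r")
  if (anyDuplicated(key)) {
    src <- split(edges$source, key)
    first <- !duplicated(key)
    merged <- vapply(src, function(s)
      paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))),
            collapse = ";"), "")
    edges <- edges[first, , drop = FALSE]
    edges$source <- merged[paste(edges$mirna, edges$gene, sep = "\r")]
  } else {
    edges$source <- vapply(strsplit(edges$source, ";", fixed = TRUE),
                           function(s) paste(sort(unique(s)),
                                             collapse = ";"), "")
  }
  rownames(edges) <- NULL
  if (is.null(mirnas)) mirnas <- sort(unique(edges$mirna))
  if (is.null(genes)) genes <- sort(unique(edges$gene))
  if (!all(edges$mirna %in% mirnas) || !all(edges$gene %in% genes))
    stop("edge endpoint(s) outside the declared universes")
  structure(list(edges = edges[c("mirna", "gene", "source")],
                 mirnas = mirnas, genes = genes),
            class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  cat(sprintf("target_network: %d edges, %d miRNAs, %d genes\n",
              nrow(x$edges), length(x$mirnas), length(x$genes)))
  invisible(x)
}

#' Assemble an interaction network from several edge tables
#'
#' Takes the union of edge lists from multiple interaction databases
#' (experimentally validated and computationally predicted sources alike),
#' merging evidence-source sets on duplicate pairs.
#'
#' @param edge_tables Non-empty list of data frames with columns `mirna`,
#'   `gene`, `source`.
#' @return A [target_network()].
#' @export
build_network <- function(edge_tables) {
  if (!is.list(edge_tables) || !length(edge_tables))
    stop("'edge_tables' must be a non-empty list of edge data frames")
  if (is.data.frame(edge_tables)) edge_tables <- list(edge_tables)
  all_edges <- do.call(rbind, lapply(edge_tables, function(t) {
    if (!all(c("mirna", "gene", "source") %in% names(t)))
      stop("edge table lacks mirna/gene/source columns")
    t[c("mirna", "gene", "source")]
  }))
  if (!nrow(all_edges)) stop("no edges supplied")
  target_network(all_edges)
}

#' Deregulated genes of one mRNA dataset
#'
#' Top-fraction outlier genes detected with MOST (two-sided), the
#' dataset-level input to the regulatory-activity filter.
#'
#' @param mrna_data Preprocessed [expression_dataset()].
#' @param selection_fraction Top fraction (default 0.05).
#' @param ... Passed to [score_dataset()].
#' @return Sorted character vector of deregulated gene ids.
#' @export
dereg_genes <- function(mrna_data, selection_fraction = 0.05, ...) {
  sort(selected_features(score_dataset(mrna_data, method = "MOST",
                                       selection_fraction =
                                         selection_fraction, ...)))
}

#' Disease-specific subnetwork
#'
#' Restricts an interaction network to edges whose gene endpoint is
#' deregulated; miRNAs left without edges are dropped from the miRNA
#' universe.
#'
#' @param network A [target_network()].
#' @param dereg Character vector of deregulated gene ids.
#' @return A [target_network()] over the deregulated genes.
#' @export
build_subnetwork <- function(network, dereg) {
  stopifnot(inherits(network, "target_network"))
  keep <- network$edges$gene %in% dereg
  edges <- network$edges[keep, , drop = FALSE]
  if (!nrow(edges)) {
    warning("empty subnetwork: no network gene is deregulated")
    return(structure(list(edges = edges, mirnas = character(0),
                          genes = character(0)),
                     class = "target_network"))
  }
  target_network(edges)
}

#' Regulatory-activity score Z = alpha / beta
#'
#' Within the disease-specific subnetwork, for each miRNA: `beta` is the
#' number of deregulated genes it targets and `alpha` the number of those
#' targeted by no other miRNA (subnetwork gene degree exactly 1). The
#' score `z = alpha / beta` measures how exclusively the miRNA controls
#' its deregulated targets; records with `alpha < 2` or `beta < 2` are
#' marked ineligible.
#'
#' @param sub A [target_network()] restricted to deregulated genes (see
#'   [build_subnetwork()]).
#' @return Data frame of class `z_records` with columns `mirna`, `alpha`,
#'   `beta`, `z`, `eligible`, sorted by decreasing `z` then miRNA id.
#' @export
compute_z <- function(sub) {
  stopifnot(inherits(sub, "target_network"))
  if (!nrow(sub$edges)) {
    out <- data.frame(mirna = character(0), alpha = integer(0),
                      beta = integer(0), z = numeric(0),
                      eligible = logical(0))
    class(out) <- c("z_records", "data.frame")
    return(out)
  }
  deg <- table(sub$edges$gene)  # subnetwork degree on the gene side
  by_mirna <- split(sub$edges$gene, sub$edges$mirna)
  beta <- vapply(by_mirna, length, 0L)
  alpha <- vapply(by_mirna, function(g) sum(deg[g] == 1L), 0L)
  z <- ifelse(beta > 0L, alpha / beta, NA_real_)
  out <- data.frame(mirna = names(by_mirna), alpha = as.integer(alpha),
                    beta = as.integer(beta), z = z,
                    eligible = alpha >= 2L & beta >= 2L,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$z, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("z_records", "data.frame")
  out
}

#' Active miRNAs of one mRNA dataset
#'
#' Eligible miRNAs (alpha >= 2 and beta >= 2) whose regulatory-activity
#' score reaches the threshold (inclusive comparison, default 0.1).
#'
#' @param zrecords A `z_records` table from [compute_z()].
#' @param z_threshold Activity threshold (default 0.1).
#' @return Sorted character vector of active miRNA ids.
#' @export
active_mirnas <- function(zrecords, z_threshold = 0.1) {
  stopifnot(inherits(zrecords, "z_records"))
  if (!(z_threshold > 0 && z_threshold <= 1))
    stop("'z_threshold' must be in (0, 1]")
  sort(zrecords$mirna[zrecords$eligible & zrecords$z >= z_threshold])
}

#' Cross-dataset consensus of active miRNAs
#'
#' miRNAs called active in at least `min_datasets` of the per-mRNA-dataset
#' active lists. The strict rule uses 3 of 4; a relaxed variant with
#' `min_datasets = 2` broadens the filter to admit less consistently
#' supported regulators.
#'
#' @param per_dataset_active List of character vectors (one per mRNA
#'   dataset).
#' @param min_datasets Minimum number of supporting datasets (default 3).
#' @return Sorted character vector of consensus-active miRNA ids.
#' @export
active_consensus <- function(per_dataset_active, min_datasets = 3L) {
  stopifnot(is.list(per_dataset_active))
  if (length(per_dataset_active) < min_datasets)
    stop("fewer lists than 'min_datasets'")
  tab <- table(unlist(lapply(per_dataset_active, unique)))
  sort(names(tab)[tab >= min_datasets])
}

#' Cross-match active miRNAs with a differential-expression list
#'
#' Intersection of the consensus-active set with one miRNA dataset's
#' differential (outlier) list — the filtration step that removes
#' differential miRNAs lacking regulatory activity.
#'
#' @param active Character vector of consensus-active miRNA ids.
#' @param de_list Character vector of differential miRNA ids.
#' @return Sorted intersection.
#' @export
cross_match <- function(active, de_list) {
  sort(intersect(active, de_list))
}

#' Final consensus signature across miRNA datasets
#'
#' miRNAs present in at least `min_support` of the filtered per-dataset
#' lists, with their support counts.
#'
#' @param filtered_lists List of character vectors (one filtered
#'   differential list per miRNA dataset).
#' @param min_support Minimum number of supporting datasets (default 4).
#' @return Data frame with columns `mirna`, `support`, sorted by
#'   decreasing support then id.
#' @export
final_signature <- function(filtered_lists, min_support = 4L) {
  stopifnot(is.list(filtered_lists))
  if (length(filtered_lists) < min_support)
    stop("fewer lists than 'min_support'")
  tab <- table(unlist(lapply(filtered_lists, unique)))
  keep <- tab[tab >= min_support]
  out <- data.frame(mirna = if (length(keep)) names(keep) else character(0),
                    support = as.integer(keep),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
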