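#' Consolidate predicted targets across evidence sources
#'
#' Removes low-confidence targets supported by only one prediction
#' program: per miRNA, a gene is retained when it appears in at least
#' `min_sources` sources. Genes reported by a source flagged as
#' experimental (e.g. a curated validation database) are retained
#' regardless, since experimental evidence is not a prediction vote —
#' switch off by passing `experimental_sources = character(0)`.
#'
#' @param per_source_targets Named list: source name -> (named list:
#'   miRNA id -> character vector of target gene ids).
#' @param min_sources Minimum number of supporting sources (default 2).
#' @param experimental_sources Names of sources whose targets bypass the
#'   vote (must be a subset of `names(per_source_targets)`).
#'
#' @return Named list: miRNA id -> sorted character vector of consolidated
#'   target gene ids (miRNAs with no surviving targets are dropped).
#' @export
consolidate_targets <- function(per_source_targets, min_sources = 2L,
                                experimental_sources = character(0)) {
  if (!is.list(per_source_targets) || length(per_source_targets) < 2L)
    stop("need target tables from at least 2 sources")
  if (is.null(names(per_source_targets)) ||
      any(names(per_source_targets) == ""))
    stop("'per_source_targets' must be a named list (source names)")
  unknown <- setdiff(experimental_sources, names(per_source_targets))
  if (length(unknown))
    stop("unknown experimental source(s): ", paste(unknown, collapse = ", "))
  mirnas <- sort(unique(unlist(lapply(per_source_targets, names))))
  out <- list()
  for (m in mirnas) {
    hits <- lapply(per_source_targets, function(src) unique(src[[m]]))
    votes <- table(unlist(hits))
    keep <- names(votes)[votes >= min_sources]
    exp_hits <- unique(unlist(hits[experimental_sources]))
    keep <- sort(union(keep, exp_hits))
    if (length(keep)) out[[m]] <- keep
  }
  out
}

#' Gene-set collection
#'
#' @param sets Named list of non-empty character vectors (gene ids).
#' @param universe Background gene universe; defaults to the union of all
#'   sets. Sets are restricted to the universe.
#' @return List of class `gene_set_collection` with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (!is.list(sets) || !length(sets) || is.null(names(sets)) ||
      any(names(sets) == ""))
    stop("'sets' must be a non-empty named list")
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  universe <- sort(unique(as.character(universe)))
  if (!length(universe)) stop("empty universe")
  sets <- lapply(sets, intersect, universe)
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop("gene set(s) empty after restriction to the universe: ",
         paste(empty, collapse = ", "))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, tests over-representation of the query genes with the
#' exact hypergeometric upper tail P(X >= k), where k is the number of
#' query genes in the set, K the set size, n the query size and N the
#' universe size; p-values are adjusted across the collection with the
#' Benjamini-Hochberg step-up procedure.
#'
#' @param query Character vector of gene ids; genes outside the universe
#'   are dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @return Data frame with columns `set_name`, `k`, `K`, `n`, `N`, `ratio`
#'   (k/K), `p`, `fdr`, sorted by increasing `p` then set name.
#' @export
hypergeom_enrich <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, collection$universe)
  }
  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N,
               ratio = k / K, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Disease-relevance screen of enriched pathways
#'
#' Flags pathways that are both highly saturated with disease-related
#' members (enrichment ratio strictly above `ratio_min`) and strongly
#' significant (p strictly below `p_max`), and emits the volcano-plot
#' coordinates (ratio, -log10 p).
#'
#' @param rows Data frame with columns `pathway`, `hits`, `size`, `p`.
#' @param ratio_min Ratio cutoff, exclusive (default 0.15).
#' @param p_max P-value cutoff, exclusive (default 1e-4).
#' @return The input with added columns `ratio`, `neg_log10_p`, `flagged`.
#' @export
relevance_screen <- function(rows, ratio_min = 0.15, p_max = 1e-4) {
  if (!is.data.frame(rows) ||
      !all(c("pathway", "hits", "size", "p") %in% names(rows)))
    stop("'rows' must have columns pathway, hits, size, p")
  if (any(rows$hits > rows$size))
    stop("'hits' cannot exceed 'size'")
  rows$ratio <- rows$hits / rows$size
  rows$neg_log10_p <- -log10(rows$p)
  rows$flagged <- rows$ratio > ratio_min & rows$p < p_max
  rows
}
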