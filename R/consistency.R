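#' Overlap percentage between two id sets
#'
#' @param a,b Character vectors (id sets); not both empty.
#' @param mode `"jaccard"` (default): |A.B| / |A+B|; `"min"`:
#'   |A.B| / min(|A|, |B|).
#' @return A number in [0, 1].
#' @export
overlap_percentage <- function(a, b, mode = c("jaccard", "min")) {
  mode <- match.arg(mode)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!length(a) && !length(b))
    stop("both sets are empty; overlap undefined")
  inter <- length(intersect(a, b))
  denom <- switch(mode,
                  jaccard = length(union(a, b)),
                  min = min(length(a), length(b)))
  if (denom == 0L) return(0)  # min mode with one empty set
  inter / denom
}

#' Pairwise overlap across datasets
#'
#' Overlap percentage for every unordered pair of dataset-level id sets
#' (C(5,2) = 10 pairs for five datasets).
#'
#' @param lists Named list of character vectors, one per dataset (>= 2).
#' @param mode Overlap mode, see [overlap_percentage()].
#' @param level Optional label for the observation level (miRNA, target,
#'   pathway, ...).
#' @return Data frame of class `overlap_report` with columns `a`, `b`,
#'   `overlap`; attributes `mode`, `level`, `mean`, `median`.
#' @export
pairwise_overlap <- function(lists, mode = c("jaccard", "min"),
                             level = "miRNA") {
  mode <- match.arg(mode)
  if (!is.list(lists) || length(lists) < 2L)
    stop("need at least 2 dataset lists")
  if (is.null(names(lists)))
    names(lists) <- paste0("ds", seq_along(lists))
  pairs <- utils::combn(names(lists), 2L)
  ov <- apply(pairs, 2L, function(p)
    overlap_percentage(lists[[p[1L]]], lists[[p[2L]]], mode = mode))
  out <- data.frame(a = pairs[1L, ], b = pairs[2L, ], overlap = ov,
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "level") <- level
  attr(out, "mean") <- mean(ov)
  attr(out, "median") <- stats::median(ov)
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' Paired t-test on before/after overlap percentages
#'
#' Classical paired t on the differences `after - before`, two-sided p
#' from the t distribution with n - 1 degrees of freedom.
#'
#' @param before,after Equal-length numeric vectors (>= 2) of per-pair
#'   overlap percentages.
#' @return List with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(before, after) {
  if (length(before) != length(after) || length(before) < 2L)
    stop("'before' and 'after' must have equal length >= 2")
  d <- after - before
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    stop("zero variance of paired differences; t undefined")
  n <- length(d)
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1L), df = n - 1L,
       mean_diff = mean(d))
}

#' Multi-level consistency report
#'
#' Pairwise overlap reports at several observation levels (differential
#' miRNA, consolidated target genes, enriched functional categories, ...),
#' plus a cross-level summary table.
#'
#' @param sets_by_level Named list: level name -> (named list of
#'   per-dataset id sets).
#' @param mode Overlap mode.
#' @return List of class `level_report`: `reports` (one `overlap_report`
#'   per level) and `summary` (data frame level/mean/median).
#' @export
level_report <- function(sets_by_level, mode = c("jaccard", "min")) {
  mode <- match.arg(mode)
  if (!is.list(sets_by_level) || is.null(names(sets_by_level)))
    stop("'sets_by_level' must be a named list of per-level set lists")
  missing_lvl <- names(sets_by_level)[!vapply(sets_by_level, is.list, TRUE)]
  if (length(missing_lvl))
    stop("missing per-dataset sets for level(s): ",
         paste(missing_lvl, collapse = ", "))
  reports <- lapply(names(sets_by_level), function(lvl)
    pairwise_overlap(sets_by_level[[lvl]], mode = mode, level = lvl))
  names(reports) <- names(sets_by_level)
  summary <- data.frame(
    level = names(reports),
    mean = vapply(reports, function(r) attr(r, "mean"), 0),
    median = vapply(reports, function(r) attr(r, "median"), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(reports = reports, summary = summary, mode = mode),
            class = "level_report")
}

#' @export
print.level_report <- function(x, ...) {
  cat("Cross-dataset overlap by level (mode =", x$mode, "):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
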