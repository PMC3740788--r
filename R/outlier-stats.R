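#' Outlier detection statistics for heterogeneous differential expression
#'
#' Five per-feature statistics designed for the regime where a feature is
#' shifted in only a subset of tumor samples: the classical pooled-variance
#' two-sample t, COPA (percentile of median/MAD-standardized tumor values),
#' OS (outlier sum above an IQR cutoff on all samples), ORT (outlier sum
#' with cutoff and centering from the normal group and a pooled robust
#' scale) and MOST (maximum ordered-subset t, standardized by null
#' order-statistic moments). All robust scales use the median absolute
#' deviation with the 1.4826 normal-consistency factor; quantiles use the
#' linear-interpolation definition (R type 7). Each function returns `NA`
#' when its scale estimate degenerates to zero (the feature is then flagged
#' undefined and ranked last by [score_dataset()]).
#'
#' @param x Numeric vector of one feature's values across samples (`NA`
#'   allowed; dropped).
#' @param is_tumor Logical vector, `TRUE` for tumor samples.
#' @param welch Use the Welch (unequal-variance) t instead of the pooled
#'   form.
#' @param r COPA percentile in (0, 100], default 90.
#' @param null_table A [most_null_moments()] table whose `n_tumor` equals
#'   the number of observed tumor values.
#'
#' @return A single numeric statistic (sign of t = tumor mean - normal
#'   mean), or `NA_real_` when undefined.
#' @name outlier_statistics
NULL

MAD_CONST <- 1.4826

obs_split <- function(x, is_tumor) {
  ok <- !is.na(x)
  list(normal = x[ok & !is_tumor], tumor = x[ok & is_tumor],
       all = x[ok])
}

#' @rdname outlier_statistics
#' @export
stat_t <- function(x, is_tumor, welch = FALSE) {
  s <- obs_split(x, is_tumor)
  n1 <- length(s$normal); n2 <- length(s$tumor)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  m1 <- mean(s$normal); m2 <- mean(s$tumor)
  v1 <- stats::var(s$normal); v2 <- stats::var(s$tumor)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  if (se == 0) return(NA_real_)
  (m2 - m1) / se
}

#' @rdname outlier_statistics
#' @export
stat_copa <- function(x, is_tumor, r = 90) {
  s <- obs_split(x, is_tumor)
  if (!length(s$tumor)) return(NA_real_)
  med <- stats::median(s$all)
  scale <- MAD_CONST * stats::median(abs(s$all - med))
  if (scale == 0) return(NA_real_)
  z_t <- (s$tumor - med) / scale
  stats::quantile(z_t, probs = r / 100, names = FALSE, type = 7)
}

#' @rdname outlier_statistics
#' @export
stat_os <- function(x, is_tumor) {
  s <- obs_split(x, is_tumor)
  if (!length(s$tumor)) return(NA_real_)
  med <- stats::median(s$all)
  scale <- MAD_CONST * stats::median(abs(s$all - med))
  if (scale == 0) return(NA_real_)
  z <- (s$all - med) / scale
  q <- stats::quantile(z, probs = c(0.25, 0.75), names = FALSE, type = 7)
  cutoff <- q[2L] + (q[2L] - q[1L])
  z_t <- (s$tumor - med) / scale
  sum(z_t[z_t > cutoff])
}

#' @rdname outlier_statistics
#' @export
stat_ort <- function(x, is_tumor) {
  s <- obs_split(x, is_tumor)
  if (length(s$normal) < 2L || !length(s$tumor)) return(NA_real_)
  med_n <- stats::median(s$normal)
  med_t <- stats::median(s$tumor)
  resid <- c(abs(s$normal - med_n), abs(s$tumor - med_t))
  scale <- MAD_CONST * stats::median(resid)
  if (scale == 0) return(NA_real_)
  q <- stats::quantile(s$normal, probs = c(0.25, 0.75), names = FALSE,
                       type = 7)
  cutoff <- q[2L] + (q[2L] - q[1L])
  o <- s$tumor[s$tumor > cutoff]
  if (!length(o)) return(0)
  sum(o - med_n) / scale
}

#' Monte Carlo null moments for the MOST statistic
#'
#' For k = 1..n_tumor, estimates the mean `mu_k` and standard deviation
#' `sigma_k` of the sum of the k largest order statistics of `n_tumor`
#' independent standard normals, from `B` Monte Carlo replicates. Results
#' are cached per (n_tumor, B, seed) within the session. Note `mu_k` rises
#' while the added order statistics have positive expectation and falls
#' back to `mu_n = 0` (symmetry) as k approaches n_tumor.
#'
#' @param n_tumor Number of tumor samples (>= 1).
#' @param B Number of Monte Carlo replicates (>= 1000; default 20000).
#' @param seed RNG seed for the table (default fixed so all analyses share
#'   one null reference).
#'
#' @return A list of class `most_null_table` with `n_tumor`, `mu`, `sigma`
#'   (length-n_tumor vectors), `B`, `seed`.
#' @export
most_null_moments <- function(n_tumor, B = 20000L, seed = 20130710L) {
  n_tumor <- as.integer(n_tumor)
  if (n_tumor < 1L) stop("'n_tumor' must be >= 1")
  if (B < 1000L) stop("'B' must be >= 1000")
  key <- sprintf("n%d_B%d_s%d", n_tumor, B, seed)
  cached <- .most_null_cache[[key]]
  if (!is.null(cached)) return(cached)
  tab <- with_seed(seed, {
    draws <- matrix(stats::rnorm(B * n_tumor), nrow = B)
    sums <- t(apply(draws, 1L, function(r)
      cumsum(sort(r, decreasing = TRUE))))
    if (n_tumor == 1L) sums <- matrix(sums, ncol = 1L)
    list(n_tumor = n_tumor, mu = colMeans(sums),
         sigma = apply(sums, 2L, stats::sd), B = as.integer(B),
         seed = as.integer(seed))
  })
  class(tab) <- "most_null_table"
  .most_null_cache[[key]] <- tab
  tab
}

.most_null_cache <- new.env(parent = emptyenv())

#' @rdname outlier_statistics
#' @export
stat_most <- function(x, is_tumor, null_table) {
  s <- obs_split(x, is_tumor)
  if (!length(s$tumor) || length(s$normal) < 2L) return(NA_real_)
  if (!inherits(null_table, "most_null_table") ||
      null_table$n_tumor != length(s$tumor))
    stop("'null_table' does not match the number of observed tumor values")
  med_n <- stats::median(s$normal)
  scale <- MAD_CONST * stats::median(abs(s$normal - med_n))
  if (scale == 0) return(NA_real_)
  z <- sort((s$tumor - med_n) / scale, decreasing = TRUE)
  m <- cumsum(z)
  max((m - null_table$mu) / null_table$sigma)
}

#' Score every feature of a dataset with one outlier statistic
#'
#' Applies the chosen statistic to each feature on both tails (original and
#' sign-flipped values), keeps the larger score with its direction, ranks
#' features by decreasing score (undefined scores last; ties broken by
#' feature id) and selects the top `ceiling(selection_fraction * n)` as
#' differential candidates.
#'
#' @param data A preprocessed [expression_dataset()] with >= 2 samples per
#'   group.
#' @param method One of `"t"`, `"COPA"`, `"OS"`, `"ORT"`, `"MOST"`.
#' @param selection_fraction Top fraction selected (default 0.05).
#' @param copa_r COPA percentile (default 90).
#' @param two_sided Score both tails (default `TRUE`); otherwise the up
#'   tail only.
#' @param null_B,null_seed Monte Carlo settings for the MOST null table.
#'
#' @return A data frame of class `outlier_scores` with columns
#'   `feature_id`, `statistic`, `direction` (`"up"`/`"down"`), `rank`,
#'   `selected`, and attributes `dataset_id`, `method`,
#'   `selection_fraction`. Rows are in rank order.
#' @export
score_dataset <- function(data, method = c("t", "COPA", "OS", "ORT", "MOST"),
                          selection_fraction = 0.05, copa_r = 90,
                          two_sided = TRUE, null_B = 20000L,
                          null_seed = 20130710L) {
  stopifnot(inherits(data, "expr_dataset"))
  method <- match.arg(method)
  if (!(selection_fraction > 0 && selection_fraction < 1))
    stop("'selection_fraction' must be in (0, 1)")
  assert_two_groups(data)
  is_tumor <- data$groups == "tumor"
  v <- data$values

  fun <- switch(method,
    t = function(x) stat_t(x, is_tumor),
    COPA = function(x) stat_copa(x, is_tumor, r = copa_r),
    OS = function(x) stat_os(x, is_tumor),
    ORT = function(x) stat_ort(x, is_tumor),
    MOST = local({
      # one null table per distinct count of observed tumor values
      counts <- apply(v[, is_tumor, drop = FALSE], 1L,
                      function(x) sum(!is.na(x)))
      tabs <- lapply(unique(counts[counts >= 1L]), most_null_moments,
                     B = null_B, seed = null_seed)
      names(tabs) <- vapply(tabs, function(t) as.character(t$n_tumor), "")
      function(x) {
        nt <- sum(!is.na(x[is_tumor]))
        if (nt < 1L) return(NA_real_)
        stat_most(x, is_tumor, tabs[[as.character(nt)]])
      }
    }))

  up <- apply(v, 1L, fun)
  if (two_sided) {
    down <- apply(-v, 1L, fun)
    if (method == "t") down <- -up  # antisymmetric; avoid recomputation
    stat <- pmax(up, down, na.rm = FALSE)
    undef <- is.na(up) | is.na(down)
    direction <- ifelse(!undef & down > up, "down", "up")
    stat[undef] <- NA_real_
  } else {
    stat <- up
    direction <- rep("up", length(up))
    undef <- is.na(up)
  }

  ids <- rownames(v)
  sort_key <- ifelse(is.na(stat), 0, -stat)  # undefined last, ties by id
  ord <- order(is.na(stat), sort_key, ids)
  n <- length(ids)
  n_sel <- ceiling(selection_fraction * n)
  res <- data.frame(feature_id = ids[ord], statistic = stat[ord],
                    direction = direction[ord], rank = seq_len(n),
                    selected = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  res$selected <- res$rank <= n_sel & !is.na(res$statistic)
  attr(res, "dataset_id") <- data$dataset_id
  attr(res, "method") <- method
  attr(res, "selection_fraction") <- selection_fraction
  class(res) <- c("outlier_scores", "data.frame")
  res
}

#' Selected feature ids of a score table
#' @param scores An `outlier_scores` table from [score_dataset()].
#' @return Character vector of selected feature ids.
#' @export
selected_features <- function(scores) {
  scores$feature_id[scores$selected]
}

#' Consensus putative differential features across methods
#'
#' Features selected by at least `min_methods` of the supplied score
#' tables (all tables must come from the same feature universe).
#'
#' @param score_tables List of `outlier_scores` tables (one per method).
#' @param min_methods Minimum number of selecting methods (default 3).
#' @return Sorted character vector of putative differential feature ids.
#' @export
consensus_putative <- function(score_tables, min_methods = 3L) {
  stopifnot(length(score_tables) >= 1L)
  universes <- lapply(score_tables, function(t) sort(t$feature_id))
  if (!all(vapply(universes, identical, TRUE, universes[[1L]])))
    stop("score tables cover different feature universes")
  sel <- unlist(lapply(score_tables, selected_features))
  tab <- table(sel)
  sort(names(tab)[tab >= min_methods])
}

#' Consensus-based accuracy benchmark of the five statistics
#'
#' For each dataset, every method's top-fraction selection is compared with
#' the putative differential set (features selected by >= `min_methods`
#' methods); the per-method proportion of putative features in its own
#' selection is computed, and the method's accuracy is the median of this
#' proportion across datasets.
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param methods Methods to benchmark (default all five).
#' @param selection_fraction Top fraction per method (default 0.05).
#' @param min_methods Consensus threshold defining the putative set
#'   (default 3).
#' @param ... Passed to [score_dataset()].
#'
#' @return A list of class `method_benchmark`: `proportions` (dataset x
#'   method matrix), `accuracy` (named vector of per-method medians),
#'   `putative` (list of putative sets per dataset).
#' @export
method_accuracy <- function(datasets,
                            methods = c("t", "COPA", "OS", "ORT", "MOST"),
                            selection_fraction = 0.05, min_methods = 3L,
                            ...) {
  stopifnot(length(datasets) >= 1L)
  props <- matrix(NA_real_, length(datasets), length(methods),
                  dimnames = list(
                    vapply(datasets, function(d) d$dataset_id, ""),
                    methods))
  putative <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    tables <- lapply(methods, function(m)
      score_dataset(datasets[[i]], method = m,
                    selection_fraction = selection_fraction, ...))
    put <- consensus_putative(tables, min_methods = min_methods)
    putative[[i]] <- put
    for (j in seq_along(methods)) {
      sel <- selected_features(tables[[j]])
      if (!length(sel)) {
        warning(sprintf("method %s selected nothing in dataset %s",
                        methods[j], datasets[[i]]$dataset_id))
        next
      }
      props[i, j] <- length(intersect(sel, put)) / length(sel)
    }
  }
  acc <- apply(props, 2L, stats::median, na.rm = TRUE)
  structure(list(proportions = props, accuracy = acc, putative = putative),
            class = "method_benchmark")
}

#' @export
print.method_benchmark <- function(x, ...) {
  cat("Consensus accuracy benchmark (median across",
      nrow(x$proportions), "dataset(s)):\n")
  print(round(x$accuracy, 3))
  invisible(x)
}
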