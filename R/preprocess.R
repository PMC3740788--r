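#' Normexp background correction
#'
#' Corrects raw intensities under the convolution model X = B + S with
#' Gaussian background B ~ N(mu, sigma^2) and exponential signal
#' S ~ Exp(mean alpha). Each observed x is replaced by the posterior mean
#' E[S | X = x] (plus `offset`), which is strictly positive and monotone
#' increasing in x. Parameter fitting and the posterior-mean evaluation are
#' delegated to \pkg{limma} (maximum-likelihood fit per sample).
#'
#' @param data An [expression_dataset()] of raw intensities (missing values
#'   allowed; they are left missing).
#' @param params Either the string `"estimate"` (default; per-sample MLE,
#'   requires >= 50 observed values per sample) or a list with numeric
#'   elements `mu`, `sigma` (> 0) and `alpha` (> 0) applied to every sample.
#' @param offset Constant added after correction (default 0).
#'
#' @return An `expr_dataset` of background-corrected intensities.
#' @export
normexp_correct <- function(data, params = "estimate", offset = 0) {
  stopifnot(inherits(data, "expr_dataset"))
  v <- data$values
  if (any(!is.finite(v) & !is.na(v)))
    stop("non-finite intensities in input")
  out <- v
  for (j in seq_len(ncol(v))) {
    obs <- which(!is.na(v[, j]))
    x <- v[obs, j]
    if (identical(params, "estimate")) {
      if (length(x) < 50L)
        stop(sprintf("sample '%s' has fewer than 50 observed values; %s",
                     colnames(v)[j], "cannot estimate normexp parameters"))
      par <- tryCatch(limma::normexp.fit(x, method = "mle")$par,
                      error = function(e)
                        stop(sprintf(
                          "normexp estimation failed for sample '%s': %s",
                          colnames(v)[j], conditionMessage(e)),
                          call. = FALSE))
    } else {
      if (!is.list(params) ||
          !all(c("mu", "sigma", "alpha") %in% names(params)))
        stop("'params' must be \"estimate\" or a list(mu, sigma, alpha)")
      if (params$sigma <= 0 || params$alpha <= 0)
        stop("'sigma' and 'alpha' must be > 0")
      par <- c(params$mu, log(params$sigma), log(params$alpha))
    }
    out[obs, j] <- limma::normexp.signal(par, x) + offset
  }
  expression_dataset(out, data$groups, data$dataset_id)
}

#' Estimate normexp convolution parameters for one sample
#'
#' Maximum-likelihood fit of the normal-plus-exponential model to a vector
#' of raw intensities.
#'
#' @param x Numeric vector of intensities (>= 50 values).
#' @return A list with elements `mu`, `sigma`, `alpha`.
#' @export
estimate_normexp_params <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 50L) stop("need at least 50 observed values")
  par <- limma::normexp.fit(x, method = "mle")$par
  list(mu = par[1L], sigma = exp(par[2L]), alpha = exp(par[3L]))
}

#' Quantile normalization
#'
#' Forces every sample (column) to share one empirical distribution: the
#' across-column mean of sorted values. On complete data each column's
#' sorted values equal this reference exactly and the operation is
#' idempotent. Missing entries are excluded from the reference and left
#' missing; a column with m < n observed values is mapped onto the
#' reference by linear interpolation at its m ordinal quantiles. Ties take
#' stable first-occurrence ranks, so the result is deterministic.
#'
#' @param data An [expression_dataset()] with >= 2 samples; every column
#'   must have >= 2 observed values.
#' @return The normalized `expr_dataset`.
#' @export
quantile_normalize <- function(data) {
  stopifnot(inherits(data, "expr_dataset"))
  v <- data$values
  if (ncol(v) < 2L) stop("quantile normalization needs >= 2 samples")
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 2L))
    stop("column(s) with fewer than 2 observed values: ",
         paste(colnames(v)[n_obs < 2L], collapse = ", "))
  n <- nrow(v)
  grid <- seq(0, 1, length.out = n)
  # reference: mean over columns of the sorted observed values, each column
  # interpolated onto a common grid of n quantiles
  qs <- vapply(seq_len(ncol(v)), function(j) {
    stats::quantile(v[, j], probs = grid, na.rm = TRUE, names = FALSE,
                    type = 7)
  }, numeric(n))
  ref <- rowMeans(qs)
  out <- v
  for (j in seq_len(ncol(v))) {
    obs <- which(!is.na(v[, j]))
    m <- length(obs)
    r <- rank(v[obs, j], ties.method = "first")
    p <- if (m == 1L) 0.5 else (r - 1) / (m - 1)
    out[obs, j] <- stats::approx(grid, ref, xout = p, rule = 2)$y
  }
  expression_dataset(out, data$groups, data$dataset_id)
}

#' Average probes mapping to the same feature
#'
#' Collapses a probe-level matrix to one row per mapped feature by taking
#' the per-sample mean over that feature's probes, excluding missing
#' entries. Probes absent from the map are dropped (count reported via
#' `message`).
#'
#' @param data Probe-level [expression_dataset()].
#' @param probe_map Data frame with columns `probe_id`, `feature_id`.
#' @return Feature-level `expr_dataset` (rows ordered by feature id).
#' @export
average_probes <- function(data, probe_map) {
  stopifnot(inherits(data, "expr_dataset"))
  probe_map <- check_probe_map(probe_map)
  if (nrow(probe_map) == 0L) stop("empty probe map")
  probes <- rownames(data$values)
  keep <- probes %in% probe_map$probe_id
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " unmapped probe(s) dropped")
  v <- data$values[keep, , drop = FALSE]
  feat <- probe_map$feature_id[match(rownames(v), probe_map$probe_id)]
  feats <- sort(unique(feat))
  out <- matrix(NA_real_, length(feats), ncol(v),
                dimnames = list(feats, colnames(v)))
  for (f in feats) {
    rows <- v[feat == f, , drop = FALSE]
    mu <- colMeans(rows, na.rm = TRUE)
    mu[!is.finite(mu)] <- NA_real_  # all probes missing for that sample
    out[f, ] <- mu
  }
  expression_dataset(out, data$groups, data$dataset_id)
}

#' k-nearest-neighbour imputation of missing values
#'
#' Fills each missing cell (f, s) with the mean of the values at sample s
#' of the k features nearest to f. Distance is Euclidean over the columns
#' observed in both features; candidate neighbours must themselves be
#' observed at s. When fewer than k candidates exist, all of them are used.
#' Observed entries are never modified.
#'
#' @param data An [expression_dataset()].
#' @param k Number of neighbours (default 5).
#' @return The imputed `expr_dataset`.
#' @export
knn_impute <- function(data, k = 5L) {
  stopifnot(inherits(data, "expr_dataset"))
  if (k < 1L) stop("'k' must be >= 1")
  v <- data$values
  miss <- which(is.na(v), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(data)
  all_missing <- rownames(v)[rowSums(!is.na(v)) == 0L]
  if (length(all_missing))
    stop("feature(s) with no observed values: ",
         paste(all_missing, collapse = ", "))
  out <- v
  obs_mask <- !is.na(v)
  v0 <- v
  v0[!obs_mask] <- 0
  for (f in unique(miss[, 1L])) {
    xf <- v0[f, ]
    of <- obs_mask[f, ]
    # squared Euclidean distance to every feature over co-observed columns
    shared <- obs_mask & rep(of, each = nrow(v))
    diff <- (v0 - rep(xf, each = nrow(v))) * shared
    d2 <- rowSums(diff * diff)
    d2[rowSums(shared) == 0L] <- NA_real_
    d2[f] <- NA_real_
    for (s in which(is.na(v[f, ]))) {
      cand <- which(!is.na(d2) & obs_mask[, s])
      if (!length(cand)) next  # no neighbour observed at s; left missing
      ord <- cand[order(d2[cand], cand)]
      use <- ord[seq_len(min(k, length(ord)))]
      out[f, s] <- mean(v[use, s])
    }
  }
  expression_dataset(out, data$groups, data$dataset_id)
}

#' Retain only genes measured by a single probe
#'
#' Removes genes that map to multiple probes, keeping genes represented by
#' exactly one probe (rows renamed to gene ids).
#'
#' @param data Probe-level [expression_dataset()].
#' @param probe_map Data frame with columns `probe_id`, `feature_id`
#'   (gene ids).
#' @return Gene-level `expr_dataset` with single-probe genes only.
#' @export
collapse_multiprobe_genes <- function(data, probe_map) {
  stopifnot(inherits(data, "expr_dataset"))
  probe_map <- check_probe_map(probe_map)
  probes <- rownames(data$values)
  pm <- probe_map[probe_map$probe_id %in% probes, , drop = FALSE]
  n_probes <- table(pm$feature_id)
  single <- names(n_probes)[n_probes == 1L]
  removed <- length(n_probes) - length(single)
  if (removed) message(removed, " multi-probe gene(s) removed")
  if (!length(single)) {
    warning("no single-probe genes remain; returning empty dataset")
    v <- matrix(numeric(0), nrow = 0L, ncol = ncol(data$values),
                dimnames = list(character(0), colnames(data$values)))
    return(expression_dataset(v, data$groups, data$dataset_id))
  }
  keep_probes <- pm$probe_id[pm$feature_id %in% single]
  v <- data$values[keep_probes, , drop = FALSE]
  rownames(v) <- pm$feature_id[match(keep_probes, pm$probe_id)]
  v <- v[order(rownames(v)), , drop = FALSE]
  expression_dataset(v, data$groups, data$dataset_id)
}

check_probe_map <- function(probe_map) {
  if (is.null(probe_map) || !is.data.frame(probe_map) ||
      !all(c("probe_id", "feature_id") %in% names(probe_map)))
    stop("'probe_map' must be a data frame with columns probe_id, ",
         "feature_id")
  if (anyDuplicated(probe_map$probe_id))
    stop("duplicate probe ids in probe map")
  probe_map
}

#' Standard preprocessing chain
#'
#' Runs the default order: normexp background correction, quantile
#' normalization, probe averaging (when a probe map is supplied), then kNN
#' imputation. Steps can be switched off for data that is already on a
#' clean log scale (e.g. simulated studies need only normalization and
#' imputation).
#'
#' @param data Raw [expression_dataset()].
#' @param probe_map Optional probe-to-feature map for [average_probes()].
#' @param knn_k Neighbours for imputation (default 5).
#' @param offset Normexp offset (default 0).
#' @param steps Character subset of
#'   `c("normexp", "quantile", "average", "impute")`.
#' @return Preprocessed `expr_dataset`.
#' @export
preprocess_dataset <- function(data, probe_map = NULL, knn_k = 5L,
                               offset = 0,
                               steps = c("normexp", "quantile", "average",
                                         "impute")) {
  steps <- match.arg(steps, c("normexp", "quantile", "average", "impute"),
                     several.ok = TRUE)
  if ("normexp" %in% steps) data <- normexp_correct(data, offset = offset)
  if ("quantile" %in% steps) data <- quantile_normalize(data)
  if ("average" %in% steps && !is.null(probe_map))
    data <- average_probes(data, probe_map)
  if ("impute" %in% steps && anyNA(data$values))
    data <- knn_impute(data, k = knn_k)
  data
}
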