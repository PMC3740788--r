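#' Expression dataset container
#'
#' A light-weight container for one feature-by-sample expression matrix with
#' a two-group (normal/tumor) design. Missing values are stored as `NA` in
#' the matrix itself.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Rownames (feature ids) and colnames (sample ids) must be present and
#'   unique.
#' @param groups Character or factor of length `ncol(values)` with values
#'   `"normal"` or `"tumor"`, one per sample.
#' @param dataset_id Single string identifying the dataset.
#'
#' @return An object of class `expr_dataset`: a list with elements `values`,
#'   `groups` (factor with levels normal/tumor) and `dataset_id`.
#' @export
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
#' d <- expression_dataset(m, c("normal", "normal", "tumor", "tumor", "tumor"))
#' d
expression_dataset <- function(values, groups, dataset_id = "dataset") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("'values' must have rownames (features) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (length(groups) != ncol(values))
    stop("length(groups) must equal ncol(values)")
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), c("normal", "tumor"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (!is.character(dataset_id) || length(dataset_id) != 1L)
    stop("'dataset_id' must be a single string")
  structure(
    list(values = values,
         groups = factor(groups, levels = c("normal", "tumor")),
         dataset_id = dataset_id),
    class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  nm <- sum(is.na(x$values))
  cat(sprintf(
    "expr_dataset '%s': %d features x %d samples (%d normal, %d tumor)%s\n",
    x$dataset_id, nrow(x$values), ncol(x$values),
    sum(x$groups == "normal"), sum(x$groups == "tumor"),
    if (nm) sprintf(", %d missing values", nm) else ""))
  invisible(x)
}

#' @rdname expression_dataset
#' @param x An `expr_dataset`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expression_dataset
#' @export
sample_ids <- function(x) colnames(x$values)

# Check a dataset supports two-group statistics (>= 2 samples per group).
assert_two_groups <- function(x, min_per_group = 2L) {
  tab <- table(x$groups)
  if (any(tab < min_per_group))
    stop(sprintf("dataset '%s' needs at least %d samples per group",
                 x$dataset_id, min_per_group))
  invisible(x)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
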