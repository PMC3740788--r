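#' Read and write the package's plain-text interchange formats
#'
#' Expression matrices travel as TSV with a `#key=value` metadata header,
#' a `feature_id` first column, sample ids as remaining column names and
#' empty cells for missing values. Group maps are 2-column TSV
#' (`sample_id`, `group`); interaction networks 3-column TSV (`mirna`,
#' `gene`, `source`); gene sets standard GMT (name, description, members).
#' Values are written with 9 significant digits, so write-then-read
#' round-trips are exact to that precision.
#'
#' @param data An [expression_dataset()].
#' @param path File path.
#' @param metadata Named character vector written as `#key=value` header
#'   lines (the dataset id and package version are always included).
#' @return `write_*` functions return `path` invisibly; readers return the
#'   parsed object.
#' @name interchange_io
NULL

meta_header <- function(metadata) {
  metadata <- c(metadata,
                generator = paste0("mirpoma ",
                                   as.character(utils::packageVersion(
                                     "mirpoma"))))
  sprintf("#%s=%s", names(metadata), unname(metadata))
}

#' @rdname interchange_io
#' @export
write_expression_tsv <- function(data, path, metadata = character(0)) {
  stopifnot(inherits(data, "expr_dataset"))
  hdr <- meta_header(c(dataset_id = data$dataset_id, metadata))
  v <- data$values
  body <- cbind(feature_id = rownames(v),
                matrix(ifelse(is.na(v), "", sprintf("%.9g", v)),
                       nrow = nrow(v), dimnames = dimnames(v)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname interchange_io
#' @param group_map Data frame (`sample_id`, `group`) or path to one, as
#'   written by [write_group_map()]. Every sample in the matrix must be
#'   present.
#' @export
read_expression_tsv <- function(path, group_map) {
  lines <- readLines(path)
  meta <- grep("^#", lines)
  hdr <- lines[meta]
  dataset_id <- sub("^#dataset_id=", "",
                    grep("^#dataset_id=", hdr, value = TRUE)[1])
  if (is.na(dataset_id)) dataset_id <- basename(path)
  body <- if (length(meta)) lines[-meta] else lines
  tab <- utils::read.delim(text = body, check.names = FALSE,
                           colClasses = "character")
  if (names(tab)[1L] != "feature_id")
    stop("first column must be 'feature_id' in ", path)
  ids <- tab$feature_id
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  v <- as.matrix(tab[-1L])
  v[v == ""] <- NA
  storage.mode(v) <- "double"
  rownames(v) <- ids
  if (is.character(group_map)) group_map <- read_group_map(group_map)
  missing_s <- setdiff(colnames(v), group_map$sample_id)
  if (length(missing_s))
    stop("sample(s) missing from group map: ",
         paste(missing_s, collapse = ", "))
  groups <- group_map$group[match(colnames(v), group_map$sample_id)]
  expression_dataset(v, groups, dataset_id)
}

#' @rdname interchange_io
#' @export
write_group_map <- function(data, path) {
  stopifnot(inherits(data, "expr_dataset"))
  utils::write.table(
    data.frame(sample_id = sample_ids(data),
               group = as.character(data$groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname interchange_io
#' @export
read_group_map <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(tab)))
    stop("group map must have columns sample_id, group: ", path)
  tab
}

#' @rdname interchange_io
#' @param network A [target_network()].
#' @export
write_edge_list <- function(network, path, metadata = character(0)) {
  stopifnot(inherits(network, "target_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(metadata), con)
  utils::write.table(network$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname interchange_io
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  data_lines <- grep("^#", lines, invert = TRUE)
  fields <- strsplit(lines[data_lines], "\t", fixed = TRUE)
  bad <- data_lines[lengths(fields) < 3L]
  if (length(bad))
    stop("malformed edge row(s) at line(s): ", paste(bad, collapse = ", "))
  tab <- utils::read.delim(text = lines[data_lines],
                           colClasses = "character")
  if (!all(c("mirna", "gene", "source") %in% names(tab)))
    stop("edge list must have columns mirna, gene, source: ", path)
  target_network(tab)
}

#' @rdname interchange_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(bad, collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in ", path)
  gene_set_collection(sets)
}

#' @rdname interchange_io
#' @param collection A [gene_set_collection()].
#' @param descriptions Optional per-set description column.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(descriptions))
    descriptions <- rep("na", length(collection$sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(collection$sets), descriptions, collection$sets)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname interchange_io
#' @param truth A `synthetic_truth` object from [simulate_study()].
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname interchange_io
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(raw, class = "synthetic_truth")
}
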