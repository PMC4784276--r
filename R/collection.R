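#' Construct an expression dataset
#'
#' A thin container for one dataset's log-scale expression matrix (genes in
#' rows, samples in columns) plus a dataset identifier. Expression is assumed
#' to be pre-normalized *within* the dataset; no between-dataset normalization
#' is ever applied by this package.
#'
#' @param values numeric matrix, genes x samples, with unique rownames (gene
#'   symbols) and unique colnames (sample ids). No missing values.
#' @param dataset_id length-one character identifier.
#' @return An object of class `expression_dataset` with fields `dataset_id`
#'   and `values`.
#' @export
expression_dataset <- function(values, dataset_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in dataset '", dataset_id, "'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in dataset '", dataset_id, "'")
  if (anyNA(values))
    stop("missing values in dataset '", dataset_id,
         "' (drop incomplete rows before constructing)")
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)
  structure(list(dataset_id = dataset_id, values = values),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s': %d genes x %d samples>\n",
              x$dataset_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

genes <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

new_collection <- function(datasets, feature_set, min_coverage = 0) {
  ids <- vapply(datasets, `[[`, "", "dataset_id")
  if (anyDuplicated(ids)) stop("duplicate dataset ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(datasets) <- ids
  structure(list(datasets = datasets, feature_set = feature_set,
                 min_coverage = min_coverage),
            class = "expr_collection")
}

#' @export
print.expr_collection <- function(x, ...) {
  cat(sprintf("<collection: %d datasets, %d analysis genes, min coverage %.2f>\n",
              length(x$datasets), length(x$feature_set), x$min_coverage))
  invisible(x)
}

#' Load a collection of expression matrices from delimited text files
#'
#' Each file must be a rectangular labeled matrix: first column gene symbols,
#' header row sample ids, numeric cells. Rows containing missing values are
#' dropped (with a message); duplicated gene rows are collapsed by keeping the
#' row with the largest mean absolute deviation across samples.
#'
#' @param paths character vector of file paths (one dataset per file).
#' @param delimiter field separator, default tab.
#' @param log2 if `TRUE`, apply `log2(x + 1)` to raw inputs after loading.
#' @param dataset_ids optional ids, default the file names without extension.
#' @return An `expr_collection` whose `feature_set` is the union of all genes.
#' @export
load_collection <- function(paths, delimiter = "\t", log2 = FALSE,
                            dataset_ids = NULL) {
  if (is.null(dataset_ids))
    dataset_ids <- sub("\\.[^.]*$", "", basename(paths))
  stopifnot(length(dataset_ids) == length(paths))
  datasets <- mapply(function(p, id) {
    if (!file.exists(p)) stop("cannot read dataset file: ", p)
    read_expression_matrix(p, delimiter, id, log2 = log2)
  }, paths, dataset_ids, SIMPLIFY = FALSE)
  feature_set <- sort(unique(unlist(lapply(datasets, genes))))
  new_collection(datasets, feature_set)
}

read_expression_matrix <- function(path, delimiter, dataset_id, log2 = FALSE) {
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2L) stop("file '", path, "' has no sample columns")
  gene_col <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                dimnames = dimnames(cells)))
  bad <- which(is.na(num) & !(is.na(cells) | cells %in% c("NA", "")),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric cell '%s' in file '%s' at gene row %d ('%s'), sample column '%s'",
      cells[bad[1L, 1L], bad[1L, 2L]], path, bad[1L, 1L],
      gene_col[bad[1L, 1L]], colnames(cells)[bad[1L, 2L]]))
  }
  rownames(num) <- gene_col
  incomplete <- apply(num, 1L, anyNA)
  if (any(incomplete)) {
    message(sprintf("%s: dropped %d gene rows with missing values",
                    dataset_id, sum(incomplete)))
    num <- num[!incomplete, , drop = FALSE]
  }
  if (log2) num <- log2(num + 1)
  if (anyDuplicated(rownames(num))) {
    score <- rowMeans(abs(num - rowMeans(num)))
    keep <- order(-score)                       # best row of each symbol first
    num <- num[keep, , drop = FALSE]
    dup <- duplicated(rownames(num))
    warning(sprintf(
      "%s: collapsed %d duplicated gene rows (kept highest mean absolute deviation)",
      dataset_id, sum(dup)), call. = FALSE)
    num <- num[!dup, , drop = FALSE]
    num <- num[order(match(rownames(num), gene_col)), , drop = FALSE]
  }
  expression_dataset(num, dataset_id)
}

#' Harmonize a collection onto a shared feature set
#'
#' Datasets covering less than `min_coverage` of `feature_set` are excluded;
#' the retained datasets are each subset to their intersection with
#' `feature_set` (in `feature_set` order). The union of matched genes across
#' retained datasets becomes the collection's analysis feature set. At least
#' three datasets must survive, since a meta-cluster requires clusters from at
#' least three distinct datasets downstream.
#'
#' @param collection an `expr_collection`.
#' @param feature_set character vector of gene symbols.
#' @param min_coverage minimum fraction of `feature_set` a dataset must carry,
#'   in (0, 1]. Suggested values range from 0.7 to 1.
#' @return Harmonized `expr_collection`; the per-dataset coverage report is
#'   available via [harmonization_report()].
#' @export
harmonize <- function(collection, feature_set, min_coverage = 0.7) {
  stopifnot(inherits(collection, "expr_collection"),
            min_coverage > 0, min_coverage <= 1)
  feature_set <- unique(feature_set)
  report <- do.call(rbind, lapply(collection$datasets, function(d) {
    matched <- sum(feature_set %in% genes(d))
    data.frame(dataset_id = d$dataset_id, n_genes_in = length(genes(d)),
               n_genes_matched = matched,
               coverage = matched / length(feature_set))
  }))
  report$retained <- report$coverage >= min_coverage
  rownames(report) <- NULL
  for (i in which(!report$retained))
    message(sprintf("excluding dataset '%s': coverage %.3f < %.3f",
                    report$dataset_id[i], report$coverage[i], min_coverage))
  kept <- collection$datasets[report$retained]
  if (length(kept) < 3L)
    stop("fewer than 3 datasets meet min_coverage = ", min_coverage,
         "; meta-clustering requires >= 3 datasets")
  kept <- lapply(kept, function(d) {
    g <- feature_set[feature_set %in% genes(d)]
    expression_dataset(d$values[g, , drop = FALSE], d$dataset_id)
  })
  analysis_genes <- feature_set[feature_set %in%
                                  unique(unlist(lapply(kept, genes)))]
  out <- new_collection(kept, analysis_genes, min_coverage)
  attr(out, "harmonization_report") <- report
  out
}

#' Per-dataset coverage report of the last harmonization
#' @param collection a harmonized `expr_collection`.
#' @return data.frame with columns dataset_id, n_genes_in, n_genes_matched,
#'   coverage, retained (or `NULL` if the collection was never harmonized).
#' @export
harmonization_report <- function(collection) {
  attr(collection, "harmonization_report")
}

#' Gene-wise batch mean centering
#'
#' Subtracts each gene's within-dataset mean from its row, the classical
#' transform applied before concatenating datasets. Idempotent and
#' shape-preserving. Note that gene-wise centering does change Pearson
#' correlations between sample columns (all columns are shifted by the common
#' row-mean vector), which is precisely why it alters downstream clustering.
#'
#' @param dataset an `expression_dataset`.
#' @return The centered `expression_dataset` (row means 0).
#' @export
batch_mean_center <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  expression_dataset(dataset$values - rowMeans(dataset$values),
                     dataset$dataset_id)
}
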