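# Step 2 internals: every cross-dataset cluster comparison reduces to Pearson
# correlations between query sample columns and reference centroid columns.
# Columns are scaled to unit-norm z-scores once, so correlation matrices are
# plain cross products.

std_unit_cols <- function(M) {
  ctr <- sweep(M, 2L, colMeans(M))
  nrm <- sqrt(colSums(ctr^2))
  constant <- nrm < 1e-12
  nrm[constant] <- 1
  list(Z = sweep(ctr, 2L, nrm, "/"), constant = constant)
}

# m x k Pearson correlation matrix between sample columns of X and centroid
# columns of C; constant columns yield the sentinel -2 (below any real
# correlation, so never nearest).
col_cor <- function(X, C) {
  zx <- std_unit_cols(X)
  zc <- std_unit_cols(C)
  S <- crossprod(zx$Z, zc$Z)
  if (any(zc$constant)) S[, zc$constant] <- -2
  if (any(zx$constant)) S[zx$constant, ] <- -2
  attr(S, "constant_samples") <- zx$constant
  attr(S, "constant_centroids") <- zc$constant
  S
}

#' Compute cluster centroids of one dataset
#'
#' @param dataset an `expression_dataset`.
#' @param clust a [clustering()] whose sample names all occur in `dataset`.
#' @param genes optional gene subset (must be present in the dataset);
#'   default all dataset genes.
#' @return A `centroid_set`: list with `dataset_id`, `genes`, `centroids`
#'   (genes x k, column `c` = mean profile of cluster `c`), `center` (the
#'   per-gene mean over all clustered samples, the pivot of the null
#'   rotation), and `sizes`.
#' @export
compute_centroids <- function(dataset, clust, genes = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"), inherits(clust, "clustering"))
  if (is.null(genes)) genes <- rownames(dataset$values)
  if (!all(genes %in% rownames(dataset$values)))
    stop("`genes` must all be present in dataset '", dataset$dataset_id, "'")
  ids <- names(clust$labels)
  if (!all(ids %in% colnames(dataset$values)))
    stop("clustering of '", clust$dataset_id,
         "' names samples absent from the dataset")
  X <- dataset$values[genes, ids, drop = FALSE]
  centroids <- vapply(seq_len(clust$k), function(c) {
    mem <- clust$labels == c
    if (!any(mem)) stop("cluster ", c, " is empty")
    rowMeans(X[, mem, drop = FALSE])
  }, numeric(length(genes)))
  centroids <- matrix(centroids, nrow = length(genes),
                      dimnames = list(genes, paste0("c", seq_len(clust$k))))
  structure(list(dataset_id = dataset$dataset_id, genes = genes,
                 centroids = centroids, center = rowMeans(X),
                 sizes = tabulate(clust$labels, clust$k)),
            class = "centroid_set")
}

shared_gene_space <- function(query_genes, reference, min_shared_genes) {
  shared <- intersect(reference$genes, query_genes)
  if (length(shared) < min_shared_genes)
    stop("only ", length(shared), " shared genes; need at least ",
         min_shared_genes)
  shared
}

#' Assign samples to their nearest reference centroid
#'
#' Each sample is assigned to the reference centroid with which it has the
#' highest Pearson correlation over the genes shared by query and reference.
#' Ties break toward the lowest centroid index. A constant sample or centroid
#' vector on the shared genes can never be nearest (its correlations are
#' treated as minus infinity) and is reported via a warning.
#'
#' @param query an `expression_dataset`.
#' @param reference a `centroid_set` from another dataset.
#' @param samples optional sample ids to assign (default all).
#' @param min_shared_genes minimum size of the gene intersection (default 10).
#' @return List with `assignment` (named integer vector of centroid indices),
#'   `correlations` (samples x centroids matrix) and `shared_genes`.
#' @export
assign_nearest <- function(query, reference, samples = NULL,
                           min_shared_genes = 10L) {
  stopifnot(inherits(query, "expression_dataset"),
            inherits(reference, "centroid_set"))
  if (is.null(samples)) samples <- colnames(query$values)
  shared <- shared_gene_space(rownames(query$values), reference,
                              min_shared_genes)
  X <- query$values[shared, samples, drop = FALSE]
  C <- reference$centroids[shared, , drop = FALSE]
  S <- col_cor(X, C)
  if (all(attr(S, "constant_samples")) || all(attr(S, "constant_centroids")))
    stop("all vectors constant on the shared genes; assignment undefined")
  if (any(attr(S, "constant_samples")))
    warning(sum(attr(S, "constant_samples")),
            " constant query sample(s) on the shared genes; assigned to centroid 1 by tie rule")
  if (any(attr(S, "constant_centroids")))
    warning(sum(attr(S, "constant_centroids")),
            " constant centroid(s) excluded from nearest-neighbor assignment")
  assignment <- max.col(S, ties.method = "first")
  names(assignment) <- samples
  list(assignment = assignment, correlations = S, shared_genes = shared)
}

# Per-query-cluster summaries of an assignment: best-fit reference cluster
# (mode of assignments, ties toward the lower index), nearest neighbor
# fraction, and the full nnf / mean-correlation matrices (query clusters x
# reference centroids) needed for the density curve.
dir_stats <- function(S, labels, k_query, k_ref) {
  nnf_mat <- matrix(0, k_query, k_ref)
  sim_mat <- matrix(NA_real_, k_query, k_ref)
  assignment <- max.col(S, ties.method = "first")
  for (q in seq_len(k_query)) {
    mem <- labels == q
    nnf_mat[q, ] <- tabulate(assignment[mem], k_ref) / sum(mem)
    sim_mat[q, ] <- colMeans(S[mem, , drop = FALSE])
  }
  best <- max.col(nnf_mat, ties.method = "first")
  list(best = best, nnf_mat = nnf_mat, sim_mat = sim_mat,
       nnf = nnf_mat[cbind(seq_len(k_query), best)],
       sim = sim_mat[cbind(seq_len(k_query), best)])
}

#' Generate one null centroid set
#'
#' Re-embeds the reference centroid frame at a uniformly random orientation
#' about the reference data's overall mean point: with `B = C - center` and
#' QR factorization `B = Q R`, the null set is `center + V R` where `V` is a
#' Haar-uniform orthonormal frame (QR of a standard Gaussian matrix with sign
#' correction). All pairwise centroid distances and all centroid norms about
#' `center` are preserved exactly; only the orientation is randomized.
#'
#' @param reference a `centroid_set`.
#' @param genes optional gene subset (default the reference genes); at least
#'   two genes are required for a rotation to exist.
#' @return genes x k matrix of null centroids.
#' @export
null_centroid_set <- function(reference, genes = NULL) {
  stopifnot(inherits(reference, "centroid_set"))
  if (is.null(genes)) genes <- reference$genes
  if (length(genes) < 2L)
    stop("a rotation is undefined on fewer than 2 genes")
  C <- reference$centroids[genes, , drop = FALSE]
  center <- reference$center[genes]
  Rb <- qr.R(qr(C - center))
  k <- ncol(C)
  G <- matrix(stats::rnorm(length(genes) * k), length(genes), k)
  qg <- qr(G)
  V <- qr.Q(qg)
  d <- sign(diag(qr.R(qg)))
  d[d == 0] <- 1
  V <- sweep(V, 2L, d, "*")
  out <- V %*% Rb + center
  dimnames(out) <- list(genes, colnames(C))
  out
}

#' Permutation P value for an observed cluster-centroid match
#'
#' Draws `n_null` null centroid sets (see [null_centroid_set()]), re-assigns
#' the real query samples to each null set, and counts the draws in which
#' *both* the null best-fit mean similarity and the null nearest neighbor
#' fraction strictly exceed the observed values. The P value is that count
#' divided by `n_null` (resolution `1/n_null`; 0 is reportable).
#'
#' @param query_values genes x samples matrix of the query cluster's samples,
#'   with gene rownames.
#' @param reference a `centroid_set`.
#' @param observed_nnf,observed_sim the observed best-fit statistics.
#' @param n_null number of null draws (default 500).
#' @param seed optional integer seed.
#' @param min_shared_genes minimum gene intersection (default 10).
#' @return P value in `[0, 1]`.
#' @export
null_pvalue <- function(query_values, reference, observed_nnf, observed_sim,
                        n_null = 500L, seed = NULL, min_shared_genes = 10L) {
  stopifnot(n_null >= 1L)
  if (!is.null(seed)) set.seed(seed)
  shared <- shared_gene_space(rownames(query_values), reference,
                              max(2L, min_shared_genes))
  X <- query_values[shared, , drop = FALSE]
  nulls <- null_stats(X, rep(1L, ncol(X)), 1L, reference, shared, n_null)
  mean(nulls$sim[, 1L] > observed_sim & nulls$nnf[, 1L] > observed_nnf)
}

# Shared-gene null draws for all query clusters of one ordered dataset pair.
null_stats <- function(X, labels, k_query, reference, shared, n_null) {
  C <- reference$centroids[shared, , drop = FALSE]
  center <- reference$center[shared]
  Rb <- qr.R(qr(C - center))
  Zq <- std_unit_cols(X)$Z
  cpp_null_stats(Zq, as.integer(labels), as.integer(k_query), Rb, center,
                 as.integer(n_null))
}

#' Compare one query cluster against a reference centroid set
#'
#' The directional Step-2 comparison: every sample of the query cluster is
#' assigned to its nearest reference centroid by Pearson correlation; the
#' centroid attracting the highest fraction of samples is the best fit; the
#' nearest neighbor fraction (NNF), the mean correlation with the best-fit
#' centroid, and the rotation-null permutation P value are returned.
#'
#' @param query an `expression_dataset`.
#' @param query_clustering the [clustering()] of `query`.
#' @param cluster query cluster index to compare.
#' @param reference a `centroid_set` from a different dataset.
#' @param n_null null draws for the P value (default 500).
#' @param seed optional integer seed.
#' @param min_shared_genes minimum gene intersection (default 10).
#' @return A `directional_comparison` list: `query_dataset`, `query_cluster`,
#'   `reference_dataset`, `best_reference_cluster`, `nnf`, `mean_sim`,
#'   `p_value`, `n_null`.
#' @export
directional_compare <- function(query, query_clustering, cluster, reference,
                                n_null = 500L, seed = NULL,
                                min_shared_genes = 10L) {
  stopifnot(inherits(query_clustering, "clustering"),
            cluster %in% seq_len(query_clustering$k))
  if (!is.null(seed)) set.seed(seed)
  ids <- names(query_clustering$labels)[query_clustering$labels == cluster]
  res <- assign_nearest(query, reference, samples = ids,
                        min_shared_genes = min_shared_genes)
  st <- dir_stats(res$correlations, rep(1L, length(ids)), 1L,
                  ncol(reference$centroids))
  p <- null_pvalue(query$values[, ids, drop = FALSE], reference,
                   st$nnf, st$sim, n_null = n_null,
                   min_shared_genes = min_shared_genes)
  structure(list(query_dataset = query$dataset_id, query_cluster = cluster,
                 reference_dataset = reference$dataset_id,
                 best_reference_cluster = st$best, nnf = st$nnf,
                 mean_sim = st$sim, p_value = p, n_null = n_null),
            class = "directional_comparison")
}

# Deterministic per-ordered-pair RNG stream: a function of the global seed and
# the two dataset id strings only, so results do not depend on the order in
# which datasets are stored in the collection.
pair_seed <- function(seed, ref_id, query_id) {
  h <- function(s) {
    v <- utf8ToInt(s)
    sum(v * (seq_along(v) %% 31L + 1L)) %% 100003L
  }
  (abs(seed) + 131L * h(ref_id) + 30011L * h(query_id)) %% 2147483647L
}

#' All bidirectional cluster comparisons of a collection
#'
#' For every ordered pair of clustered datasets, every query cluster is
#' compared against the other dataset's centroid set ([directional_compare()]
#' semantics, with null draws shared across the query clusters of one ordered
#' pair). Unordered cluster pairs that are mutual best fits are marked
#' reciprocal, with NNF and mean similarity averaged over the two directions
#' and both directional P values retained (they are thresholded separately,
#' never averaged). Non-reciprocal pairs are kept -- their directional mean
#' similarities feed the threshold-selection density curve. Dataset pairs in
#' which *both* datasets carry exactly one cluster are skipped (such clusters
#' have no within-dataset contrast to compare).
#'
#' @param collection an `expr_collection` (>= 2 clustered datasets).
#' @param clusterings named list of [clustering()] objects, one per dataset.
#' @param n_null null draws per directional P value (default 500).
#' @param seed integer seed; each ordered dataset pair derives its own
#'   deterministic stream from it, so results are invariant to dataset order.
#' @param min_shared_genes minimum pairwise gene intersection (default 10).
#' @return A `pair_table` data.frame with one row per cross-dataset cluster
#'   pair: `dataset_a`, `cluster_a`, `size_a`, `dataset_b`, `cluster_b`,
#'   `size_b`, `reciprocal`, `nnf_avg`, `sim_avg`, `p_a`, `p_b`,
#'   `sim_a_to_b`, `sim_b_to_a`, `nnf_a_to_b`, `nnf_b_to_a`,
#'   `n_shared_genes`. All directional mean similarities (including
#'   non-best-fit ones) are attached as attribute `"sim_values"`.
#' @export
all_pairs <- function(collection, clusterings, n_null = 500L, seed = 1L,
                      min_shared_genes = 10L) {
  stopifnot(inherits(collection, "expr_collection"))
  ids <- names(collection$datasets)
  if (!all(ids %in% names(clusterings)))
    stop("clusterings must be a named list covering every dataset")
  if (length(ids) < 2L) stop("need at least 2 clustered datasets")
  cents <- lapply(ids, function(i)
    compute_centroids(collection$datasets[[i]], clusterings[[i]]))
  names(cents) <- ids
  ks <- vapply(clusterings[ids], `[[`, 0L, "k")

  dir_res <- list()    # keyed "ref|query"
  sim_values <- numeric()
  for (ref in ids) for (qry in ids) {
    if (ref == qry) next
    if (ks[[ref]] == 1L && ks[[qry]] == 1L) next
    cl <- clusterings[[qry]]
    shared <- tryCatch(
      shared_gene_space(genes(collection$datasets[[qry]]), cents[[ref]],
                        min_shared_genes),
      error = function(e) NULL)
    if (is.null(shared)) {
      warning("skipping pair ", ref, " / ", qry, ": gene intersection below ",
              min_shared_genes, call. = FALSE)
      next
    }
    X <- collection$datasets[[qry]]$values[shared, names(cl$labels),
                                           drop = FALSE]
    C <- cents[[ref]]$centroids[shared, , drop = FALSE]
    S <- col_cor(X, C)
    st <- dir_stats(S, cl$labels, cl$k, ncol(C))
    set.seed(pair_seed(seed, ref, qry))
    nulls <- null_stats(X, cl$labels, cl$k, cents[[ref]], shared, n_null)
    st$p <- vapply(seq_len(cl$k), function(q)
      mean(nulls$sim[, q] > st$sim[q] & nulls$nnf[, q] > st$nnf[q]), 0)
    st$n_shared <- length(shared)
    dir_res[[paste(ref, qry, sep = "|")]] <- st
    sim_values <- c(sim_values, as.vector(st$sim_mat))
  }

  rows <- list()
  ord <- ids[order(ids)]
  for (i in seq_along(ord)) for (j in seq_along(ord)) {
    if (i >= j) next
    d1 <- ord[i]; d2 <- ord[j]
    fwd <- dir_res[[paste(d1, d2, sep = "|")]]   # d2 clusters vs d1 centroids
    rev <- dir_res[[paste(d2, d1, sep = "|")]]   # d1 clusters vs d2 centroids
    if (is.null(fwd) || is.null(rev)) next
    for (a in seq_len(ks[[d1]])) for (b in seq_len(ks[[d2]])) {
      recip <- fwd$best[b] == a && rev$best[a] == b
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_a = d1, cluster_a = a, size_a = cents[[d1]]$sizes[a],
        dataset_b = d2, cluster_b = b, size_b = cents[[d2]]$sizes[b],
        reciprocal = recip,
        nnf_avg = if (recip) (fwd$nnf_mat[b, a] + rev$nnf_mat[a, b]) / 2 else NA_real_,
        sim_avg = if (recip) (fwd$sim_mat[b, a] + rev$sim_mat[a, b]) / 2 else NA_real_,
        p_a = if (rev$best[a] == b) rev$p[a] else NA_real_,
        p_b = if (fwd$best[b] == a) fwd$p[b] else NA_real_,
        sim_a_to_b = rev$sim_mat[a, b], sim_b_to_a = fwd$sim_mat[b, a],
        nnf_a_to_b = rev$nnf_mat[a, b], nnf_b_to_a = fwd$nnf_mat[b, a],
        n_shared_genes = fwd$n_shared)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sim_values") <- sim_values
  attr(out, "n_null") <- n_null
  class(out) <- c("pair_table", "data.frame")
  out
}
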