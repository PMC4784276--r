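#' Consensus k-means clustering of one dataset
#'
#' Repeatedly subsamples the dataset's samples, runs Hartigan-Wong k-means
#' (one random start, samples as points, genes as dimensions) on each
#' subsample, and records how often each sample pair lands in the same
#' cluster. `consensus(i, j)` is the co-clustered count divided by the
#' co-sampled count (0, and flagged, for pairs never drawn together). Final
#' labels come from average-linkage hierarchical clustering of
#' `1 - consensus` cut at `k`.
#'
#' @param dataset an `expression_dataset`.
#' @param k number of clusters, `2 <= k < n_samples`.
#' @param n_resamples number of subsampling iterations (default 100).
#' @param subsample_fraction fraction of samples drawn per iteration without
#'   replacement (default 0.9).
#' @param seed optional integer seed for this call.
#' @return A `consensus_result`: list with `dataset_id`, `k`, `consensus`
#'   (samples x samples), `labels` (named integer vector), `pac` (PAC at the
#'   default 0.1--0.9 band) and `n_never_cosampled`.
#' @export
consensus_kmeans <- function(dataset, k, n_resamples = 100L,
                             subsample_fraction = 0.9, seed = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"),
            subsample_fraction > 0, subsample_fraction <= 1,
            n_resamples >= 1L)
  if (!is.null(seed)) set.seed(seed)
  pts <- t(dataset$values)
  n <- nrow(pts)
  if (k < 2L || k >= n) stop("need 2 <= k < n_samples (k = ", k,
                             ", n = ", n, ")")
  n_distinct <- nrow(unique(pts))
  if (n_distinct < k)
    stop("only ", n_distinct, " distinct sample profiles; cannot form k = ",
         k, " clusters")
  m <- max(1L, ceiling(subsample_fraction * n))
  co_clust <- matrix(0, n, n)
  co_samp <- matrix(0, n, n)
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, m)
    km <- one_start_kmeans(pts[idx, , drop = FALSE], k)
    co_samp[idx, idx] <- co_samp[idx, idx] + 1
    for (c in seq_len(k)) {
      ii <- idx[km == c]
      co_clust[ii, ii] <- co_clust[ii, ii] + 1
    }
  }
  consensus <- ifelse(co_samp > 0, co_clust / pmax(co_samp, 1), 0)
  dimnames(consensus) <- list(rownames(pts), rownames(pts))
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(dataset_id = dataset$dataset_id, k = k,
                 consensus = consensus, labels = labels,
                 pac = pac_score(consensus),
                 n_never_cosampled = sum(co_samp[upper.tri(co_samp)] == 0)),
            class = "consensus_result")
}

# One random start of Hartigan-Wong k-means; initial centers are drawn from
# the distinct sample profiles so duplicated points (e.g. noise-free
# archetypes) cannot abort the run with non-distinct centers.
one_start_kmeans <- function(pts, k) {
  uniq <- unique(pts)
  centers <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
  stats::kmeans(pts, centers = centers, iter.max = 50L,
                algorithm = "Hartigan-Wong")$cluster
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of strictly-upper-triangle consensus entries that fall strictly
#' inside the ambiguity band `(lower, upper)`. Lower PAC indicates a
#' better-resolved clustering.
#'
#' @param consensus square symmetric consensus matrix (entries in `[0, 1]`).
#' @param lower,upper band bounds, `0 <= lower < upper <= 1`
#'   (defaults 0.1, 0.9).
#' @return PAC fraction in `[0, 1]`.
#' @export
pac_score <- function(consensus, lower = 0.1, upper = 0.9) {
  stopifnot(is.matrix(consensus), nrow(consensus) == ncol(consensus),
            lower >= 0, lower < upper, upper <= 1)
  v <- consensus[upper.tri(consensus)]
  if (!length(v)) return(0)
  mean(v > lower & v < upper)
}

# Rounded-PAC model selection: round to 2 decimals, pick the smallest k
# achieving the minimum.
argmin_rounded_pac <- function(pac_by_k) {
  rounded <- round(pac_by_k, 2L)
  ks <- as.integer(names(pac_by_k))
  ks[which.min(rounded)]          # which.min takes the first (smallest k) tie
}

#' Select the number of clusters by rounded PAC
#'
#' Runs [consensus_kmeans()] for each candidate `k`, rounds each PAC to two
#' decimal places, and keeps the `k` with the minimal rounded PAC (ties broken
#' toward smaller `k`). With `allow_k1 = TRUE`, a dataset whose rounded PAC at
#' `k = 2` exceeds `k1_ceiling` is treated as a single cluster.
#'
#' @param dataset an `expression_dataset`.
#' @param k_range integer candidates, default `2:6`.
#' @param n_resamples,subsample_fraction,seed passed to [consensus_kmeans()].
#' @param pac_band PAC ambiguity band, default `c(0.1, 0.9)`.
#' @param allow_k1 permit a single-cluster call (default `FALSE`).
#' @param k1_ceiling rounded-PAC ceiling at `k = 2` above which the dataset is
#'   declared single-cluster (default 0.5).
#' @return A `clustering` object (see [clustering()]) with `pac_by_k`
#'   recorded.
#' @export
select_k <- function(dataset, k_range = 2:6, n_resamples = 100L,
                     subsample_fraction = 0.9, pac_band = c(0.1, 0.9),
                     allow_k1 = FALSE, k1_ceiling = 0.5, seed = NULL) {
  stopifnot(all(k_range >= 2L), all(k_range < ncol(dataset$values)))
  if (!is.null(seed)) set.seed(seed)
  k_range <- sort(unique(as.integer(k_range)))
  fits <- lapply(k_range, function(k)
    consensus_kmeans(dataset, k, n_resamples, subsample_fraction))
  pac_by_k <- vapply(fits, function(f)
    pac_score(f$consensus, pac_band[1L], pac_band[2L]), 0)
  names(pac_by_k) <- k_range
  if (allow_k1 && 2L %in% k_range &&
      round(pac_by_k[["2"]], 2L) > k1_ceiling) {
    labels <- stats::setNames(rep(1L, ncol(dataset$values)),
                              sample_ids(dataset))
    return(clustering(labels, dataset$dataset_id, pac_by_k = pac_by_k))
  }
  best_k <- argmin_rounded_pac(pac_by_k)
  labels <- fits[[match(best_k, k_range)]]$labels
  clustering(labels, dataset$dataset_id, pac_by_k = pac_by_k)
}

#' Construct a per-dataset clustering
#'
#' Container for a sample -> cluster-label assignment. Also the entry point
#' for user-supplied clusterings (e.g. centroid-classified subtype labels read
#' from a TSV), which bypass [select_k()] entirely.
#'
#' @param labels integer vector of cluster indices `1..k`, named by sample id;
#'   every cluster index must be non-empty.
#' @param dataset_id dataset identifier the labels belong to.
#' @param pac_by_k optional named numeric of PAC per candidate k.
#' @return An object of class `clustering` with fields `dataset_id`,
#'   `labels`, `k`, `pac_by_k`.
#' @export
clustering <- function(labels, dataset_id, pac_by_k = NULL) {
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (is.null(names(labels)) || anyNA(names(labels)))
    stop("labels must be named by sample id")
  k <- max(labels)
  if (anyNA(labels) || min(labels) < 1L ||
      !all(seq_len(k) %in% unique(labels)))
    stop("labels must cover 1..k with every cluster non-empty")
  structure(list(dataset_id = dataset_id, labels = labels, k = k,
                 pac_by_k = pac_by_k),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("<clustering '%s': %d samples in %d clusters>\n",
              x$dataset_id, length(x$labels), x$k))
  invisible(x)
}
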