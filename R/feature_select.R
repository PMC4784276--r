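#' Rank genes of one dataset by variability
#'
#' The variability score of a gene is its mean absolute deviation about its
#' within-dataset mean: `score(g) = mean_s |x_gs - mean_s(x_g)|`. Ranks are
#' descending in score (rank 1 = most variable) with ties broken
#' alphabetically by gene symbol.
#'
#' @param dataset an `expression_dataset` with at least two samples.
#' @return A `gene_ranking`: data.frame with columns `gene`, `score`, `rank`,
#'   ordered by rank, carrying the dataset id as an attribute.
#' @export
rank_genes <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (ncol(dataset$values) < 2L)
    stop("gene variability is undefined for a single-sample dataset")
  score <- rowMeans(abs(dataset$values - rowMeans(dataset$values)))
  ord <- order(-score, names(score))
  out <- data.frame(gene = names(score)[ord], score = unname(score)[ord],
                    rank = seq_along(score))
  attr(out, "dataset_id") <- dataset$dataset_id
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Build a cross-dataset meta-rank gene set
#'
#' Genes are ranked within each dataset by [rank_genes()]; a gene's global
#' score is its mean rank across datasets, where a gene absent from a dataset
#' receives that dataset's worst rank plus one. The top `n_global` genes by
#' mean rank are then augmented with every gene appearing in any dataset's top
#' `n_intra` that is not already included, so strong dataset-specific genes
#' survive even when their cross-dataset consensus is weak.
#'
#' @param collection an `expr_collection`.
#' @param n_global number of genes taken by ascending mean rank.
#' @param n_intra per-dataset top-rank depth for the union step (0 disables).
#' @param exclude gene symbols removed from every dataset *before* ranking.
#' @return Character vector of gene symbols, ordered by mean rank then symbol;
#'   mean ranks attached as attribute `"global_score"`.
#' @export
meta_rank <- function(collection, n_global, n_intra = 0L,
                      exclude = character()) {
  stopifnot(inherits(collection, "expr_collection"),
            n_global >= 1L, n_intra >= 0L)
  rankings <- lapply(collection$datasets, function(d) {
    keep <- setdiff(genes(d), exclude)
    if (length(keep) < nrow(d$values))
      d <- expression_dataset(d$values[keep, , drop = FALSE], d$dataset_id)
    rank_genes(d)
  })
  all_genes <- sort(unique(unlist(lapply(rankings, `[[`, "gene"))))
  if (n_global > length(all_genes))
    stop("n_global = ", n_global, " exceeds the ", length(all_genes),
         " genes in the collection (after exclusions)")
  rank_mat <- vapply(rankings, function(r) {
    v <- r$rank[match(all_genes, r$gene)]
    v[is.na(v)] <- nrow(r) + 1L          # missing-gene penalty: worst rank + 1
    v
  }, numeric(length(all_genes)))
  mean_rank <- rowMeans(rank_mat)
  names(mean_rank) <- all_genes
  ord <- order(mean_rank, all_genes)
  chosen <- all_genes[ord][seq_len(n_global)]
  if (n_intra > 0L) {
    intra <- unique(unlist(lapply(rankings, function(r)
      r$gene[r$rank <= n_intra])))
    chosen <- union(chosen, intra)
  }
  chosen <- chosen[order(mean_rank[chosen], chosen)]
  structure(chosen, global_score = mean_rank[chosen])
}
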