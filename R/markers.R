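# Marker-gene scoring: standardized mean differences per dataset, pooled
# across datasets -- the supervised meta-analysis pattern applied post hoc to
# the unsupervised meta-cluster labels.

#' Hedges' g for one gene in one dataset
#'
#' Bias-corrected standardized mean difference of a gene between the samples
#' of a dataset that belong to a meta-cluster's member clusters and all other
#' clustered samples of the same dataset, with its large-sample variance
#' `v = 1/n1 + 1/n2 + g^2 / (2(n1 + n2))`.
#'
#' @param dataset an `expression_dataset`.
#' @param clust the dataset's [clustering()].
#' @param member_clusters cluster indices of the dataset belonging to the
#'   meta-cluster.
#' @param gene gene symbol.
#' @param use_clusters clusters considered at all (default all); clusters
#'   absent from the final network should be excluded here.
#' @return Named numeric `c(effect, variance, n_in, n_out)`, or `NULL` (with
#'   a message) if either group has fewer than 2 samples.
#' @export
per_dataset_effect <- function(dataset, clust, member_clusters, gene,
                               use_clusters = seq_len(clust$k)) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(clust, "clustering"),
            gene %in% rownames(dataset$values))
  labels <- clust$labels[clust$labels %in% use_clusters]
  grp_in <- names(labels)[labels %in% member_clusters]
  grp_out <- names(labels)[!labels %in% member_clusters]
  if (length(grp_in) < 2L || length(grp_out) < 2L) {
    message(sprintf("%s / %s: group too small (%d vs %d), dataset skipped",
                    dataset$dataset_id, gene, length(grp_in), length(grp_out)))
    return(NULL)
  }
  x <- dataset$values[gene, grp_in]
  y <- dataset$values[gene, grp_out]
  hedges_g(x, y)
}

hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df)
  delta <- mean(x) - mean(y)
  if (sp == 0) {
    d <- if (delta == 0) 0 else sign(delta) * Inf   # zero pooled spread
  } else {
    d <- delta / sp
  }
  # exact small-sample bias correction (gamma form; ~ 1 - 3/(4*df - 1))
  j <- exp(lgamma(df / 2) - 0.5 * log(df / 2) - lgamma((df - 1) / 2))
  g <- j * d
  v <- 1 / n1 + 1 / n2 + g^2 / (2 * (n1 + n2))
  c(effect = g, variance = v, n_in = n1, n_out = n2)
}

#' Pool per-dataset effects into a summary effect size
#'
#' Inverse-variance weighted mean of the per-dataset standardized mean
#' differences. The default fixed-effect model weights by `1/v`; the
#' DerSimonian-Laird random-effects option adds the method-of-moments
#' between-dataset variance `tau^2` to every weight denominator.
#'
#' @param effects numeric vector of per-dataset effects (>= 2).
#' @param variances their sampling variances (positive, same length).
#' @param method `"fixed"` (default) or `"random"`.
#' @return List with `effect`, `se`, `tau2` (0 under the fixed-effect model)
#'   and `n_datasets`.
#' @export
summary_effect <- function(effects, variances, method = c("fixed", "random")) {
  method <- match.arg(method)
  stopifnot(length(effects) == length(variances), all(variances > 0))
  if (length(effects) < 2L)
    stop("summary effect requires >= 2 contributing datasets")
  w <- 1 / variances
  tau2 <- 0
  if (method == "random") {
    fe <- sum(w * effects) / sum(w)
    q <- sum(w * (effects - fe)^2)
    cc <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (length(effects) - 1)) / cc)
    w <- 1 / (variances + tau2)
  }
  list(effect = sum(w * effects) / sum(w), se = sqrt(1 / sum(w)),
       tau2 = tau2, n_datasets = length(effects))
}

#' Meta-analytic marker table for every meta-cluster
#'
#' For each meta-cluster and each gene, computes the per-dataset Hedges' g of
#' meta-cluster member samples versus all other network-retained clustered
#' samples of the same dataset, and pools the effects across datasets by
#' inverse-variance weighting. Only datasets contributing clusters both inside
#' and outside the meta-cluster (each group >= 2 samples) are used; genes with
#' fewer than 2 contributing datasets carry `NA` summaries and their
#' `n_datasets` flag.
#'
#' @param collection an `expr_collection`.
#' @param clusterings named list of [clustering()] objects.
#' @param meta a `meta_cluster_result`.
#' @param genes genes to score (default the collection feature set).
#' @param method pooling model, `"fixed"` (default) or `"random"`.
#' @return A `marker_table` data.frame: `meta_cluster`, `gene`,
#'   `summary_effect`, `summary_se`, `n_datasets`, `per_dataset` (JSON-encoded
#'   per-dataset effects).
#' @export
marker_table <- function(collection, clusterings, meta, genes = NULL,
                         method = "fixed") {
  stopifnot(inherits(meta, "meta_cluster_result"))
  if (is.null(genes)) genes <- collection$feature_set
  com <- meta$community
  rows <- list()
  for (mc in sort(unique(com$meta_cluster))) {
    members <- com[com$meta_cluster == mc, , drop = FALSE]
    for (gene in genes) {
      effs <- list()
      for (ds in unique(members$dataset_id)) {
        retained <- com$cluster[com$dataset_id == ds]
        member_cl <- members$cluster[members$dataset_id == ds]
        if (length(setdiff(retained, member_cl)) == 0L) next
        d <- collection$datasets[[ds]]
        if (!gene %in% rownames(d$values)) next
        e <- suppressMessages(per_dataset_effect(
          d, clusterings[[ds]], member_cl, gene, use_clusters = retained))
        if (!is.null(e)) effs[[ds]] <- e
      }
      n_ds <- length(effs)
      if (n_ds >= 2L) {
        s <- summary_effect(vapply(effs, `[[`, 0, "effect"),
                            vapply(effs, `[[`, 0, "variance"),
                            method = method)
        summ <- s$effect; se <- s$se
      } else {
        summ <- NA_real_; se <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        meta_cluster = mc, gene = gene, summary_effect = summ,
        summary_se = se, n_datasets = n_ds,
        per_dataset = as.character(jsonlite::toJSON(
          lapply(effs, function(e) unname(e[c("effect", "variance")])),
          digits = NA)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Filter a marker table by summary effect size
#'
#' The default inclusive rule (`summary_effect >= threshold`) matches the
#' convention used to nominate enrichment-analysis inputs at 0.5; the strict
#' variant (`>`) matches the druggable-target rule at 0.75.
#'
#' @param table a `marker_table`.
#' @param threshold nonnegative effect-size threshold (default 0.5).
#' @param strict require strictly greater (default `FALSE`).
#' @return The filtered `marker_table` (rows lacking a summary are dropped).
#' @export
filter_markers <- function(table, threshold = 0.5, strict = FALSE) {
  stopifnot(threshold >= 0)
  keep <- !is.na(table$summary_effect) &
    (if (strict) table$summary_effect > threshold
     else table$summary_effect >= threshold)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
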