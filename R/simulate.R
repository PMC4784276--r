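# Synthetic multi-dataset collections with known tissue-archetype truth, and
# the edge-level TPR/FPR harness used to benchmark the whole pipeline.

#' Configure a simulation scenario
#'
#' Seven scenario families define how cluster sizes and cluster counts vary
#' across the datasets of a collection:
#'
#' 1. fixed sizes (50), every dataset has all 4 archetype clusters;
#' 2. random sizes (1--100), all 4 clusters;
#' 3. fixed sizes, random 2--4 clusters per dataset;
#' 4. fixed sizes, random 1--4 clusters per dataset;
#' 5. random sizes, random 2--4 clusters;
#' 6. random sizes, random 1--4 clusters;
#' 7. as scenario 1, but half the clusters of each dataset are replaced by
#'    "mixed" clusters whose samples draw their archetype uniformly at random
#'    (the negative control).
#'
#' @param scenario integer 1--7.
#' @param n_datasets datasets per collection (default 10).
#' @param n_genes simulated genes (default 200).
#' @param n_archetypes ground-truth archetypes (default 4).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (default 0; the benchmark grid spans 0 to 2.4).
#' @param archetype_sd per-gene standard deviation of the archetype mean
#'   vectors (default 0.7), the separation calibration constant: the mean
#'   pairwise archetype distance is about `sqrt(2 * n_genes) * archetype_sd`.
#' @param noisy_cluster_fraction fraction of clusters made "mixed" in
#'   scenario 7 (default 0.5).
#' @param seed integer seed fixing archetypes and all draws.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario, n_datasets = 10L, n_genes = 200L,
                            n_archetypes = 4L, noise_sd = 0,
                            archetype_sd = 0.7,
                            noisy_cluster_fraction = 0.5, seed = 1L) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:7) stop("scenario must be 1..7")
  size_rule <- if (scenario %in% c(2L, 5L, 6L)) "random" else "fixed"
  k_rule <- switch(scenario, "4", "4", "2-4", "1-4", "2-4", "1-4", "4")
  stopifnot(noise_sd >= 0, n_datasets >= 3L, n_archetypes >= 2L,
            n_genes >= 2L)
  structure(list(scenario = scenario, n_datasets = n_datasets,
                 n_genes = n_genes, n_archetypes = n_archetypes,
                 cluster_size_rule = size_rule, clusters_rule = k_rule,
                 noise_sd = noise_sd, archetype_sd = archetype_sd,
                 noisy_cluster_fraction =
                   if (scenario == 7L) noisy_cluster_fraction else 0,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a collection of clustered datasets with known archetype truth
#'
#' Archetype mean vectors are drawn once per seed as i.i.d. Gaussians with
#' per-gene standard deviation `archetype_sd`. Each dataset receives a number
#' of clusters per its scenario rule; each cluster is assigned an archetype
#' (sampled without replacement within a dataset) and a size; every sample is
#' its archetype mean plus i.i.d. `N(0, noise_sd^2)` noise per gene. "Mixed"
#' clusters (scenario 7) draw each sample's archetype uniformly at random and
#' are labeled `"mixed"` in the truth table.
#'
#' @param config a [scenario_config()].
#' @return A `sim_collection`: list with `collection` (an `expr_collection`),
#'   `clusterings` (the ground-truth [clustering()] per dataset), `truth`
#'   (data.frame dataset_id, cluster, archetype), `archetypes` (genes x
#'   n_archetypes matrix) and `config`.
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  g <- config$n_genes
  arch <- matrix(stats::rnorm(g * config$n_archetypes,
                              sd = config$archetype_sd),
                 g, config$n_archetypes,
                 dimnames = list(sprintf("g%03d", seq_len(g)),
                                 paste0("A", seq_len(config$n_archetypes))))
  datasets <- vector("list", config$n_datasets)
  clusterings <- vector("list", config$n_datasets)
  truth <- list()
  for (d in seq_len(config$n_datasets)) {
    ds_id <- sprintf("ds%02d", d)
    k <- switch(config$clusters_rule,
                "4" = config$n_archetypes,
                "2-4" = sample(2:config$n_archetypes, 1L),
                "1-4" = sample(1:config$n_archetypes, 1L))
    arch_idx <- sample.int(config$n_archetypes, k)
    sizes <- if (config$cluster_size_rule == "fixed") rep(50L, k)
             else sample.int(100L, k, replace = TRUE)
    mixed <- rep(FALSE, k)
    if (config$noisy_cluster_fraction > 0)
      mixed[sample.int(k, floor(config$noisy_cluster_fraction * k))] <- TRUE
    cols <- list(); labels <- integer(0); archetype_of <- character(k)
    for (c in seq_len(k)) {
      if (mixed[c]) {
        draw <- sample.int(config$n_archetypes, sizes[c], replace = TRUE)
        mu <- arch[, draw, drop = FALSE]
        archetype_of[c] <- "mixed"
      } else {
        mu <- arch[, rep(arch_idx[c], sizes[c]), drop = FALSE]
        archetype_of[c] <- colnames(arch)[arch_idx[c]]
      }
      noise <- if (config$noise_sd > 0)
        matrix(stats::rnorm(g * sizes[c], sd = config$noise_sd), g, sizes[c])
      else 0
      cols[[c]] <- mu + noise
      labels <- c(labels, rep(c, sizes[c]))
    }
    values <- do.call(cbind, cols)
    dimnames(values) <- list(rownames(arch),
                             sprintf("%s_s%03d", ds_id, seq_along(labels)))
    datasets[[d]] <- expression_dataset(values, ds_id)
    clusterings[[d]] <- clustering(
      stats::setNames(labels, colnames(values)), ds_id)
    truth[[d]] <- data.frame(dataset_id = ds_id, cluster = seq_len(k),
                             archetype = archetype_of)
  }
  names(clusterings) <- vapply(datasets, `[[`, "", "dataset_id")
  structure(list(collection = new_collection(datasets, rownames(arch)),
                 clusterings = clusterings,
                 truth = do.call(rbind, truth),
                 archetypes = arch, config = config),
            class = "sim_collection")
}

#' Score a network's edges against the simulation truth
#'
#' Over all cross-dataset cluster pairs eligible for an edge (pairs whose two
#' parent datasets do not both carry a single cluster): a true positive is an
#' edge between two clusters of the same archetype; a false positive an edge
#' between different archetypes (a "mixed" cluster differs from everything,
#' including other mixed clusters); false negatives and true negatives are the
#' absent-edge counterparts. When a `meta_cluster_result` is supplied, only
#' edges between nodes retained after community pruning count as present.
#'
#' @param network a `cluster_network`.
#' @param truth the `truth` data.frame of a [simulate_collection()] result.
#' @param meta optional `meta_cluster_result` for post-pruning scoring.
#' @return List with `tp`, `fp`, `fn`, `tn`, `tpr`, `fpr`, `n_eligible`.
#' @export
score_edges <- function(network, truth, meta = NULL) {
  stopifnot(inherits(network, "cluster_network"))
  key <- paste(truth$dataset_id, truth$cluster, sep = "::")
  if (!all(network$nodes$node %in% key))
    stop("truth table does not cover every network node")
  arch <- stats::setNames(truth$archetype, key)
  k_per_ds <- table(truth$dataset_id)
  edges <- network$edges
  if (!is.null(meta)) {
    keep <- edges$from %in% meta$community$node &
      edges$to %in% meta$community$node
    edges <- edges[keep, , drop = FALSE]
  }
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
  present <- edge_key(edges$from, edges$to)
  tp <- fp <- fn <- tn <- 0L
  n <- length(key)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    di <- truth$dataset_id[i]; dj <- truth$dataset_id[j]
    if (di == dj) next
    if (k_per_ds[[di]] == 1L && k_per_ds[[dj]] == 1L) next
    same <- arch[[key[i]]] != "mixed" && arch[[key[i]]] == arch[[key[j]]]
    has_edge <- edge_key(key[i], key[j]) %in% present
    if (same && has_edge) tp <- tp + 1L
    else if (!same && has_edge) fp <- fp + 1L
    else if (same) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       tpr = if (tp + fn > 0) tp / (tp + fn) else 0,
       fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
       n_eligible = tp + fp + fn + tn)
}

replicate_seed <- function(seed, scenario, noise_index, rep) {
  (abs(seed) * 7919L + scenario * 104729L + noise_index * 1299709L +
     rep * 15485863L) %% 2147483647L
}

#' Benchmark the pipeline over scenarios, noise levels and thresholds
#'
#' For every scenario x noise-level replicate, simulates a collection, runs
#' the cross-dataset comparison with the ground-truth clusterings as inputs,
#' then -- for each minimum mean similarity threshold -- builds the network,
#' prunes meta-clusters spanning fewer than `min_datasets` datasets, and
#' scores the surviving edges against the archetype truth. NNF and P value
#' thresholds are held at their defaults (0.7 and 0.01). TPR and FPR are
#' averaged over replicates.
#'
#' @param scenarios scenario ids (default 1:7).
#' @param noise_levels noise standard deviations
#'   (default `seq(0, 2.4, by = 0.4)`).
#' @param sim_thresholds minimum mean similarity grid
#'   (default `c(0, 0.15, 0.3, 0.5, 0.7)`).
#' @param n_reps replicates per cell (default 50).
#' @param n_null null draws per directional P value (default 500).
#' @param nnf_threshold,p_threshold,min_datasets network thresholds
#'   (defaults 0.7, 0.01, 3).
#' @param seed master seed; every replicate derives its own stream from
#'   (seed, scenario, noise index, replicate).
#' @param ... passed to [scenario_config()] (e.g. `n_datasets`, `n_genes`).
#' @return A `sweep_result`: `results` (long data.frame scenario, noise,
#'   threshold, rep, tpr, fpr) and `averaged` (means over replicates).
#' @export
sweep_scenarios <- function(scenarios = 1:7,
                            noise_levels = seq(0, 2.4, by = 0.4),
                            sim_thresholds = c(0, 0.15, 0.3, 0.5, 0.7),
                            n_reps = 50L, n_null = 500L, nnf_threshold = 0.7,
                            p_threshold = 0.01, min_datasets = 3L, seed = 1L,
                            ...) {
  stopifnot(length(noise_levels) >= 1L, length(sim_thresholds) >= 1L,
            n_reps >= 1L)
  rows <- list()
  for (sc in scenarios) for (ni in seq_along(noise_levels)) {
    for (r in seq_len(n_reps)) {
      rs <- replicate_seed(seed, sc, ni, r)
      sim <- simulate_collection(scenario_config(
        sc, noise_sd = noise_levels[ni], seed = rs, ...))
      pairs <- all_pairs(sim$collection, sim$clusterings, n_null = n_null,
                         seed = rs)
      for (thr in sim_thresholds) {
        net <- build_network(pairs, sim_threshold = thr,
                             nnf_threshold = nnf_threshold,
                             p_threshold = p_threshold)
        meta <- if (nrow(net$edges))
          detect_meta_clusters(net, min_datasets = min_datasets) else NULL
        sc_res <- score_edges(net, sim$truth, meta = meta)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, noise = noise_levels[ni], threshold = thr, rep = r,
          tpr = sc_res$tpr, fpr = sc_res$fpr)
      }
    }
  }
  results <- do.call(rbind, rows)
  averaged <- stats::aggregate(cbind(tpr, fpr) ~ scenario + noise + threshold,
                               data = results, FUN = mean)
  averaged <- averaged[order(averaged$scenario, averaged$noise,
                             averaged$threshold), , drop = FALSE]
  rownames(averaged) <- NULL
  structure(list(results = results, averaged = averaged,
                 n_reps = n_reps, n_null = n_null, seed = seed),
            class = "sweep_result")
}
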