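#' Kernel density of the observed mean similarities
#'
#' Gaussian kernel density estimate of all directional mean similarity values
#' (including non-best-fit pairs) over the interval `[-1, 1]`, used to pick
#' the minimum mean similarity threshold by inspecting its local maxima.
#' Bandwidth defaults to Silverman's rule of thumb; the curve is renormalized
#' to integrate to 1 over the evaluation grid.
#'
#' @param x a `pair_table` from [all_pairs()] (its `"sim_values"` attribute is
#'   used), or a numeric vector of similarities. At least 10 finite values are
#'   required.
#' @param bw bandwidth specification passed to [stats::density()]
#'   (default `"nrd0"`, Silverman's rule).
#' @param n_grid number of grid points (default 512).
#' @return A `sim_density` list with `grid`, `density`, `bw`, `n`.
#' @export
similarity_density <- function(x, bw = "nrd0", n_grid = 512L) {
  v <- if (inherits(x, "pair_table")) attr(x, "sim_values") else as.numeric(x)
  v <- v[is.finite(v) & v >= -1 & v <= 1]
  if (length(v) < 10L)
    stop("fewer than 10 similarity values; choose a threshold manually")
  d <- stats::density(v, bw = bw, from = -1, to = 1, n = n_grid)
  step <- diff(d$x[1:2])
  area <- sum((d$y[-1] + d$y[-length(d$y)]) / 2) * step
  structure(list(grid = d$x, density = d$y / area, bw = d$bw, n = length(v)),
            class = "sim_density")
}

local_maxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

#' Suggest a minimum mean similarity threshold from the density curve
#'
#' Returns the similarity location of the smallest-similarity local maximum of
#' the density curve that lies above the baseline (both the peak's similarity
#' location and its density height must exceed `baseline`). All qualifying
#' maxima are reported so alternates can be run when the curve is multimodal.
#' The smallest maximum is preferred because aggressive pruning near a
#' similarity of one is known to discard clusters -- or whole datasets --
#' whose signal is reliable but noisy.
#'
#' @param dens a `sim_density` from [similarity_density()].
#' @param baseline baseline threshold in `[0, 1)` (default 0.1).
#' @return List with `threshold` (the primary suggestion) and `candidates`
#'   (all qualifying peak locations, ascending).
#' @export
suggest_threshold <- function(dens, baseline = 0.1) {
  stopifnot(inherits(dens, "sim_density"), baseline >= 0, baseline < 1)
  peaks <- local_maxima(dens$density)
  ok <- peaks[dens$grid[peaks] > baseline & dens$density[peaks] > baseline]
  if (!length(ok))
    stop("no density peak above the ", baseline,
         " baseline; choose a threshold manually")
  cand <- dens$grid[ok]
  list(threshold = cand[1L], candidates = cand)
}

#' Build the cluster similarity network
#'
#' Assigns an edge to every reciprocal cross-dataset cluster pair whose
#' averaged nearest neighbor fraction, averaged mean similarity, and *both*
#' directional P values pass the thresholds (inclusive: `>=` for NNF and
#' similarity, `<=` for P). The edge weight is the averaged mean similarity.
#' Clusters never receive edges to clusters of their own dataset. Isolated
#' clusters remain in the node table for diagnostics.
#'
#' @param pairs a `pair_table` from [all_pairs()].
#' @param sim_threshold minimum averaged mean similarity.
#' @param nnf_threshold minimum averaged nearest neighbor fraction
#'   (default 0.7).
#' @param p_threshold maximum for each directional P value (default 0.01).
#' @return A `cluster_network`: list with `nodes` (node, dataset_id, cluster,
#'   size), `edges` (from, to, weight), and the thresholds used.
#' @export
build_network <- function(pairs, sim_threshold, nnf_threshold = 0.7,
                          p_threshold = 0.01) {
  stopifnot(inherits(pairs, "pair_table"))
  node_key <- function(ds, cl) paste(ds, cl, sep = "::")
  nodes <- unique(rbind(
    data.frame(node = node_key(pairs$dataset_a, pairs$cluster_a),
               dataset_id = pairs$dataset_a, cluster = pairs$cluster_a,
               size = pairs$size_a),
    data.frame(node = node_key(pairs$dataset_b, pairs$cluster_b),
               dataset_id = pairs$dataset_b, cluster = pairs$cluster_b,
               size = pairs$size_b)))
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL
  keep <- pairs$reciprocal &
    !is.na(pairs$nnf_avg) & pairs$nnf_avg >= nnf_threshold &
    !is.na(pairs$sim_avg) & pairs$sim_avg >= sim_threshold &
    !is.na(pairs$p_a) & pairs$p_a <= p_threshold &
    !is.na(pairs$p_b) & pairs$p_b <= p_threshold
  ed <- pairs[keep, , drop = FALSE]
  edges <- data.frame(from = node_key(ed$dataset_a, ed$cluster_a),
                      to = node_key(ed$dataset_b, ed$cluster_b),
                      weight = ed$sim_avg)
  rownames(edges) <- NULL
  if (nrow(edges) &&
      any(sub("::.*", "", edges$from) == sub("::.*", "", edges$to)))
    stop("internal error: edge joins two clusters of the same dataset")
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(sim = sim_threshold, nnf = nnf_threshold,
                                   p = p_threshold)),
            class = "cluster_network")
}

#' @export
print.cluster_network <- function(x, ...) {
  cat(sprintf("<cluster_network: %d nodes, %d edges (sim >= %.3g, nnf >= %.3g, p <= %.3g)>\n",
              nrow(x$nodes), nrow(x$edges), x$thresholds$sim,
              x$thresholds$nnf, x$thresholds$p))
  invisible(x)
}

#' Detect meta-clusters by Girvan-Newman community detection
#'
#' Runs edge-betweenness (Girvan-Newman) community detection on the weighted
#' cluster network. Edge weights are treated as connection strengths: the
#' betweenness removal sequence uses `1/weight` as the edge distance, and the
#' partition along the resulting dendrogram that maximizes weighted modularity
#' (weights as strengths) is kept. Communities whose clusters span fewer than
#' `min_datasets` unique datasets are then removed; so are isolated clusters.
#' Meta-cluster labels are canonical: communities are numbered by their
#' lexicographically smallest member node, so they do not depend on input
#' order.
#'
#' @param network a `cluster_network` with at least one edge.
#' @param min_datasets minimum unique datasets per retained meta-cluster
#'   (default 3).
#' @param clusterings optional named list of [clustering()] objects; when
#'   supplied, per-sample meta-cluster assignments are derived.
#' @param unweighted ignore edge weights entirely (default `FALSE`).
#' @return A `meta_cluster_result`: `community` (node, dataset_id, cluster,
#'   size, meta_cluster), `removed_nodes`, `datasets_per_meta`,
#'   `sample_assignments` (or `NULL`), `modularity`.
#' @export
detect_meta_clusters <- function(network, min_datasets = 3L,
                                 clusterings = NULL, unweighted = FALSE) {
  stopifnot(inherits(network, "cluster_network"))
  if (nrow(network$edges) == 0L)
    stop("network has no edges; nothing to detect")
  in_graph <- network$nodes$node %in%
    c(network$edges$from, network$edges$to)
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = network$nodes[in_graph, "node", drop = FALSE])
  w <- if (unweighted) NULL else igraph::E(g)$weight
  comm <- igraph::cluster_edge_betweenness(
    g, weights = if (is.null(w)) NULL else 1 / w,
    modularity = FALSE, membership = FALSE)
  n_nodes <- igraph::vcount(g)
  cut_range <- seq(igraph::count_components(g), n_nodes)  # cannot merge components
  qs <- vapply(cut_range, function(s) {
    igraph::modularity(g, igraph::cut_at(comm, no = s), weights = w)
  }, 0)
  memb <- igraph::cut_at(comm, no = cut_range[which.max(qs)])
  names(memb) <- igraph::V(g)$name

  com <- network$nodes
  com$meta_cluster <- memb[com$node]            # NA for isolated nodes
  per_com <- split(com, com$meta_cluster)
  ok <- vapply(per_com, function(d)
    length(unique(d$dataset_id)) >= min_datasets, TRUE)
  removed <- c(com$node[is.na(com$meta_cluster)],
               unlist(lapply(per_com[!ok], `[[`, "node"), use.names = FALSE))
  com <- com[!is.na(com$meta_cluster) &
               com$meta_cluster %in% names(per_com)[ok], , drop = FALSE]
  # canonical numbering: by lexicographically smallest member node
  if (nrow(com)) {
    anchor <- vapply(split(com$node, com$meta_cluster), min, "")
    relab <- stats::setNames(rank(anchor), names(anchor))
    com$meta_cluster <- as.integer(relab[as.character(com$meta_cluster)])
    com <- com[order(com$meta_cluster, com$node), , drop = FALSE]
  }
  rownames(com) <- NULL
  datasets_per_meta <- if (nrow(com))
    vapply(split(com$dataset_id, com$meta_cluster),
           function(d) length(unique(d)), 0L) else integer()
  sample_assignments <- NULL
  if (!is.null(clusterings) && nrow(com)) {
    sample_assignments <- do.call(rbind, lapply(seq_len(nrow(com)), function(i) {
      cl <- clusterings[[com$dataset_id[i]]]
      ids <- names(cl$labels)[cl$labels == com$cluster[i]]
      data.frame(dataset_id = com$dataset_id[i], sample_id = ids,
                 meta_cluster = com$meta_cluster[i])
    }))
    rownames(sample_assignments) <- NULL
  }
  structure(list(community = com, removed_nodes = sort(removed),
                 datasets_per_meta = datasets_per_meta,
                 sample_assignments = sample_assignments,
                 modularity = max(qs)),
            class = "meta_cluster_result")
}

#' @export
print.meta_cluster_result <- function(x, ...) {
  cat(sprintf("<meta_cluster_result: %d meta-clusters over %d retained clusters (%d removed)>\n",
              length(x$datasets_per_meta), nrow(x$community),
              length(x$removed_nodes)))
  invisible(x)
}

#' Export a cluster network and its meta-clusters to disk
#'
#' Writes an edge-list TSV, a node-attribute TSV (dataset, cluster, size,
#' meta-cluster), a per-sample subtype TSV when sample assignments exist, and
#' a GraphML file readable by standard network tools.
#'
#' @param network a `cluster_network`.
#' @param meta a `meta_cluster_result` for the same network.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, meta, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             nodes = file.path(dir, "nodes.tsv"),
             graphml = file.path(dir, "network.graphml"))
  utils::write.table(network$edges, paths[["edges"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nodes <- network$nodes
  nodes$meta_cluster <- meta$community$meta_cluster[
    match(nodes$node, meta$community$node)]
  utils::write.table(nodes, paths[["nodes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  if (!is.null(meta$sample_assignments)) {
    paths <- c(paths, samples = file.path(dir, "sample_subtypes.tsv"))
    utils::write.table(meta$sample_assignments, paths[["samples"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
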