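#' Write one expression dataset as a delimited matrix
#'
#' @param dataset an `expression_dataset`.
#' @param path output file; first column `gene`, header row = sample ids.
#' @param delimiter field separator (default tab).
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(dataset, path, delimiter = "\t") {
  df <- data.frame(gene = rownames(dataset$values), dataset$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

default_run_config <- function() {
  list(delimiter = "\t", log2 = FALSE, min_coverage = 0.7,
       feature_set_file = NULL, n_global = 200L, n_intra = 20L,
       exclude_file = NULL, labels_dir = NULL,
       k_min = 2L, k_max = 6L, n_resamples = 100L, subsample_fraction = 0.9,
       allow_k1 = FALSE, n_null = 500L, min_shared_genes = 10L,
       sim_threshold = "auto", density_baseline = 0.1, nnf_threshold = 0.7,
       p_threshold = 0.01, min_datasets = 3L,
       markers = FALSE, marker_threshold = 0.5, marker_method = "fixed",
       seed = 1L)
}

#' Run the whole subtype-discovery pipeline
#'
#' Orchestrates load -> harmonize -> feature selection -> per-dataset
#' consensus clustering -> cross-dataset comparison -> threshold selection ->
#' network -> meta-clusters (-> markers), writing every intermediate artifact
#' and a JSON manifest with checksums to `out_dir`. Reruns with the same
#' config and seed reproduce the artifacts exactly.
#'
#' @param config a list, or the path of a YAML file, with at least `datasets`
#'   (vector of matrix file paths). Optional keys and their defaults:
#'   `delimiter` ("\t"), `log2` (FALSE), `feature_set_file` (NULL: use the
#'   meta-rank gene set), `n_global` (200), `n_intra` (20), `exclude_file`
#'   (NULL), `min_coverage` (0.7), `labels_dir` (NULL: directory of
#'   `<dataset_id>.tsv` files with columns sample_id, cluster, bypassing the
#'   clustering step), `k_min` (2), `k_max` (6), `n_resamples` (100),
#'   `subsample_fraction` (0.9), `allow_k1` (FALSE), `n_null` (500),
#'   `min_shared_genes` (10), `sim_threshold` ("auto"), `density_baseline`
#'   (0.1), `nnf_threshold` (0.7), `p_threshold` (0.01), `min_datasets` (3),
#'   `markers` (FALSE), `marker_threshold` (0.5), `marker_method` ("fixed"),
#'   `seed` (1).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$datasets)) stop("config must list dataset file paths")
  missing <- cfg$datasets[!file.exists(cfg$datasets)]
  if (length(missing)) stop("missing dataset file: ", missing[1L])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  add_file <- function(path) files <<- c(files, path)

  coll <- load_collection(cfg$datasets, delimiter = cfg$delimiter,
                          log2 = cfg$log2)
  message(sprintf("loaded %d datasets", length(coll$datasets)))

  exclude <- if (!is.null(cfg$exclude_file))
    readLines(cfg$exclude_file) else character()
  feature_set <- if (!is.null(cfg$feature_set_file)) {
    readLines(cfg$feature_set_file)
  } else {
    meta_rank(coll, n_global = cfg$n_global, n_intra = cfg$n_intra,
              exclude = exclude)
  }
  coll <- harmonize(coll, feature_set, min_coverage = cfg$min_coverage)
  gene_file <- file.path(out_dir, "genes.txt")
  writeLines(coll$feature_set, gene_file); add_file(gene_file)
  rep_file <- file.path(out_dir, "harmonization.tsv")
  utils::write.table(harmonization_report(coll), rep_file, sep = "\t",
                     quote = FALSE, row.names = FALSE); add_file(rep_file)

  clusterings <- lapply(coll$datasets, function(d) {
    if (!is.null(cfg$labels_dir)) {
      lf <- file.path(cfg$labels_dir, paste0(d$dataset_id, ".tsv"))
      lab <- utils::read.table(lf, sep = "\t", header = TRUE)
      clustering(stats::setNames(lab$cluster, lab$sample_id), d$dataset_id)
    } else {
      select_k(d, k_range = cfg$k_min:cfg$k_max,
               n_resamples = cfg$n_resamples,
               subsample_fraction = cfg$subsample_fraction,
               allow_k1 = cfg$allow_k1,
               seed = pair_seed(cfg$seed, d$dataset_id, "cluster"))
    }
  })
  clus_file <- file.path(out_dir, "clusters.tsv")
  clus_df <- do.call(rbind, lapply(clusterings, function(cl)
    data.frame(dataset_id = cl$dataset_id, sample_id = names(cl$labels),
               cluster = cl$labels)))
  rownames(clus_df) <- NULL
  utils::write.table(clus_df, clus_file, sep = "\t", quote = FALSE,
                     row.names = FALSE); add_file(clus_file)
  pac_file <- file.path(out_dir, "pac_by_k.json")
  jsonlite::write_json(lapply(clusterings, `[[`, "pac_by_k"), pac_file,
                       auto_unbox = FALSE, digits = NA); add_file(pac_file)
  message(sprintf("clustered: %s clusters total",
                  sum(vapply(clusterings, `[[`, 0L, "k"))))

  pairs <- all_pairs(coll, clusterings, n_null = cfg$n_null, seed = cfg$seed,
                     min_shared_genes = cfg$min_shared_genes)
  pairs_file <- file.path(out_dir, "pairs.tsv")
  utils::write.table(as.data.frame(pairs), pairs_file, sep = "\t",
                     quote = FALSE, row.names = FALSE); add_file(pairs_file)
  message(sprintf("%d cluster pairs, %d reciprocal", nrow(pairs),
                  sum(pairs$reciprocal)))

  dens <- similarity_density(pairs)
  dens_file <- file.path(out_dir, "similarity_density.tsv")
  utils::write.table(data.frame(similarity = dens$grid,
                                density = dens$density),
                     dens_file, sep = "\t", quote = FALSE,
                     row.names = FALSE); add_file(dens_file)
  sim_thr <- cfg$sim_threshold
  if (identical(sim_thr, "auto")) {
    sim_thr <- suggest_threshold(dens, baseline = cfg$density_baseline)$threshold
    message(sprintf("auto similarity threshold: %.3f", sim_thr))
  }

  net <- build_network(pairs, sim_threshold = sim_thr,
                       nnf_threshold = cfg$nnf_threshold,
                       p_threshold = cfg$p_threshold)
  meta <- detect_meta_clusters(net, min_datasets = cfg$min_datasets,
                               clusterings = clusterings)
  net_paths <- export_network(net, meta, file.path(out_dir, "network"))
  for (p in net_paths) add_file(p)
  meta_file <- file.path(out_dir, "meta_clusters.tsv")
  utils::write.table(meta$community, meta_file, sep = "\t", quote = FALSE,
                     row.names = FALSE); add_file(meta_file)
  message(sprintf("%d edges -> %d meta-clusters (%d clusters removed)",
                  nrow(net$edges), length(meta$datasets_per_meta),
                  length(meta$removed_nodes)))

  if (isTRUE(cfg$markers)) {
    mk <- marker_table(coll, clusterings, meta, method = cfg$marker_method)
    mk_file <- file.path(out_dir, "markers.tsv")
    utils::write.table(mk, mk_file, sep = "\t", quote = FALSE,
                       row.names = FALSE); add_file(mk_file)
  }

  manifest <- list(
    package = "crossclust",
    version = as.character(utils::packageVersion("crossclust")),
    seed = cfg$seed,
    thresholds = list(sim = sim_thr, nnf = cfg$nnf_threshold,
                      p = cfg$p_threshold, min_datasets = cfg$min_datasets),
    counts = list(n_datasets = length(coll$datasets),
                  n_genes = length(coll$feature_set),
                  n_clusters = sum(vapply(clusterings, `[[`, 0L, "k")),
                  n_reciprocal_pairs = sum(pairs$reciprocal),
                  n_edges = nrow(net$edges),
                  n_meta_clusters = length(meta$datasets_per_meta)),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
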