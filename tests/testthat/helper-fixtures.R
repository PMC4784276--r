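# Fixtures are generated in code; no data files are shipped.

# Dataset from a bare matrix, auto-labelling genes/samples when unnamed.
make_ds <- function(values, id = "ds1") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("%s_s%03d", id, seq_len(ncol(values)))
  expression_dataset(values, id)
}

rand_ds <- function(g = 20, n = 10, id = "ds1", sd = 1) {
  make_ds(matrix(rnorm(g * n, sd = sd), g, n), id)
}

# Well-separated Gaussian blobs (samples as columns); returns dataset + truth.
make_blobs <- function(k = 2, n_per = 10, g = 30, sep = 6, noise = 0.3,
                       id = "blobs") {
  centers <- matrix(rnorm(g * k, sd = sep / sqrt(2 * g) * sqrt(g)), g, k)
  # rescale so pairwise center distances ~ sep
  centers <- centers / mean(dist(t(centers))) * sep
  labels <- rep(seq_len(k), each = n_per)
  values <- centers[, labels] + matrix(rnorm(g * k * n_per, sd = noise),
                                       g, k * n_per)
  ds <- make_ds(values, id)
  list(dataset = ds, labels = stats::setNames(labels, colnames(ds$values)))
}

new_collection_for_test <- function(datasets, feature_set = NULL) {
  if (is.null(feature_set))
    feature_set <- sort(unique(unlist(lapply(datasets, function(d)
      rownames(d$values)))))
  crossclust:::new_collection(datasets, feature_set)
}

# Synthetic centroid set (not derived from data); center defaults to origin.
synthetic_centroid_set <- function(C, center = NULL, id = "ref") {
  if (is.null(rownames(C))) rownames(C) <- sprintf("g%03d", seq_len(nrow(C)))
  if (is.null(center)) center <- stats::setNames(rep(0, nrow(C)), rownames(C))
  structure(list(dataset_id = id, genes = rownames(C), centroids = C,
                 center = center, sizes = rep(10L, ncol(C))),
            class = "centroid_set")
}

# Minimal pair_table for network-level tests.
make_pair_table <- function(df) {
  need <- c("dataset_a", "cluster_a", "size_a", "dataset_b", "cluster_b",
            "size_b", "reciprocal", "nnf_avg", "sim_avg", "p_a", "p_b",
            "sim_a_to_b", "sim_b_to_a", "nnf_a_to_b", "nnf_b_to_a",
            "n_shared_genes")
  defaults <- list(size_a = 10L, size_b = 10L, reciprocal = TRUE,
                   nnf_avg = 1, p_a = 0, p_b = 0, sim_a_to_b = NA_real_,
                   sim_b_to_a = NA_real_, nnf_a_to_b = NA_real_,
                   nnf_b_to_a = NA_real_, n_shared_genes = 30L)
  for (col in need) if (is.null(df[[col]])) {
    if (is.null(defaults[[col]])) stop("missing column ", col)
    df[[col]] <- defaults[[col]]
  }
  attr(df, "sim_values") <- df$sim_avg
  class(df) <- c("pair_table", "data.frame")
  df
}
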