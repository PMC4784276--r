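test_that("the similarity density is a proper density with faithful modes", {
  d <- similarity_density(rep(0.4, 25))
  expect_equal(d$grid[which.max(d$density)], 0.4, tolerance = 0.02)
  step <- diff(d$grid[1:2])
  area <- sum((d$density[-1] + d$density[-length(d$density)]) / 2) * step
  expect_equal(area, 1, tolerance = 1e-6)

  set.seed(61)
  bim <- c(rnorm(120, 0.1, 0.02), rnorm(120, 0.6, 0.02))
  db <- similarity_density(bim)
  peaks <- db$grid[crossclust:::local_maxima(db$density)]
  main <- peaks[db$density[crossclust:::local_maxima(db$density)] > 0.5]
  expect_length(main, 2L)
  expect_equal(main, c(0.1, 0.6), tolerance = 0.05)
  expect_error(similarity_density(rep(0.2, 5)), "fewer than 10")
})

test_that("threshold suggestion returns the smallest qualifying peak", {
  set.seed(62)
  uni <- similarity_density(rnorm(200, 0.5, 0.05))
  expect_equal(suggest_threshold(uni)$threshold, 0.5, tolerance = 0.05)
  two <- similarity_density(c(rnorm(150, 0.5, 0.04), rnorm(150, 0.7, 0.03)))
  s <- suggest_threshold(two)
  expect_equal(s$threshold, 0.5, tolerance = 0.05)
  expect_length(s$candidates, 2L)
  expect_equal(sort(s$candidates), c(0.5, 0.7), tolerance = 0.05)
  low <- similarity_density(rnorm(200, -0.5, 0.05))
  expect_error(suggest_threshold(low), "no density peak")
})

test_that("edges require reciprocity and every threshold inclusively", {
  pt <- make_pair_table(data.frame(
    dataset_a = "d1", cluster_a = 1:4, dataset_b = "d2", cluster_b = 1:4,
    reciprocal = c(TRUE, TRUE, TRUE, FALSE),
    nnf_avg = c(0.69, 0.70, 0.90, 0.95),
    sim_avg = c(0.80, 0.30, 0.80, 0.90),
    p_a = c(0.005, 0.01, 0.005, 0.001),
    p_b = c(0.005, 0.01, 0.02, 0.001)))
  net <- build_network(pt, sim_threshold = 0.3, nnf_threshold = 0.7,
                       p_threshold = 0.01)
  # row 1: nnf 0.69 < 0.7 fails; row 2: all exactly at thresholds passes;
  # row 3: p_b 0.02 fails (both P values must pass); row 4: not reciprocal
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$from, "d1::2")
  expect_equal(net$edges$weight, 0.3)
  expect_equal(nrow(net$nodes), 8L)       # isolated nodes kept for diagnostics
})

test_that("raising the similarity threshold never adds edges", {
  set.seed(63)
  pt <- make_pair_table(data.frame(
    dataset_a = "d1", cluster_a = 1:30,
    dataset_b = "d2", cluster_b = sample(1:30),
    reciprocal = runif(30) < 0.8, nnf_avg = runif(30, 0.5, 1),
    sim_avg = runif(30, -0.2, 1), p_a = runif(30, 0, 0.05),
    p_b = runif(30, 0, 0.05)))
  prev <- NULL
  for (thr in c(0, 0.25, 0.5, 0.75, 1)) {
    e <- build_network(pt, thr)$edges
    key <- paste(e$from, e$to)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("two bridged 4-cliques resolve into exactly the two cliques", {
  nodes <- sprintf("d%d::1", 1:8)
  clique <- function(idx) t(combn(idx, 2))
  ed <- rbind(clique(1:4), clique(5:8), c(4, 5))      # one bridge edge
  pt <- make_pair_table(data.frame(
    dataset_a = sprintf("d%d", ed[, 1]), cluster_a = 1L,
    dataset_b = sprintf("d%d", ed[, 2]), cluster_b = 1L,
    sim_avg = 0.8))
  net <- build_network(pt, 0.5)
  meta <- detect_meta_clusters(net, min_datasets = 3)
  expect_length(meta$datasets_per_meta, 2L)
  memb <- stats::setNames(meta$community$meta_cluster, meta$community$node)
  expect_length(unique(memb[nodes[1:4]]), 1L)
  expect_length(unique(memb[nodes[5:8]]), 1L)
  expect_false(memb[[nodes[1]]] == memb[[nodes[5]]])
})

test_that("communities below the dataset-count floor are pruned", {
  # triangle over 3 datasets + a 2-dataset pair, disconnected from each other
  pt <- make_pair_table(data.frame(
    dataset_a = c("d1", "d1", "d2", "d4"), cluster_a = c(1L, 1L, 1L, 1L),
    dataset_b = c("d2", "d3", "d3", "d5"), cluster_b = c(1L, 1L, 1L, 1L),
    sim_avg = 0.8))
  net <- build_network(pt, 0.5)
  meta <- detect_meta_clusters(net, min_datasets = 3)
  expect_length(meta$datasets_per_meta, 1L)
  expect_setequal(meta$removed_nodes, c("d4::1", "d5::1"))
  expect_setequal(meta$community$node, c("d1::1", "d2::1", "d3::1"))
  # disconnected components are never merged
  meta2 <- detect_meta_clusters(net, min_datasets = 2)
  expect_length(meta2$datasets_per_meta, 2L)
})

test_that("meta-cluster labels do not depend on pair-table row order", {
  set.seed(64)
  pt_df <- data.frame(
    dataset_a = c("d1", "d1", "d2", "d4", "d4", "d5"),
    cluster_a = 1L,
    dataset_b = c("d2", "d3", "d3", "d5", "d6", "d6"),
    cluster_b = 1L, sim_avg = c(0.9, 0.8, 0.7, 0.9, 0.8, 0.7))
  m1 <- detect_meta_clusters(build_network(make_pair_table(pt_df), 0.5))
  shuf <- pt_df[sample(nrow(pt_df)), ]
  m2 <- detect_meta_clusters(build_network(make_pair_table(shuf), 0.5))
  expect_equal(m1$community, m2$community)
})

test_that("no edge ever joins clusters of the same dataset", {
  set.seed(65)
  sim <- simulate_collection(scenario_config(1, n_datasets = 4, n_genes = 30,
                                             noise_sd = 0.8, seed = 31))
  pairs <- all_pairs(sim$collection, sim$clusterings, n_null = 30, seed = 66)
  expect_true(all(pairs$dataset_a != pairs$dataset_b))
  net <- build_network(pairs, 0.3)
  expect_true(all(sub("::.*", "", net$edges$from) !=
                    sub("::.*", "", net$edges$to)))
  expect_error(detect_meta_clusters(build_network(pairs, 1.01)), "no edges")
})

test_that("sample assignments cover exactly the retained clusters' samples", {
  set.seed(67)
  sim <- simulate_collection(scenario_config(1, n_datasets = 4, n_genes = 30,
                                             noise_sd = 0.5, seed = 37))
  pairs <- all_pairs(sim$collection, sim$clusterings, n_null = 30, seed = 68)
  net <- build_network(pairs, 0.3)
  meta <- detect_meta_clusters(net, clusterings = sim$clusterings)
  expected <- sum(vapply(seq_len(nrow(meta$community)), function(i) {
    cl <- sim$clusterings[[meta$community$dataset_id[i]]]
    sum(cl$labels == meta$community$cluster[i])
  }, 0L))
  expect_equal(nrow(meta$sample_assignments), expected)
  expect_true(all(meta$datasets_per_meta >= 3L))
})
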