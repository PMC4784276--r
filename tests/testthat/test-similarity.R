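test_that("centroids are per-cluster means, including singleton clusters", {
  vals <- cbind(s1 = c(1, 3), s2 = c(3, 5), s3 = c(10, 20))
  rownames(vals) <- c("gA", "gB")
  d <- expression_dataset(vals, "d")
  cl <- clustering(c(s1 = 1, s2 = 1, s3 = 2), "d")
  cs <- compute_centroids(d, cl)
  expect_equal(unname(cs$centroids[, 1L]), c(2, 4))
  expect_equal(unname(cs$centroids[, 2L]), c(10, 20))  # singleton = profile
  expect_equal(cs$sizes, c(2L, 1L))

  set.seed(41)
  for (case in 1:20) {
    d <- rand_ds(8, 12)
    lab <- stats::setNames(sample(rep(1:3, length.out = 12)),
                           colnames(d$values))
    cs <- compute_centroids(d, clustering(lab, "ds1"))
    for (c in 1:3) {
      mem <- names(lab)[lab == c]
      oracle <- apply(d$values[, mem, drop = FALSE], 1L, mean)
      expect_equal(unname(cs$centroids[, c]), unname(oracle))
    }
    expect_equal(cs$center, rowMeans(d$values))
  }
})

test_that("nearest-centroid assignment maximizes Pearson correlation", {
  set.seed(42)
  C <- matrix(rnorm(60), 20, 3)
  ref <- synthetic_centroid_set(C)
  # a sample equal to centroid 2 is assigned there with correlation 1
  q <- make_ds(C[, 2L, drop = FALSE], "q")
  a <- assign_nearest(q, ref)
  expect_equal(unname(a$assignment), 2L)
  expect_equal(unname(a$correlations[1L, 2L]), 1)
  # anti-correlated sample with a single centroid: argmax over a singleton
  ref1 <- synthetic_centroid_set(C[, 1L, drop = FALSE])
  qneg <- make_ds(-C[, 1L, drop = FALSE], "q")
  a1 <- assign_nearest(qneg, ref1)
  expect_equal(unname(a1$assignment), 1L)
  expect_equal(unname(a1$correlations[1L, 1L]), -1)
})

test_that("assignment matches a brute-force cor() argmax oracle", {
  set.seed(43)
  for (case in 1:100) {
    g <- sample(10:25, 1)
    C <- matrix(rnorm(g * 3), g, 3)
    X <- matrix(rnorm(g * 5), g, 5)
    ref <- synthetic_centroid_set(C)
    q <- make_ds(X, "q")
    got <- assign_nearest(q, ref)
    for (i in 1:5) {
      cors <- vapply(1:3, function(j) cor(X[, i], C[, j]), 0)
      expect_equal(unname(got$assignment[i]), which.max(cors))
      expect_equal(unname(got$correlations[i, ]), cors)
    }
  }
})

test_that("constant vectors are never nearest and degenerate cases error", {
  C <- cbind(rep(1, 10), rnorm(10))      # centroid 1 constant
  ref <- synthetic_centroid_set(C)
  q <- make_ds(matrix(C[, 2L] + rnorm(10, sd = 0.01), 10, 1), "q")
  expect_warning(a <- assign_nearest(q, ref), "constant centroid")
  expect_equal(unname(a$assignment), 2L)
  flat <- make_ds(matrix(1, 10, 2), "flat")
  refflat <- synthetic_centroid_set(cbind(rep(2, 10), rep(3, 10)))
  expect_error(suppressWarnings(assign_nearest(flat, refflat)),
               "all vectors constant")
  expect_error(assign_nearest(q, ref, min_shared_genes = 11), "shared genes")
})

test_that("a query cluster identical to a reference cluster matches perfectly", {
  set.seed(44)
  sim <- simulate_collection(scenario_config(1, n_datasets = 3, n_genes = 40,
                                             noise_sd = 0.3, seed = 9))
  d1 <- sim$collection$datasets$ds01
  ref <- compute_centroids(d1, sim$clusterings$ds01)
  twin <- expression_dataset(d1$values, "twin")
  dc <- directional_compare(twin, sim$clusterings$ds01, cluster = 2L,
                            reference = ref, n_null = 50, seed = 45)
  expect_equal(dc$best_reference_cluster, 2L)
  expect_equal(dc$nnf, 1)
  expect_gt(dc$mean_sim, 0.9)
  expect_equal(dc$p_value, 0)
})

test_that("null centroid sets preserve geometry about the data center", {
  set.seed(46)
  for (draw in 1:20) {
    g <- 15; k <- 4
    C <- matrix(rnorm(g * k), g, k)
    center <- stats::setNames(rnorm(g), sprintf("g%03d", 1:g))
    ref <- synthetic_centroid_set(C, center = center)
    N <- null_centroid_set(ref)
    expect_equal(dim(N), dim(C))
    expect_equal(as.numeric(dist(t(N))), as.numeric(dist(t(C))),
                 tolerance = 1e-8)
    expect_equal(sqrt(colSums((N - center)^2)),
                 sqrt(colSums((C - center)^2)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(null_centroid_set(synthetic_centroid_set(
    matrix(1:2, 1, 2, dimnames = list("g1", NULL)))), "fewer than 2 genes")
})

test_that("the compiled null sampler reproduces the R reference construction", {
  set.seed(47)
  g <- 25; k <- 3; m <- 8
  C <- matrix(rnorm(g * k), g, k, dimnames = list(sprintf("g%03d", 1:g), NULL))
  ref <- synthetic_centroid_set(C)
  X <- matrix(rnorm(g * m), g, m, dimnames = list(rownames(C), NULL))
  labels <- rep(1:2, c(3, 5))
  n_null <- 10L
  set.seed(48)
  fast <- crossclust:::null_stats(X, labels, 2L, ref, ref$genes, n_null)
  # R oracle: same RNG stream, explicit rotation + correlation argmax per draw
  set.seed(48)
  for (it in seq_len(n_null)) {
    N <- null_centroid_set(ref)
    S <- crossclust:::col_cor(X, N)
    st <- crossclust:::dir_stats(S, labels, 2L, k)
    expect_equal(fast$sim[it, ], st$sim, tolerance = 1e-8)
    expect_equal(fast$nnf[it, ], st$nnf, tolerance = 1e-12)
  }
})

test_that("a perfect observed match cannot be exceeded: p = 0", {
  set.seed(49)
  C <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("g%03d", 1:20), NULL))
  ref <- synthetic_centroid_set(C)
  X <- C[, c(1, 1, 1)] ; colnames(X) <- paste0("s", 1:3)
  expect_equal(null_pvalue(X, ref, observed_nnf = 1, observed_sim = 1,
                           n_null = 100), 0)
})

test_that("all_pairs marks twin datasets fully reciprocal with nnf 1", {
  set.seed(51)
  sim <- simulate_collection(scenario_config(1, n_datasets = 3, n_genes = 40,
                                             noise_sd = 0.3, seed = 14))
  d1 <- sim$collection$datasets$ds01
  twin <- expression_dataset(
    `colnames<-`(d1$values, sub("ds01", "tw", colnames(d1$values))), "tw")
  cl_twin <- clustering(stats::setNames(
    sim$clusterings$ds01$labels,
    sub("ds01", "tw", names(sim$clusterings$ds01$labels))), "tw")
  coll <- new_collection_for_test(list(d1, twin))
  pairs <- all_pairs(coll, list(ds01 = sim$clusterings$ds01, tw = cl_twin),
                     n_null = 30, seed = 52)
  twins <- pairs[pairs$cluster_a == pairs$cluster_b, ]
  expect_true(all(twins$reciprocal))
  expect_equal(twins$nnf_avg, rep(1, 4))
  expect_true(all(twins$sim_avg > 0.9))
  off <- pairs[pairs$cluster_a != pairs$cluster_b, ]
  expect_false(any(off$reciprocal))
})

test_that("reciprocity equals brute-force mutual argmax of directional tables", {
  set.seed(53)
  sim <- simulate_collection(scenario_config(3, n_datasets = 3, n_genes = 30,
                                             noise_sd = 1, seed = 19))
  pairs <- all_pairs(sim$collection, sim$clusterings, n_null = 20, seed = 54)
  cents <- lapply(names(sim$clusterings), function(id)
    compute_centroids(sim$collection$datasets[[id]], sim$clusterings[[id]]))
  names(cents) <- names(sim$clusterings)
  best_of <- function(qry, ref, cl) {
    # independent route: per-sample cor loop, majority vote
    labs <- sim$clusterings[[qry]]$labels
    d <- sim$collection$datasets[[qry]]
    votes <- table(factor(vapply(names(labs)[labs == cl], function(s) {
      which.max(vapply(seq_len(ncol(cents[[ref]]$centroids)), function(j)
        cor(d$values[, s], cents[[ref]]$centroids[, j]), 0))
    }, 0L), levels = seq_len(ncol(cents[[ref]]$centroids))))
    as.integer(which.max(votes))
  }
  for (r in seq_len(nrow(pairs))) {
    expected <- best_of(pairs$dataset_b[r], pairs$dataset_a[r],
                        pairs$cluster_b[r]) == pairs$cluster_a[r] &&
      best_of(pairs$dataset_a[r], pairs$dataset_b[r],
              pairs$cluster_a[r]) == pairs$cluster_b[r]
    expect_equal(pairs$reciprocal[r], expected)
  }
})

test_that("all_pairs output is invariant to dataset order and skips 1-vs-1", {
  set.seed(55)
  sim <- simulate_collection(scenario_config(4, n_datasets = 4, n_genes = 30,
                                             noise_sd = 0.5, seed = 23))
  ks <- vapply(sim$clusterings, `[[`, 0L, "k")
  coll <- sim$collection
  rev_coll <- new_collection_for_test(rev(unname(coll$datasets)),
                                      coll$feature_set)
  p1 <- all_pairs(coll, sim$clusterings, n_null = 20, seed = 56)
  p2 <- all_pairs(rev_coll, rev(sim$clusterings), n_null = 20, seed = 56)
  strip <- function(p) { d <- as.data.frame(p); attributes(d) <-
    attributes(d)[c("names", "row.names", "class")]; d }
  expect_equal(strip(p1), strip(p2))
  expect_equal(sort(attr(p1, "sim_values")), sort(attr(p2, "sim_values")))
  expect_true(all(p1$p_a >= 0 & p1$p_a <= 1, na.rm = TRUE))
  expect_true(all(p1$nnf_avg >= 0 & p1$nnf_avg <= 1, na.rm = TRUE))
  expect_true(all(p1$sim_a_to_b >= -1 & p1$sim_a_to_b <= 1))
  if (sum(ks == 1L) >= 2L) {
    singles <- names(ks)[ks == 1L]
    expect_equal(sum(p1$dataset_a %in% singles & p1$dataset_b %in% singles), 0L)
  }
})
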