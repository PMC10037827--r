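test_that("binarization retains the expected edge count", {
  set.seed(501)
  W <- random_weight_matrix(10)
  g <- binarize_at_sparsity(W, 0.20)
  expect_equal(g$n_edges, 9)  # round(0.2 * 45)
  expect_equal(sum(g$adjacency) / 2, 9)
  full <- binarize_at_sparsity(W, 1)
  expect_equal(full$n_edges, 45)
  expect_true(all(full$adjacency[upper.tri(full$adjacency)] == 1))
  expect_error(binarize_at_sparsity(W, 0.001), class = "hippnet_error_degenerate")
  expect_error(binarize_at_sparsity(W, 1.5), class = "hippnet_error_range")
})

test_that("binarization keeps exactly the top-k weights, ties broken lexicographically", {
  set.seed(502)
  for (rep in 1:5) {
    W <- random_weight_matrix(12)
    s <- runif(1, 0.2, 0.8)
    g <- binarize_at_sparsity(W, s)
    k <- g$n_edges
    w <- sort(W[upper.tri(W)], decreasing = TRUE)
    kept_w <- sort(W[upper.tri(W) & g$adjacency == 1], decreasing = TRUE)
    expect_equal(kept_w, w[seq_len(k)])
  }
  # tied weights: the lexicographically first index pairs win
  Wt <- matrix(0.5, 4, 4); diag(Wt) <- NA
  gt <- binarize_at_sparsity(Wt, 0.5)  # 3 of 6 possible edges
  expect_equal(which(gt$adjacency[upper.tri(gt$adjacency)] == 1), c(1, 2, 4))
  # identical matrix gives identical adjacency on repeat
  expect_identical(gt$adjacency, binarize_at_sparsity(Wt, 0.5)$adjacency)
})

test_that("path and triangle metrics match brute-force oracles on random graphs", {
  set.seed(503)
  for (rep in 1:12) {
    n <- sample(6:20, 1)
    A <- random_adjacency(n, runif(1, 0.15, 0.6))
    if (sum(A) == 0) next
    expect_equal(clustering_coefficient(A), oracle_cp(A), tolerance = 1e-10)
    expect_equal(characteristic_path_length(A), oracle_lp(A), tolerance = 1e-10)
    expect_equal(global_efficiency(A), oracle_eglobal(A), tolerance = 1e-10)
    expect_equal(local_efficiency(A), oracle_elocal(A), tolerance = 1e-10)
    a_pkg <- assortativity(A)
    a_orc <- oracle_assortativity(A)
    if (is.na(a_orc)) expect_true(is.na(a_pkg))
    else expect_equal(a_pkg, a_orc, tolerance = 1e-10)
    h_pkg <- hierarchy(A)
    h_orc <- oracle_hierarchy(A)
    if (is.na(h_orc)) expect_true(is.na(h_pkg))
    else expect_equal(h_pkg, h_orc, tolerance = 1e-10)
    expect_equal(synchronization(A), oracle_synchronization(A), tolerance = 1e-8)
  }
})

test_that("closed-form graphs give their textbook metric values", {
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(clustering_coefficient(K3), 1)
  expect_equal(characteristic_path_length(K3), 1)
  expect_equal(global_efficiency(K3), 1)

  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 1; P3 <- P3 + t(P3)
  expect_equal(clustering_coefficient(P3), 0)
  expect_equal(characteristic_path_length(P3), 4 / 3)
  expect_equal(global_efficiency(P3), 5 / 6)
  expect_equal(synchronization(P3), 1 / 3)  # Laplacian spectrum {0, 1, 3}

  P4 <- matrix(0, 4, 4); P4[1, 2] <- P4[2, 3] <- P4[3, 4] <- 1; P4 <- P4 + t(P4)
  expect_equal(assortativity(P4), -0.5)

  for (n in c(4, 6, 9)) {
    Kn <- matrix(1, n, n) - diag(n)
    expect_equal(synchronization(Kn), 1)  # eigenvalues {0, n, ..., n}
    expect_true(is.na(assortativity(Kn)))  # all degrees equal
  }
})

test_that("hierarchy returns the sentinel for degree-homogeneous graphs", {
  # ring lattice where every node has degree 2 and clustering 0
  ring <- matrix(0, 6, 6)
  for (i in 1:6) ring[i, i %% 6 + 1] <- 1
  ring <- ring + t(ring)
  expect_true(is.na(hierarchy(ring)))
  # ring lattice with neighbours-of-neighbours: degree 4 everywhere,
  # positive clustering, but zero regressor variance
  ring2 <- matrix(0, 8, 8)
  for (i in 1:8) {
    ring2[i, i %% 8 + 1] <- 1
    ring2[i, (i + 1) %% 8 + 1] <- 1
  }
  ring2 <- ring2 + t(ring2)
  expect_true(all(rowSums(ring2) == 4))
  expect_true(is.na(hierarchy(ring2)))
})

test_that("small-world sigma is 1 on complete graphs and reproducible by seed", {
  K8 <- matrix(1, 8, 8) - diag(8)
  expect_equal(small_world_sigma(K8, n_null = 10, rng_seed = 1), 1)
  set.seed(504)
  A <- random_adjacency(20, 0.3)
  s1 <- small_world_sigma(A, n_null = 20, rng_seed = 42)
  s2 <- small_world_sigma(A, n_null = 20, rng_seed = 42)
  expect_identical(s1, s2)
  s3 <- small_world_sigma(A, n_null = 20, rng_seed = 43)
  expect_false(identical(s1, s3))
})

test_that("a mildly rewired ring lattice sits in the small-world regime", {
  # n = 30, k = 4 neighbours, rewiring probability 0.1
  g <- igraph::sample_smallworld(1, 30, 2, 0.1)
  set.seed(7)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_gt(small_world_sigma(A, n_null = 50, rng_seed = 11), 1)
})

test_that("metrics are invariant under node relabelling", {
  set.seed(505)
  A <- random_adjacency(12, 0.35)
  perm <- sample(12)
  B <- A[perm, perm]
  expect_equal(clustering_coefficient(A), clustering_coefficient(B), tolerance = 1e-12)
  expect_equal(characteristic_path_length(A), characteristic_path_length(B), tolerance = 1e-12)
  expect_equal(global_efficiency(A), global_efficiency(B), tolerance = 1e-12)
  expect_equal(local_efficiency(A), local_efficiency(B), tolerance = 1e-12)
  expect_equal(synchronization(A), synchronization(B), tolerance = 1e-8)
})

test_that("efficiency grows and path length shrinks as edges accumulate", {
  set.seed(506)
  W <- random_weight_matrix(12)
  ss <- seq(0.3, 1, by = 0.1)
  metrics <- lapply(ss, function(s) {
    g <- binarize_at_sparsity(W, s)
    list(eg = global_efficiency(g),
         lp = characteristic_path_length(g),
         connected = igraph::is_connected(g$graph))
  })
  for (i in seq_len(length(ss) - 1)) {
    expect_gte(metrics[[i + 1]]$eg, metrics[[i]]$eg - 1e-12)
    if (metrics[[i]]$connected) {
      expect_lte(metrics[[i + 1]]$lp, metrics[[i]]$lp + 1e-12)
    }
  }
})

test_that("sparsity AUC follows the trapezoid rule with sentinel gaps excluded", {
  grid <- sparsity_grid()
  expect_length(grid, 31)
  expect_equal(as.numeric(auc_over_sparsity(rep(2, 31), grid)), 0.6)
  expect_equal(as.numeric(auc_over_sparsity(grid, grid)), 0.09)

  set.seed(507)
  v <- rnorm(31)
  expect_equal(as.numeric(auc_over_sparsity(v, grid)), oracle_auc(v, grid),
               tolerance = 1e-12)
  v[c(3, 10)] <- NA
  expect_equal(as.numeric(auc_over_sparsity(v, grid)), oracle_auc(v, grid),
               tolerance = 1e-12)
  expect_lt(attr(auc_over_sparsity(v, grid), "coverage"), 1)
  v[1:16] <- NA  # more than half undefined
  expect_true(is.na(auc_over_sparsity(v, grid)))
})

test_that("property curves cover the full metric-by-sparsity grid per subject", {
  co <- generate_cohort(tiny_config())
  fc <- build_fc_matrices(co)
  nodes <- co$nodes$region[co$nodes$hemisphere == "L"]
  curves <- global_property_curves(fc[1:2], nodes = nodes,
                                   sparsities = sparsity_grid(0.2, 0.4, 0.05),
                                   n_null = 10, rng_seed = 5)
  expect_equal(nrow(curves), 2 * 5 * 8)
  expect_setequal(unique(curves$metric),
                  c("assortativity", "hierarchy", "synchronization", "sigma",
                    "cp", "lp", "eglobal", "elocal"))
  auc <- property_auc(curves)
  expect_equal(nrow(auc), 16)
  # identical seed reproduces the sigma curve exactly
  curves2 <- global_property_curves(fc[1:2], nodes = nodes,
                                    sparsities = sparsity_grid(0.2, 0.4, 0.05),
                                    n_null = 10, rng_seed = 5)
  expect_identical(curves$value, curves2$value)
})
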