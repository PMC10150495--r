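test_that("the default resolution grid has 23 values and matches rational enumeration", {
  g <- resolution_grid()
  expect_length(g, 23)
  expect_equal(g[1], 0.1)
  expect_equal(g[23], 1.2)
  # exact rational enumeration (work in integer twentieths)
  expect_equal(round(g * 100), seq(10, 120, by = 5))
  expect_equal(resolution_grid(0, 1, 0.5), c(0, 0.5, 1))
  expect_error(resolution_grid(step = 0), "positive")
  expect_error(resolution_grid(2, 1), "below")
})

test_that("entropy and Simpson index match direct summation and their closed forms", {
  expect_equal(shannon_entropy(rep(1, 10)), 0)
  expect_equal(shannon_entropy(rep(1:4, each = 5)), log(4))
  expect_equal(shannon_entropy(rep(1:3, c(2, 3, 5))), 1.029653, tolerance = 1e-6)
  expect_equal(simpson_index(rep(1, 7)), 1)
  expect_equal(simpson_index(rep(1:5, each = 2)), 1 / 5)
  expect_equal(simpson_index(rep(1:3, c(2, 3, 5))), 0.38)
})

test_that("heterogeneity metrics equal brute-force oracles on random partitions", {
  set.seed(99)
  n <- 60
  pts <- matrix(rnorm(n * 4), n, 4)
  emb <- build_embedding_graph(pts, n_pcs = 4, k = 12)
  for (rep in 1:20) {
    part <- sample(1:4, n, replace = TRUE)
    # entropy / simpson against direct formulas
    p <- as.numeric(table(part)) / n
    expect_equal(shannon_entropy(part), -sum(p * log(p)), tolerance = 1e-9)
    expect_equal(simpson_index(part), sum(p^2), tolerance = 1e-9)
    # connectivity against the double loop
    expect_equal(connectivity_index(part, emb$knn, L = 10),
                 oracle_connectivity(part, emb$knn, 10), tolerance = 1e-9)
    # modularity against the edge-sum definition
    expect_equal(graph_modularity(part, emb),
                 oracle_modularity(part, emb), tolerance = 1e-9)
  }
})

test_that("connectivity index weights neighbours by 1/rank and vanishes for co-clustered neighbourhoods", {
  nn <- matrix(c(2, 3, 1, 3, 1, 2), 3, 2, byrow = TRUE)
  expect_equal(connectivity_index(c(1, 1, 1), nn, L = 2), 0)
  # spot 1's first neighbour foreign -> 1; second only -> 1/2
  expect_equal(connectivity_index(c(1, 2, 1), nn, L = 2),
               (1 + 1 / 2) + (1 + 1 / 2) + 0)
  expect_equal(connectivity_index(c(1, 1, 2), nn, L = 1), 0 + 0 + 1)
  expect_error(connectivity_index(c(1, 1, 1), nn, L = 5), "exceeds")
})

test_that("modularity closed forms hold for trivial and two-clique partitions", {
  g2 <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  igraph::E(g2)$weight <- 1
  expect_equal(graph_modularity(rep(1, 10), g2), 0)
  expect_equal(graph_modularity(rep(1:2, each = 5), g2), 0.5)
})

test_that("louvain keeps disconnected cliques apart at every grid resolution", {
  g <- igraph::make_full_graph(10) + igraph::make_full_graph(10)
  igraph::E(g)$weight <- 1
  parts <- louvain_scan(g, resolution_grid(), seed = 0)
  blocks <- rep(1:2, each = 10)
  for (j in seq_len(ncol(parts))) {
    expect_equal(length(unique(parts[, j])), 2)
    # adjusted agreement with the planted blocks is perfect
    expect_equal(length(unique(paste(parts[, j], blocks))), 2)
  }
  # a single clique stays whole at gamma <= 1
  g1 <- igraph::make_full_graph(12)
  igraph::E(g1)$weight <- 1
  p1 <- louvain_scan(g1, c(0.5, 1), seed = 0)
  expect_true(all(apply(p1, 2, function(x) length(unique(x))) == 1))
})

test_that("louvain recovers a planted partition and is deterministic given the seed", {
  set.seed(17)
  blocks <- rep(1:3, each = 10)
  pm <- matrix(0.05, 3, 3); diag(pm) <- 0.9
  g <- igraph::sample_sbm(30, pref.matrix = pm, block.sizes = rep(10, 3))
  igraph::E(g)$weight <- 1
  p <- louvain_scan(g, c(0.5, 1), seed = 0)
  # same labelling structure as the planted blocks
  expect_equal(length(unique(paste(p[, 1], blocks))), 3)
  expect_identical(louvain_scan(g, c(0.5, 1), seed = 0), p)
})

test_that("per-spot entropy reflects local label composition", {
  coords <- cbind(row = rep(1:6, each = 6), col = rep(1:6, 6))
  # homogeneous neighbourhood -> 0
  expect_equal(per_spot_entropy(rep(1, 36), coords, k_neigh = 8),
               rep(0, 36))
  # half/half labels on a 1-D line: the boundary spot's neighbourhood
  # {5, 4, 6} splits 2:1 across labels
  line <- cbind(row = 1:10, col = 0)
  lab <- rep(1:2, each = 5)
  pse <- per_spot_entropy(lab, line, k_neigh = 3)
  expect_equal(pse[5], -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3)))
  expect_equal(pse[1], 0)
  # direct count-and-sum oracle for an arbitrary neighbourhood
  set.seed(4)
  lab2 <- sample(1:3, 36, TRUE)
  pse2 <- per_spot_entropy(lab2, coords, k_neigh = 5)
  d <- as.matrix(dist(coords))
  i <- 14
  nb <- order(d[i, ])[1:5]
  p <- as.numeric(table(lab2[nb])) / 5
  expect_equal(pse2[i], -sum(p * log(p)), tolerance = 1e-9)
  expect_error(per_spot_entropy(lab2, coords, k_neigh = 50), "exceeds")
})

test_that("JSD is 0 for identical, 1 for disjoint, and matches the direct mixture computation", {
  set.seed(5)
  x <- rnorm(200)
  expect_equal(jsd_between_samples(x, x), 0)
  expect_equal(jsd_between_samples(rep(0, 50), rep(1, 50), n_bins = 2), 1)
  # two-bin analytic case: P = (0.5, 0.5), Q = (1, 0)
  a <- c(rep(0.25, 50), rep(0.75, 50))  # half in each bin
  b <- rep(0.25, 50)                     # all in first bin
  expect_equal(jsd_between_samples(a, b, n_bins = 2), 0.311278, tolerance = 1e-5)
  expect_warning(z <- jsd_between_samples(rep(1, 10), rep(1, 10)), "degenerate")
  expect_equal(z, 0)
})

test_that("cluster tree conserves spot flow between consecutive resolutions", {
  parts <- cbind(r1 = rep(1:2, c(6, 4)), r2 = c(rep(1, 4), rep(2, 2), rep(3, 4)))
  tree <- cluster_tree(parts)
  expect_equal(sort(tree$n_spots), c(2, 4, 4))
  # out-flow of each parent equals its size
  for (cl in unique(parts[, 1])) {
    expect_equal(sum(tree$n_spots[tree$from_cluster == cl]),
                 sum(parts[, 1] == cl))
  }
  # identical consecutive partitions give pure vertical edges
  same <- cbind(a = rep(1:3, c(2, 3, 5)), b = rep(1:3, c(2, 3, 5)))
  ts <- cluster_tree(same)
  expect_equal(nrow(ts), 3)
  expect_equal(sort(ts$n_spots), c(2, 3, 5))
  # random partitions against the contingency-table oracle
  set.seed(10)
  pr <- cbind(sample(1:3, 40, TRUE), sample(1:4, 40, TRUE))
  tr <- cluster_tree(pr)
  tab <- table(pr[, 1], pr[, 2])
  for (e in seq_len(nrow(tr))) {
    expect_equal(tr$n_spots[e], unname(tab[tr$from_cluster[e], tr$to_cluster[e]]))
  }
  expect_error(cluster_tree(parts[, 1, drop = FALSE]), "two resolutions")
})
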