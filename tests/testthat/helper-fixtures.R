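# Shared fixtures and independent brute-force oracles.

toy_dataset <- function(n_spots = 6, n_human = 4, n_mouse = 4, seed = 42,
                        max_count = 20) {
  set.seed(seed)
  ng <- n_human + n_mouse
  counts <- matrix(rpois(n_spots * ng, 5), n_spots, ng)
  counts[counts > max_count] <- max_count
  genes <- data.frame(
    gene_id = c(sprintf("GRCh38_H%02d", seq_len(n_human)),
                sprintf("mm10_M%02d", seq_len(n_mouse))),
    symbol = c(sprintf("H%02d", seq_len(n_human)),
               sprintf("M%02d", seq_len(n_mouse))),
    species = rep(c("human", "mouse"), c(n_human, n_mouse)),
    stringsAsFactors = FALSE)
  coords <- data.frame(row = seq_len(n_spots) - 1L, col = 0L)
  spot_dataset(counts, sprintf("BC%03d", seq_len(n_spots)), genes, coords,
               sample_id = "toy")
}

# straight-line Robinson-Oshlack TMM, written independently of the
# implementation under test
oracle_tmm <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  frac75 <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(frac75 - mean(frac75)))
  f <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    if (s == ref) { f[s] <- 1; next }
    obs <- counts[, s] / lib[s]
    rf <- counts[, ref] / lib[ref]
    keep <- obs > 0 & rf > 0
    m <- log2(obs[keep] / rf[keep])
    a <- (log2(obs[keep]) + log2(rf[keep])) / 2
    v <- (lib[s] - counts[keep, s]) / (lib[s] * counts[keep, s]) +
      (lib[ref] - counts[keep, ref]) / (lib[ref] * counts[keep, ref])
    finite <- is.finite(m) & is.finite(a)
    m <- m[finite]; a <- a[finite]; v <- v[finite]
    n <- length(m)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep2 <- rank(m) >= loM & rank(m) <= hiM &
      rank(a) >= loA & rank(a) <= hiA
    f[s] <- 2^(sum(m[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }
  f / exp(mean(log(f)))
}

# brute-force Handl-Knowles connectivity (double loop)
oracle_connectivity <- function(partition, nn, L) {
  ci <- 0
  for (i in seq_along(partition)) {
    for (j in seq_len(L)) {
      if (partition[nn[i, j]] != partition[i]) ci <- ci + 1 / j
    }
  }
  ci
}

# modularity from the edge-sum definition Q = sum_c (e_c/m - (K_c/2m)^2)
oracle_modularity <- function(partition, graph) {
  g <- if (inherits(graph, "embedding_graph")) graph$graph else graph
  el <- igraph::as_data_frame(g, what = "edges")
  w <- el$weight
  m <- sum(w)
  from <- as.integer(el$from); to <- as.integer(el$to)
  q <- 0
  for (cl in unique(partition)) {
    in_c <- which(partition == cl)
    e_c <- sum(w[from %in% in_c & to %in% in_c])
    k_c <- sum(w[from %in% in_c]) + sum(w[to %in% in_c])
    q <- q + e_c / m - (k_c / (2 * m))^2
  }
  q
}

# one-sided Fisher p by exhaustive enumeration of more-extreme tables
oracle_fisher_greater <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  p <- 0
  for (x in max(0, col1 - (n - row1)):min(row1, col1)) {
    if (x >= a)
      p <- p + choose(col1, x) * choose(n - col1, row1 - x) / choose(n, row1)
  }
  p
}

# exact two-sided rank-sum p by full permutation enumeration
oracle_ranksum_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(r_obs - mu) - 1e-12)
}

run_section_scan <- function(treated, seed, k = 50) {
  sim <- simulate_section(simulation_config(treatment = treated, seed = seed))
  hum <- which(sim$truth$spots$species_label == "human")
  norm <- normalise_counts(sim$dataset[hum, ], "logcpm")
  emb <- build_embedding_graph(norm, n_pcs = 50, k = k)
  resolution_scan(emb, seed = 0,
                  coords = sim$dataset$array_coords[hum, ])
}

suggested_call <- function(ds) {
  sc <- species_scores(ds)
  cuts <- suggest_cutoffs(sc$h_scores, sc$m_scores)$cutoffs
  classify_spots(sc$h_scores, sc$m_scores, cuts)
}
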