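#' Inclusive arithmetic resolution grid
#'
#' The default grid, 0.1 to 1.2 in steps of 0.05, spans 23 resolutions.
#'
#' @param lo,hi Grid endpoints (`lo < hi`).
#' @param step Positive step size.
#' @return Numeric vector of length `round((hi - lo) / step) + 1`.
#' @export
resolution_grid <- function(lo = 0.1, hi = 1.2, step = 0.05) {
  if (step <= 0) stop("step must be positive")
  if (lo >= hi) stop("lo must be below hi")
  n <- round((hi - lo) / step)
  lo + step * (0:n)
}

#' Louvain partitions across a resolution grid
#'
#' Runs resolution-parameterised Louvain community detection on the
#' embedding graph once per resolution. The quality being optimised is
#' `Q(gamma) = sum_c [e_c / m - gamma (K_c / 2m)^2]`. The RNG seed is
#' re-set before every resolution so the scan is deterministic and each
#' resolution is independent of grid order.
#'
#' @param graph An [build_embedding_graph()] result or an igraph object.
#' @param resolutions Numeric vector of resolution parameters.
#' @param seed Integer seed (default 0).
#' @return Integer matrix, spots x resolutions, of cluster memberships.
#' @export
louvain_scan <- function(graph, resolutions = resolution_grid(), seed = 0) {
  g <- if (inherits(graph, "embedding_graph")) graph$graph else graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  parts <- vapply(resolutions, function(res) {
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                  resolution = res)
    as.integer(igraph::membership(cl))
  }, integer(igraph::vcount(g)))
  colnames(parts) <- format(resolutions)
  parts
}

#' Shannon entropy of a partition
#'
#' `H = -sum_c p_c ln p_c` (nats) over cluster fractions; the uncertainty
#' of which cluster a random spot falls in, higher meaning more
#' heterogeneous.
#'
#' @param partition Vector of cluster labels.
#' @return Non-negative entropy in nats.
#' @export
shannon_entropy <- function(partition) {
  stopifnot(length(partition) > 0)
  p <- as.numeric(table(partition)) / length(partition)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Simpson index of a partition
#'
#' `D = sum_c p_c^2`: the probability (with replacement) that two random
#' spots share a cluster; lower means more heterogeneous.
#'
#' @param partition Vector of cluster labels.
#' @return Value in (0, 1].
#' @export
simpson_index <- function(partition) {
  stopifnot(length(partition) > 0)
  p <- as.numeric(table(partition)) / length(partition)
  sum(p^2)
}

#' Connectivity index of a partition
#'
#' Handl–Knowles connectivity: for each spot, its j-th nearest neighbour
#' contributes `1/j` when assigned to a different cluster, summed over
#' the first `L` neighbours of every spot. Zero when every spot's L
#' nearest neighbours are co-clustered; higher values mean similar spots
#' are being split apart (more heterogeneity/fragmentation).
#'
#' @param partition Vector of cluster labels.
#' @param nn Integer matrix of neighbour indices (spots x >= L, nearest
#'   first, self excluded), e.g. `embedding_graph$knn`.
#' @param L Number of neighbours to penalise over (default 10).
#' @return Non-negative connectivity value.
#' @export
connectivity_index <- function(partition, nn, L = 10) {
  if (L > ncol(nn)) stop("L exceeds the available neighbours")
  stopifnot(length(partition) == nrow(nn))
  ci <- 0
  inv <- 1 / seq_len(L)
  for (j in seq_len(L)) {
    ci <- ci + inv[j] * sum(partition[nn[, j]] != partition)
  }
  ci
}

#' Newman–Girvan modularity of a partition on the embedding graph
#'
#' @param partition Vector of cluster labels.
#' @param graph An `embedding_graph` or igraph object (edge weights used).
#' @return Modularity Q at resolution 1.
#' @export
graph_modularity <- function(partition, graph) {
  g <- if (inherits(graph, "embedding_graph")) graph$graph else graph
  igraph::modularity(g, as.integer(factor(partition)),
                     weights = igraph::E(g)$weight)
}

#' Per-spot entropy of local cluster composition
#'
#' For each spot, the Shannon entropy (nats) of the cluster-label
#' composition among its `k_neigh` nearest spatial neighbours, itself
#' included. High values mark spots sitting in locally heterogeneous
#' neighbourhoods.
#'
#' @param partition Cluster labels at the reference resolution.
#' @param coords Spot coordinates (array grid), one row per spot.
#' @param k_neigh Neighbourhood size including the spot (default 20).
#' @return Numeric vector of per-spot entropies.
#' @export
per_spot_entropy <- function(partition, coords, k_neigh = 20) {
  n <- length(partition)
  if (k_neigh > n) stop("k_neigh exceeds the number of spots")
  coords <- as.matrix(coords)
  dmat <- as.matrix(dist(coords))
  vapply(seq_len(n), function(i) {
    nb <- order(dmat[i, ])[seq_len(k_neigh)]  # self at distance 0 first
    shannon_entropy(partition[nb])
  }, 0)
}

#' Jensen–Shannon divergence between two per-spot entropy distributions
#'
#' Both vectors are histogrammed on shared equal-width bins spanning the
#' pooled range; the JSD is computed base 2, so it lies in `[0, 1]` and
#' is 0 for identical distributions. Empty bins contribute nothing.
#'
#' @param a,b Non-empty numeric vectors.
#' @param n_bins Number of shared bins (default 50).
#' @return JSD in bits.
#' @export
jsd_between_samples <- function(a, b, n_bins = 50) {
  stopifnot(length(a) > 0, length(b) > 0)
  rng <- range(c(a, b))
  if (diff(rng) == 0) {
    warning("degenerate pooled range: JSD set to 0")
    return(0)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  p <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) / length(a)
  q <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) / length(b)
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * log2(x[i] / y[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Cluster-tree edges between consecutive resolutions
#'
#' For each pair of consecutive partitions, one edge per (parent cluster,
#' child cluster) combination that shares spots, weighted by the shared
#' spot count. Out-flows of each parent sum to its size, so spot counts
#' are conserved along the tree.
#'
#' @param partitions Spots x resolutions membership matrix.
#' @return data.frame with columns `from_res`, `to_res`, `from_cluster`,
#'   `to_cluster`, `n_spots`.
#' @export
cluster_tree <- function(partitions) {
  partitions <- as.matrix(partitions)
  if (ncol(partitions) < 2) stop("need at least two resolutions")
  res_names <- colnames(partitions)
  if (is.null(res_names)) res_names <- as.character(seq_len(ncol(partitions)))
  edges <- list()
  for (t in seq_len(ncol(partitions) - 1)) {
    tab <- table(partitions[, t], partitions[, t + 1])
    nz <- which(tab > 0, arr.ind = TRUE)
    edges[[t]] <- data.frame(
      from_res = res_names[t], to_res = res_names[t + 1],
      from_cluster = rownames(tab)[nz[, 1]],
      to_cluster = colnames(tab)[nz[, 2]],
      n_spots = as.integer(tab[nz]), stringsAsFactors = FALSE)
  }
  do.call(rbind, edges)
}

#' Full heterogeneity scan over a resolution grid
#'
#' Runs [louvain_scan()] and derives, per resolution, the number of
#' clusters, Shannon entropy, Simpson index, modularity and connectivity
#' index, plus the cluster tree, the grid-summed connectivity (`ci_total`,
#' the headline per-sample connectivity) and, when coordinates are given,
#' the per-spot entropy at the reference resolution.
#'
#' @param emb An [build_embedding_graph()] result.
#' @param resolutions Resolution grid (default [resolution_grid()]).
#' @param seed Louvain seed (default 0).
#' @param ref_resolution Reference resolution for per-spot entropy
#'   (default 0.8; nearest grid point is used).
#' @param coords Optional spot coordinates for per-spot entropy.
#' @param L Connectivity neighbour depth (default 10).
#' @param k_neigh Per-spot entropy neighbourhood size (default 20).
#' @return A `resolution_scan` list: `resolutions`, `partitions`,
#'   `metrics` data.frame, `ci_total`, `tree`, `per_spot_entropy`, `seed`.
#' @export
resolution_scan <- function(emb, resolutions = resolution_grid(), seed = 0,
                            ref_resolution = 0.8, coords = NULL, L = 10,
                            k_neigh = 20) {
  stopifnot(inherits(emb, "embedding_graph"))
  parts <- louvain_scan(emb, resolutions, seed = seed)
  L_use <- min(L, ncol(emb$knn))
  metrics <- data.frame(
    resolution = resolutions,
    n_clusters = apply(parts, 2, function(p) length(unique(p))),
    shannon = apply(parts, 2, shannon_entropy),
    simpson = apply(parts, 2, simpson_index),
    modularity = apply(parts, 2, graph_modularity, graph = emb),
    connectivity = apply(parts, 2, connectivity_index,
                         nn = emb$knn[, seq_len(L_use), drop = FALSE],
                         L = L_use))
  pse <- NULL
  if (!is.null(coords)) {
    ref_i <- which.min(abs(resolutions - ref_resolution))
    pse <- per_spot_entropy(parts[, ref_i], coords,
                            k_neigh = min(k_neigh, nrow(parts)))
  }
  structure(list(resolutions = resolutions, partitions = parts,
                 metrics = metrics,
                 ci_total = sum(metrics$connectivity),
                 tree = if (length(resolutions) > 1) cluster_tree(parts),
                 per_spot_entropy = pse,
                 ref_resolution = ref_resolution, seed = seed),
            class = "resolution_scan")
}

#' @exportS3Method base::print
print.resolution_scan <- function(x, ...) {
  cat(sprintf("resolution_scan: %d resolutions (%.2f-%.2f), ci_total = %.1f\n",
              length(x$resolutions), min(x$resolutions), max(x$resolutions),
              x$ci_total))
  invisible(x)
}
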