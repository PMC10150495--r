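#' Normalise a spot count matrix
#'
#' * `logcpm`: `log2(1e6 * count / libsize + 0.5)` per cell (edgeR's
#'   log-cpm convention, base 2).
#' * `log1p_median`: `log(1 + count * median(lib) / lib)`, the
#'   median-library scaling used for species scoring.
#' * `external`: pass-through of a supplied matrix after a shape check,
#'   for plugging in an externally computed normalisation (e.g.
#'   variance-stabilised residuals).
#'
#' @param ds A [spot_dataset()] or a spots x genes count matrix.
#' @param method One of "logcpm", "log1p_median", "external".
#' @param external Matrix used when `method = "external"`.
#' @return Dense numeric matrix, spots x genes.
#' @export
normalise_counts <- function(ds, method = c("logcpm", "log1p_median",
                                            "external"),
                             external = NULL) {
  method <- match.arg(method)
  counts <- if (inherits(ds, "spot_dataset")) ds$counts else ds
  if (method == "external") {
    stopifnot(!is.null(external))
    if (!all(dim(external) == dim(counts)))
      stop("external matrix shape does not match the dataset")
    return(as.matrix(external))
  }
  lib <- Matrix::rowSums(counts)
  if (any(lib == 0))
    stop("zero-library spot(s) present: filter spots before normalising")
  counts <- as.matrix(counts)
  if (method == "logcpm") {
    log2(1e6 * counts / lib + 0.5)
  } else {
    log1p(counts * (median(lib) / lib))
  }
}

#' Remove genes with low total counts
#'
#' @param ds A [spot_dataset()].
#' @param min_total Keep genes whose total count is >= this (default 50).
#' @return Filtered `spot_dataset`; drop count reported via `message`.
#' @export
filter_genes_min_count <- function(ds, min_total = 50) {
  tot <- Matrix::colSums(ds$counts)
  keep <- tot >= min_total
  if (!any(keep)) stop("no genes survive the minimum-count filter")
  if (any(!keep))
    message(sum(!keep), " gene(s) removed (total count < ", min_total, ")")
  ds[, keep]
}

# neighbour index list within Chebyshev radius on the array grid
chebyshev_neighbours <- function(coords, radius = 1) {
  key <- paste(coords[, 1], coords[, 2], sep = ",")
  lookup <- setNames(seq_len(nrow(coords)), key)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  lapply(seq_len(nrow(coords)), function(i) {
    k <- paste(coords[i, 1] + offs$dr, coords[i, 2] + offs$dc, sep = ",")
    unname(lookup[k[k %in% names(lookup)]])
  })
}

#' Spatial-neighbour expression smoothing
#'
#' An expression-space surrogate for morphology-aware smoothing: each
#' spot's profile is blended with the mean profile of its grid neighbours
#' within a Chebyshev radius,
#' `smoothed = (1 - alpha) * own + alpha * neighbour_mean`.
#' Spots without neighbours are left unchanged.
#'
#' @param normalised Spots x genes matrix.
#' @param coords Integer array coordinates (row, col), one row per spot.
#' @param radius Chebyshev neighbourhood radius (default 1 = 8 neighbours).
#' @param alpha Blend weight in `[0, 1]`.
#' @return Smoothed matrix of the same shape.
#' @export
spatial_smooth <- function(normalised, coords, radius = 1, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (alpha == 0) return(as.matrix(normalised))
  normalised <- as.matrix(normalised)
  nb <- chebyshev_neighbours(as.matrix(coords), radius)
  out <- normalised
  for (i in seq_len(nrow(normalised))) {
    if (length(nb[[i]]) == 0) next
    nmean <- colMeans(normalised[nb[[i]], , drop = FALSE])
    out[i, ] <- (1 - alpha) * normalised[i, ] + alpha * nmean
  }
  out
}

#' Build the PCA embedding and nearest-neighbour graph
#'
#' Exact PCA (SVD) of the centred matrix, k nearest neighbours by
#' Euclidean distance in PC space, edges symmetrised by union and
#' weighted by shared-neighbour similarity
#' `(|N(i) intersect N(j)| + 1) / (k + 1)` so every edge weight is
#' positive.
#'
#' @param mat Spots x genes (normalised) matrix.
#' @param n_pcs Number of principal components (default 50, capped at the
#'   matrix rank).
#' @param k Neighbours per spot (default 50; must be < number of spots).
#' @return An `embedding_graph`: list with `pcs` (spots x n_pcs), `knn`
#'   (spots x k neighbour indices, nearest first), `graph` (weighted
#'   undirected igraph) and `params`.
#' @export
build_embedding_graph <- function(mat, n_pcs = 50, k = 50) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (k >= n) stop("k must be smaller than the number of spots")
  n_pcs <- min(n_pcs, n - 1, ncol(mat))
  pcs <- prcomp(mat, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  dmat <- as.matrix(dist(pcs))
  diag(dmat) <- Inf
  knn <- t(apply(dmat, 1, function(r) order(r)[seq_len(k)]))
  nb_sets <- lapply(seq_len(n), function(i) knn[i, ])
  ei <- rep(seq_len(n), each = k)
  ej <- as.vector(t(knn))
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)
  keyed <- !duplicated(cbind(lo, hi))
  lo <- lo[keyed]; hi <- hi[keyed]
  w <- vapply(seq_along(lo), function(e) {
    (length(intersect(nb_sets[[lo[e]]], nb_sets[[hi[e]]])) + 1) / (k + 1)
  }, 0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  structure(list(pcs = pcs, knn = knn, graph = g,
                 params = list(n_pcs = n_pcs, k = k)),
            class = "embedding_graph")
}

#' @exportS3Method base::print
print.embedding_graph <- function(x, ...) {
  cat(sprintf("embedding_graph: %d spots, %d PCs, k=%d, %d edges\n",
              nrow(x$pcs), ncol(x$pcs), x$params$k,
              igraph::ecount(x$graph)))
  invisible(x)
}
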