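#' Aggregate a labelled reference into per-type pseudo-profiles
#'
#' For every cell-type label, cells are pooled into up to `ncenters`
#' groups by seeded k-means on their top principal components, and each
#' group is averaged into one log-expression profile. This condenses a
#' large reference to a handful of representative profiles per type.
#'
#' @param ref Genes x cells log-expression matrix (rownames = gene ids).
#' @param labels Cell-type label per cell.
#' @param ncenters Maximum profiles per type (default 3).
#' @param n_pcs PCs used for the within-type k-means (default 10).
#' @param seed k-means seed (default 0).
#' @return A `reference_profiles` object: `profiles` (genes x centres),
#'   `profile_labels` (type of each centre), `ncenters`.
#' @export
aggregate_reference <- function(ref, labels, ncenters = 3, n_pcs = 10,
                                seed = 0) {
  ref <- as.matrix(ref)
  stopifnot(ncol(ref) == length(labels))
  types <- unique(labels)
  profiles <- list(); prof_labels <- character(0)
  for (ty in types) {
    cells <- which(labels == ty)
    if (length(cells) == 0) stop("label with zero cells: ", ty)
    k <- min(ncenters, length(cells))
    if (k == 1 || length(cells) <= k) {
      assign_k <- rep(seq_len(k), length.out = length(cells))
    } else {
      sub <- t(ref[, cells, drop = FALSE])
      npc <- min(n_pcs, nrow(sub) - 1, ncol(sub))
      pcs <- prcomp(sub, center = TRUE, rank. = npc)$x
      if (all(apply(pcs, 2, sd) == 0) || ncol(pcs) == 0) {
        assign_k <- rep(1L, length(cells))       # identical cells
      } else {
        set.seed(seed)
        assign_k <- kmeans(pcs, centers = min(k, nrow(unique(pcs))),
                           nstart = 5)$cluster
      }
    }
    for (ctr in sort(unique(assign_k))) {
      prof <- rowMeans(ref[, cells[assign_k == ctr], drop = FALSE])
      profiles[[length(profiles) + 1]] <- prof
      prof_labels <- c(prof_labels, ty)
    }
  }
  mat <- do.call(cbind, profiles)
  colnames(mat) <- make.unique(prof_labels)
  structure(list(profiles = mat, profile_labels = prof_labels,
                 ncenters = ncenters, selected_genes = rownames(mat)),
            class = "reference_profiles")
}

#' Select marker genes from aggregated reference profiles
#'
#' For every ordered pair of labels (A, B), genes are ranked either by
#' the difference of mean profiles (`classic_lfc`) or by a two-sample t
#' statistic across the labels' centre profiles (`t_stat`), and the top
#' `de_n` per pair are pooled into the classification gene list.
#'
#' @param profiles A `reference_profiles` object.
#' @param de_n Genes per ordered label pair (350 is a typical choice for
#'   `classic_lfc`, 200 for `t_stat`; capped at the gene count with a
#'   warning).
#' @param method "classic_lfc" or "t_stat".
#' @return The `reference_profiles` with `selected_genes` replaced by the
#'   marker union.
#' @export
select_marker_genes <- function(profiles, de_n = 350,
                                method = c("classic_lfc", "t_stat")) {
  method <- match.arg(method)
  stopifnot(inherits(profiles, "reference_profiles"))
  mat <- profiles$profiles
  labs <- profiles$profile_labels
  types <- unique(labs)
  if (length(types) < 2) stop("need at least two labels")
  if (de_n > nrow(mat)) {
    warning("de_n exceeds the gene count: capped at ", nrow(mat))
    de_n <- nrow(mat)
  }
  selected <- character(0)
  for (a in types) for (b in setdiff(types, a)) {
    ma <- mat[, labs == a, drop = FALSE]
    mb <- mat[, labs == b, drop = FALSE]
    if (method == "classic_lfc" || ncol(ma) < 2 || ncol(mb) < 2) {
      stat <- rowMeans(ma) - rowMeans(mb)
    } else {
      va <- apply(ma, 1, var) / ncol(ma)
      vb <- apply(mb, 1, var) / ncol(mb)
      se <- sqrt(va + vb)
      se[se == 0] <- max(se[se > 0], 1e-8)
      stat <- (rowMeans(ma) - rowMeans(mb)) / se
    }
    selected <- union(selected,
                      rownames(mat)[order(-stat)[seq_len(de_n)]])
  }
  profiles$selected_genes <- selected
  profiles$de_n <- de_n
  profiles$de_method <- method
  profiles
}

#' Classify spots against reference profiles by Spearman correlation
#'
#' Each spot is correlated (Spearman, ties mid-ranked) with every
#' aggregated profile on the selected genes shared with the query; its
#' per-label score is the maximum over that label's profiles and it is
#' assigned the label with the highest score. Spearman makes the
#' classification invariant to any per-spot monotone transform of
#' expression. Constant spots (zero rank variance) are left unassigned
#' and flagged; exact score ties resolve to the first label and are
#' flagged.
#'
#' @param query Spots x genes (log-scale) matrix with gene-id colnames.
#' @param profiles A `reference_profiles` (after [select_marker_genes()]
#'   if marker selection is wanted).
#' @return A `spot_annotation` data.frame: `barcode`, `label`, `score`,
#'   `margin`, `tie`, plus the full score matrix in
#'   `attr(, "scores")`.
#' @export
classify_spots_by_reference <- function(query, profiles) {
  stopifnot(inherits(profiles, "reference_profiles"))
  query <- as.matrix(query)
  genes <- intersect(profiles$selected_genes, colnames(query))
  if (length(genes) < 3) stop("fewer than 3 selected genes shared with the query")
  q <- query[, genes, drop = FALSE]
  p <- profiles$profiles[genes, , drop = FALSE]
  qr <- apply(q, 1, rank)                 # genes x spots
  pr <- apply(p, 2, rank)                 # genes x profiles
  const <- apply(qr, 2, function(v) var(v) == 0)
  scores <- suppressWarnings(cor(qr, pr))  # Pearson on ranks = Spearman
  labs <- profiles$profile_labels
  types <- unique(labs)
  label_scores <- vapply(types, function(ty)
    apply(scores[, labs == ty, drop = FALSE], 1, max), numeric(nrow(q)))
  if (nrow(q) == 1) label_scores <- matrix(label_scores, nrow = 1,
                                           dimnames = list(NULL, types))
  best_i <- apply(label_scores, 1, which.max)
  best <- types[best_i]
  score <- label_scores[cbind(seq_len(nrow(q)), best_i)]
  second <- apply(label_scores, 1, function(v) sort(v, decreasing = TRUE)[2])
  tie <- apply(label_scores, 1, function(v) sum(v == max(v)) > 1)
  best[const] <- NA_character_
  bc <- rownames(query)
  if (is.null(bc)) bc <- as.character(seq_len(nrow(query)))
  ann <- data.frame(barcode = bc, label = best, score = score,
                    margin = score - second, tie = tie,
                    stringsAsFactors = FALSE)
  attr(ann, "scores") <- label_scores
  class(ann) <- c("spot_annotation", "data.frame")
  ann
}

#' Annotate a section by dominant reference cell type
#'
#' Species-aware orchestration of the reference classifier: human spots
#' are matched against the human reference on human genes only, mouse
#' spots against the mouse reference on mouse genes only, and mixed spots
#' are annotated twice (once per species) with both labels retained.
#' Expression is log-cpm normalised (`log(CPM + 1)` scale via `log1p`)
#' and optionally spatially smoothed beforehand.
#'
#' @param ds A [spot_dataset()].
#' @param call A `species_call` for the same spots.
#' @param human_ref,mouse_ref `reference_profiles` objects; either may be
#'   `NULL` when the corresponding species is absent.
#' @param smooth_alpha Spatial smoothing weight (0 disables; default 0).
#' @return List with `human` and `mouse` `spot_annotation` tables (NULL
#'   when not applicable). Mixed spots appear in both.
#' @export
annotate_dataset <- function(ds, call, human_ref = NULL, mouse_ref = NULL,
                             smooth_alpha = 0) {
  stopifnot(inherits(call, "species_call"))
  idx <- match(call$barcode, ds$barcodes)
  if (anyNA(idx)) stop("species call does not match dataset barcodes")
  norm <- log1p(1e6 * as.matrix(ds$counts) / Matrix::rowSums(ds$counts))
  colnames(norm) <- ds$genes$gene_id
  rownames(norm) <- ds$barcodes
  if (smooth_alpha > 0)
    norm <- spatial_smooth(norm, ds$array_coords, alpha = smooth_alpha)
  out <- list(human = NULL, mouse = NULL)
  for (sp in c("human", "mouse")) {
    ref <- if (sp == "human") human_ref else mouse_ref
    spots <- idx[call$label %in% c(sp, "mix")]
    if (length(spots) == 0) next
    if (is.null(ref))
      stop("missing ", sp, " reference for ", length(spots), " ", sp,
           "/mix spots")
    gcols <- ds$genes$species == sp
    out[[sp]] <- classify_spots_by_reference(
      norm[spots, gcols, drop = FALSE], ref)
  }
  out
}
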