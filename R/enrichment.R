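#' Per-spot, per-gene fold changes
#'
#' On the log scale, each spot's fold change for a gene is its normalised
#' expression minus that gene's mean across all spots, so every gene's
#' column of the result is centred at zero.
#'
#' @param normalised Spots x genes normalised (log-scale) matrix.
#' @return Matrix of the same shape.
#' @export
spot_fold_changes <- function(normalised) {
  normalised <- as.matrix(normalised)
  sweep(normalised, 2, colMeans(normalised))
}

#' Per-spot parametric gene-set enrichment (PAGE) scores
#'
#' For each spot and gene set, `E = (S_m - mu) * sqrt(m) / delta`, where
#' `S_m` is the mean fold change of the set's `m` resolved members in the
#' spot and `mu`, `delta` are the mean and population standard deviation
#' of the fold changes over *all* genes in that spot. `E` is a z-like
#' statistic: it is invariant to adding a constant to all genes of a spot
#' and scales inversely with the spot's fold-change dispersion.
#'
#' Sets with no resolved members yield `NA` columns (never zeros); spots
#' with zero fold-change dispersion yield `NA` rows with a warning.
#'
#' @param fc Spots x genes fold-change matrix ([spot_fold_changes()]).
#' @param sets Named list of gene-id vectors.
#' @param restrict Optional gene-id vector (e.g. DE genes); each set is
#'   intersected with it before scoring.
#' @return An `enrichment_map`: list with `scores` (spots x sets),
#'   `set_sizes` (resolved member counts) and `n_unresolved`.
#' @export
page_scores <- function(fc, sets, restrict = NULL) {
  fc <- as.matrix(fc)
  gene_ids <- colnames(fc)
  if (is.null(gene_ids)) stop("fold-change matrix must carry gene ids as colnames")
  if (!is.null(restrict)) sets <- lapply(sets, intersect, restrict)
  res <- resolve_gene_sets(sets, gene_ids)
  mu <- rowMeans(fc)
  delta <- sqrt(rowMeans(fc^2) - mu^2)  # population sd per spot
  bad <- delta <= 0
  if (any(bad))
    warning(sum(bad), " spot(s) with zero fold-change dispersion: scores set to NA")
  scores <- matrix(NA_real_, nrow(fc), length(sets),
                   dimnames = list(rownames(fc), names(sets)))
  sizes <- lengths(res$sets)
  for (s in seq_along(sets)) {
    m <- sizes[s]
    if (m == 0) next
    members <- match(res$sets[[s]], gene_ids)
    sm <- rowMeans(fc[, members, drop = FALSE])
    e <- (sm - mu) * sqrt(m) / delta
    e[bad] <- NA_real_
    scores[, s] <- e
  }
  structure(list(scores = scores, set_sizes = sizes,
                 n_unresolved = res$n_unresolved),
            class = "enrichment_map")
}

#' @exportS3Method base::print
print.enrichment_map <- function(x, ...) {
  cat(sprintf("enrichment_map: %d spots x %d gene sets\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Rank one-vs-rest cluster markers
#'
#' For each cluster (of size >= 3), genes are ranked by the one-vs-rest
#' Wilcoxon rank-sum statistic (expressed as the AUC, ties mid-ranked);
#' genes matching the exclusion patterns (mitochondrial by default) are
#' removed, and the top `top_n` genes form that cluster's marker set.
#'
#' @param normalised Spots x genes matrix with gene ids as colnames.
#' @param partition Cluster labels per spot.
#' @param top_n Markers per cluster (default 10).
#' @param exclude Regular-expression patterns to drop (default
#'   mitochondrial prefixes `MT-`/`mt-`).
#' @param symbols Optional gene symbols to match patterns against
#'   (defaults to colnames).
#' @return List with `sets` (named list of marker gene ids) and `stats`
#'   (per-cluster data.frame of gene, auc, p).
#' @export
rank_cluster_markers <- function(normalised, partition, top_n = 10,
                                 exclude = c("^MT-", "^mt-"),
                                 symbols = NULL) {
  normalised <- as.matrix(normalised)
  gene_ids <- colnames(normalised)
  if (is.null(symbols)) symbols <- gene_ids
  excl <- rep(FALSE, length(symbols))
  for (p in exclude) excl <- excl | grepl(p, symbols)
  keep <- !excl
  clusters <- sort(unique(partition))
  if (length(clusters) < 2) stop("need at least two clusters")
  sets <- list(); stats <- list()
  for (cl in clusters) {
    in_cl <- partition == cl
    n1 <- sum(in_cl); n2 <- sum(!in_cl)
    if (n1 < 3) {
      warning("cluster ", cl, " has fewer than 3 spots: skipped")
      next
    }
    auc <- numeric(ncol(normalised)); pval <- numeric(ncol(normalised))
    for (g in which(keep)) {
      r <- rank(normalised[, g])
      u <- sum(r[in_cl]) - n1 * (n1 + 1) / 2
      auc[g] <- u / (n1 * n2)
      pval[g] <- suppressWarnings(
        wilcox.test(normalised[in_cl, g], normalised[!in_cl, g],
                    alternative = "two.sided")$p.value)
    }
    ord <- order(-auc[keep])
    top <- which(keep)[ord][seq_len(min(top_n, sum(keep)))]
    nm <- paste0("cluster_", cl)
    sets[[nm]] <- gene_ids[top]
    stats[[nm]] <- data.frame(gene = gene_ids[top], auc = auc[top],
                              p = pval[top], stringsAsFactors = FALSE)
  }
  list(sets = sets, stats = stats)
}

#' Compare gene-set activity between two conditions by pseudosampling
#'
#' Spots of each condition are split at random into equal blocks, block
#' means of the enrichment score are computed, and the two sets of block
#' means are compared with a two-tailed t-test. Blocking tempers the
#' pseudo-replication of treating every spot as independent.
#'
#' @param scores_a,scores_b Per-spot enrichment scores for one gene set
#'   in each condition.
#' @param n_blocks Pseudosample blocks per condition (default 50; reduced
#'   with a warning when a condition has fewer spots).
#' @param seed Seed for the random block assignment.
#' @return List with `difference` (mean a - mean b), `t`, `p`,
#'   `block_means_a`, `block_means_b`.
#' @export
compare_signature_activity <- function(scores_a, scores_b, n_blocks = 50,
                                       seed = 0) {
  scores_a <- scores_a[!is.na(scores_a)]
  scores_b <- scores_b[!is.na(scores_b)]
  nb <- min(n_blocks, length(scores_a), length(scores_b))
  if (nb < n_blocks)
    warning("fewer spots than blocks: using ", nb, " blocks")
  set.seed(seed)
  blocks_a <- sample(rep_len(seq_len(nb), length(scores_a)))
  blocks_b <- sample(rep_len(seq_len(nb), length(scores_b)))
  ma <- tapply(scores_a, blocks_a, mean)
  mb <- tapply(scores_b, blocks_b, mean)
  tt <- t.test(ma, mb, alternative = "two.sided")
  list(difference = mean(ma) - mean(mb),
       t = unname(tt$statistic), p = tt$p.value,
       block_means_a = as.numeric(ma), block_means_b = as.numeric(mb))
}
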