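#' Build species-stratified pseudobulk libraries
#'
#' Sums UMI counts per gene over all spots of a compartment within each
#' sample, yielding one bulk-like library per sample. The compartment
#' fixes both the spot subset and the gene subset: `human` uses
#' human-labelled spots and human genes, `mouse` uses mouse spots and
#' mouse genes, and the mixed interface is analysed separately per
#' species (`mix_human` = mix spots with human genes, `mix_mouse` = mix
#' spots with mouse genes).
#'
#' @param ds_list List of [spot_dataset()] objects (one per sample).
#' @param call_list List of `species_call` objects aligned with
#'   `ds_list`.
#' @param compartment One of "human", "mouse", "mix_human", "mix_mouse".
#' @param group Factor/character of per-sample conditions (e.g.
#'   control/treated), aligned with `ds_list`.
#' @return A `pseudobulk_set`: list with `counts` (genes x samples),
#'   `group`, `compartment`, `sample_ids`.
#' @export
pseudobulk <- function(ds_list, call_list, compartment, group) {
  compartment <- match.arg(compartment,
                           c("human", "mouse", "mix_human", "mix_mouse"))
  stopifnot(length(ds_list) == length(call_list),
            length(ds_list) == length(group))
  spot_label <- switch(compartment, human = "human", mouse = "mouse",
                       mix_human = "mix", mix_mouse = "mix")
  gene_species <- switch(compartment, human = "human", mouse = "mouse",
                         mix_human = "human", mix_mouse = "mouse")
  sample_ids <- vapply(ds_list, function(d) d$sample_id, "")
  gene_sets <- lapply(ds_list, function(d)
    d$genes$gene_id[d$genes$species == gene_species])
  shared <- Reduce(intersect, gene_sets)
  if (length(shared) == 0) stop("no shared ", gene_species, " genes across samples")
  counts <- matrix(0, length(shared), length(ds_list),
                   dimnames = list(shared, sample_ids))
  for (s in seq_along(ds_list)) {
    ds <- ds_list[[s]]; call <- call_list[[s]]
    idx <- match(call$barcode, ds$barcodes)
    if (anyNA(idx)) stop("species call does not match dataset barcodes in sample ",
                         sample_ids[s])
    spots <- idx[call$label == spot_label]
    if (length(spots) == 0)
      stop("compartment '", compartment, "' is empty in sample ", sample_ids[s])
    sub <- ds$counts[spots, match(shared, ds$genes$gene_id), drop = FALSE]
    counts[, s] <- Matrix::colSums(sub)
  }
  structure(list(counts = counts,
                 group = factor(group),
                 compartment = compartment, sample_ids = sample_ids),
            class = "pseudobulk_set")
}

#' @exportS3Method base::print
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf("pseudobulk_set [%s]: %d genes x %d samples (%s)\n",
              x$compartment, nrow(x$counts), ncol(x$counts),
              paste(levels(x$group), collapse = " vs ")))
  invisible(x)
}

pb_logcpm <- function(counts, lib = colSums(counts)) {
  log2(sweep(counts, 2, lib, "/") * 1e6 + 0.5)
}

#' Filter lowly expressed pseudobulk genes
#'
#' First removes genes with zero counts in every sample, then genes whose
#' maximum log-cpm across samples falls below the compartment threshold.
#' The default thresholds are 2 (human), 2 (mouse), 3 (mix_human) and 3
#' (mix_mouse); the mixed compartments use a higher cutoff because their
#' low-expression mode sits at higher log-cpm.
#'
#' @param pb A `pseudobulk_set`.
#' @param min_logcpm Threshold; `NULL` picks the compartment default.
#' @return Filtered `pseudobulk_set`; survivor count reported via message.
#' @export
filter_low_expression <- function(pb, min_logcpm = NULL) {
  if (is.null(min_logcpm))
    min_logcpm <- c(human = 2, mouse = 2, mix_human = 3,
                    mix_mouse = 3)[[pb$compartment]]
  nonzero <- rowSums(pb$counts) > 0
  lc <- pb_logcpm(pb$counts)
  keep <- nonzero & apply(lc, 1, max) >= min_logcpm
  message(sum(keep), " of ", nrow(pb$counts),
          " genes kept (max log-cpm >= ", min_logcpm, ")")
  pb$counts <- pb$counts[keep, , drop = FALSE]
  pb$filter_threshold <- min_logcpm
  pb
}

#' TMM size factors
#'
#' Robinson–Oshlack trimmed mean of M-values between-sample size factors
#' (reference chosen by 75th-percentile count fraction, 30% M / 5% A
#' trimming, inverse-asymptotic-variance weights), rescaled so the
#' factors have geometric mean 1.
#'
#' @param counts Genes x samples count matrix (filtered), or a
#'   `pseudobulk_set`.
#' @return Numeric vector of size factors, one per sample.
#' @export
tmm_size_factors <- function(counts) {
  if (inherits(counts, "pseudobulk_set")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  names(f) <- colnames(counts)
  f
}

# Newton inversion of the trigamma function (for the variance-prior fit)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Method-of-moments fit of a scaled inverse-chi-square prior to gene
# variances on the log scale: returns prior df d0 and prior value s0^2.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e)
  resid_var <- evar - trigamma(df / 2)
  if (is.na(resid_var) || resid_var <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(resid_var)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated differential expression with a fold-change threshold
#'
#' A two-group moderated test on TMM-adjusted log-cpm values:
#' observation-level precision weights from a lowess trend of residual
#' standard deviation versus mean log-cpm; empirical-Bayes variance
#' shrinkage by a method-of-moments fit of a scaled inverse-chi-square
#' prior (prior df `d0`, prior variance `s0^2`); and a threshold test
#' that asks whether `|logFC|` significantly exceeds `logfc_threshold`
#' rather than zero, referred to a t distribution with `d0 +` residual
#' degrees of freedom. With `logfc_threshold = 0` the test reduces to the
#' ordinary moderated t-test, and p-values are non-decreasing in the
#' threshold. FDR control is Benjamini–Hochberg.
#'
#' The contrast is the second group level versus the first
#' (`levels(group)[2] - levels(group)[1]`).
#'
#' @param pb A `pseudobulk_set` (filtered), or a genes x samples matrix
#'   together with `group`.
#' @param group Required when `pb` is a bare matrix.
#' @param logfc_threshold Minimum biologically meaningful `|logFC|`
#'   (default 0.15).
#' @param alpha FDR significance level (default 0.05).
#' @return data.frame with columns `gene`, `logFC`, `ave_logcpm`, `t`,
#'   `p`, `fdr`, `significant`, plus the prior fit in attributes
#'   (`d0`, `s02`, `size_factors`).
#' @export
moderated_de <- function(pb, group = NULL, logfc_threshold = 0.15,
                         alpha = 0.05) {
  if (inherits(pb, "pseudobulk_set")) {
    counts <- pb$counts; group <- pb$group
  } else {
    counts <- as.matrix(pb)
    if (is.null(group)) stop("group is required with a bare count matrix")
    group <- factor(group)
  }
  if (nlevels(group) != 2) stop("exactly two groups are required")
  n1 <- sum(group == levels(group)[1])
  n2 <- sum(group == levels(group)[2])
  if (n1 < 2 || n2 < 2)
    stop("zero residual degrees of freedom: need >= 2 samples per group")
  if (logfc_threshold < 0) stop("logfc_threshold must be >= 0")
  G <- nrow(counts); n <- ncol(counts)
  df_resid <- n - 2

  sf <- tmm_size_factors(counts)
  eff_lib <- colSums(counts) * sf
  y <- log2(sweep(counts + 0.5, 2, eff_lib + 1, "/") * 1e6)

  g2 <- group == levels(group)[2]
  mean1 <- rowMeans(y[, !g2, drop = FALSE])
  mean2 <- rowMeans(y[, g2, drop = FALSE])
  fitted <- matrix(mean1, G, n)
  fitted[, g2] <- mean2
  resid <- y - fitted
  s_raw <- sqrt(rowSums(resid^2) / df_resid)

  # mean-variance trend: lowess of sqrt(sd) on average log-cpm, turned
  # into per-observation precision weights at the fitted values
  ave <- rowMeans(y)
  lo <- lowess(ave, sqrt(s_raw), f = 0.5)
  pred <- approx(lo$x, lo$y, xout = as.vector(fitted), rule = 2)$y
  pred <- pmax(pred, 1e-4)
  w <- matrix(1 / pred^4, G, n)

  sw1 <- rowSums(w[, !g2, drop = FALSE])
  sw2 <- rowSums(w[, g2, drop = FALSE])
  wm1 <- rowSums((w * y)[, !g2, drop = FALSE]) / sw1
  wm2 <- rowSums((w * y)[, g2, drop = FALSE]) / sw2
  logfc <- wm2 - wm1
  fitted_w <- matrix(wm1, G, n)
  fitted_w[, g2] <- wm2
  s2 <- rowSums(w * (y - fitted_w)^2) / df_resid
  se_unscaled2 <- 1 / sw1 + 1 / sw2

  prior <- fit_variance_prior(s2, df_resid)
  if (is.finite(prior$d0)) {
    s2_post <- (prior$d0 * prior$s02 + df_resid * s2) / (prior$d0 + df_resid)
    df_total <- df_resid + prior$d0
  } else {
    s2_post <- rep(prior$s02, G)
    df_total <- 1e6
  }
  df_total <- min(df_total, 1e6)
  se <- sqrt(s2_post * se_unscaled2)

  # threshold test: is |logFC| significantly above the threshold?
  t_right <- (abs(logfc) - logfc_threshold) / se
  t_left <- (abs(logfc) + logfc_threshold) / se
  p <- pt(-t_right, df_total) + pt(-t_left, df_total)
  p <- pmin(p, 1)
  fdr <- p.adjust(p, method = "BH")

  res <- data.frame(gene = rownames(counts), logFC = logfc,
                    ave_logcpm = ave,
                    t = sign(logfc) * t_right, p = p, fdr = fdr,
                    significant = fdr < alpha,
                    stringsAsFactors = FALSE)
  attr(res, "d0") <- prior$d0
  attr(res, "s02") <- prior$s02
  attr(res, "df_total") <- df_total
  attr(res, "size_factors") <- sf
  attr(res, "logfc_threshold") <- logfc_threshold
  res
}

#' Relative log expression diagnostics
#'
#' Per-sample median relative log expression (log-cpm minus the per-gene
#' median across samples). Medians near zero indicate little unwanted
#' between-sample variation; this is a reporting aid, not a pass/fail
#' gate.
#'
#' @param pb A `pseudobulk_set` or genes x samples count matrix.
#' @return Named numeric vector of per-sample median RLEs.
#' @export
rle_stats <- function(pb) {
  counts <- if (inherits(pb, "pseudobulk_set")) pb$counts else as.matrix(pb)
  lc <- pb_logcpm(counts)
  rle <- lc - apply(lc, 1, median)
  apply(rle, 2, median)
}

#' Suggest a low-expression filter threshold
#'
#' Reports the deepest antimode of the density of per-gene maximum
#' log-cpm — the valley between the low-expression and expressed modes —
#' as an advisory threshold for [filter_low_expression()]. Returns `NA`
#' when the density is unimodal.
#'
#' @param pb A `pseudobulk_set` or genes x samples count matrix.
#' @return Suggested threshold (numeric scalar) or `NA`.
#' @export
suggest_expression_threshold <- function(pb) {
  counts <- if (inherits(pb, "pseudobulk_set")) pb$counts else as.matrix(pb)
  maxlc <- apply(pb_logcpm(counts), 1, max)
  v <- kde_valley(maxlc)
  if (is.null(v)) NA_real_ else v$valley
}
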