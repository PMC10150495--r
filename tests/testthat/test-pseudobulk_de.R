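make_two_sample_sections <- function(seeds = c(1, 2), treated = c(FALSE, TRUE)) {
  sims <- mapply(function(s, tr) simulate_section(
    simulation_config(grid_rows = 30, grid_cols = 30,
                      tumour_centre = c(15, 15), tumour_radius = 7,
                      n_genes_per_species = 160, programme_size = 20,
                      stratum_marker_size = 20, stratum_width = 3,
                      treatment = tr, seed = s)),
    seeds, treated, SIMPLIFY = FALSE)
  list(ds = lapply(sims, `[[`, "dataset"),
       truth = lapply(sims, `[[`, "truth"),
       calls = lapply(sims, function(x) suggested_call(x$dataset)))
}

test_that("pseudobulk sums the right spots and genes per compartment", {
  # explicit micro example: 2 spots, 2 genes, summation
  counts <- rbind(c(1, 2), c(3, 4))
  genes <- data.frame(gene_id = c("GRCh38_A", "GRCh38_B"),
                      symbol = c("A", "B"), species = "human")
  ds <- spot_dataset(counts, c("S1", "S2"),
                     rbind(genes),
                     data.frame(row = 0:1, col = 0), sample_id = "x")
  # need a mouse gene for scoring-free manual call construction
  call <- classify_spots(c(10, 10), c(0, 0),
                         list(h_c1 = 1, h_c2 = 1, m_c1 = 1, m_c2 = 1),
                         barcodes = c("S1", "S2"))
  pb <- pseudobulk(list(ds), list(call), "human", "control")
  expect_equal(unname(pb$counts[, 1]), c(4, 6))

  # synthetic sections against a direct group-by-sum oracle
  two <- make_two_sample_sections()
  pbh <- pseudobulk(two$ds, two$calls, "human", c("control", "treated"))
  s <- 1
  hum <- two$calls[[s]]$barcode[two$calls[[s]]$label == "human"]
  hg <- two$ds[[s]]$genes$gene_id[two$ds[[s]]$genes$species == "human"]
  oracle <- Matrix::colSums(two$ds[[s]]$counts[hum, hg])
  expect_equal(unname(pbh$counts[, s]), unname(oracle[rownames(pbh$counts)]))
  # conservation: column sums equal compartment totals over the gene subset
  expect_equal(unname(colSums(pbh$counts)[s]), sum(oracle))
  # the mixed-human compartment never contains a mouse gene
  pbm <- pseudobulk(two$ds, two$calls, "mix_human", c("control", "treated"))
  expect_false(any(startsWith(rownames(pbm$counts), "mm10_")))
  # empty compartment errors with the sample named
  no_mix <- lapply(two$calls, function(cl) { cl$label[cl$label == "mix"] <- "mouse"; cl })
  expect_error(pseudobulk(two$ds, no_mix, "mix_human", c("control", "treated")),
               "empty in sample")
})

test_that("low-expression filtering drops all-zero genes and applies the max log-cpm rule", {
  counts <- rbind(allzero = c(0, 0, 0, 0),
                  low = c(2, 1, 3, 2),
                  high = c(5000, 6000, 5500, 5800),
                  mid = c(60, 50, 70, 40))
  filler <- matrix(rpois(400, 30), 100, 4,
                   dimnames = list(paste0("f", 1:100), NULL))
  pb <- structure(list(counts = rbind(counts, filler),
                       group = factor(c("c", "c", "t", "t")),
                       compartment = "human",
                       sample_ids = paste0("s", 1:4)),
                  class = "pseudobulk_set")
  f <- suppressMessages(filter_low_expression(pb, min_logcpm = 2))
  expect_false("allzero" %in% rownames(f$counts))
  # direct-filter oracle
  lc <- log2(sweep(pb$counts, 2, colSums(pb$counts), "/") * 1e6 + 0.5)
  keep <- rowSums(pb$counts) > 0 & apply(lc, 1, max) >= 2
  expect_equal(rownames(f$counts), rownames(pb$counts)[keep])
  # a gene whose max log-cpm sits just below the threshold is dropped
  expect_true(all(apply(lc[rownames(f$counts), ], 1, max) >= 2))
})

test_that("TMM factors are 1 for identical and depth-scaled samples and match the oracle", {
  set.seed(13)
  base <- rpois(500, 100)
  ident <- cbind(a = base, b = base)
  expect_equal(unname(tmm_size_factors(ident)), c(1, 1), tolerance = 1e-9)
  doubled <- cbind(a = base, b = 2L * base)
  expect_equal(unname(tmm_size_factors(doubled)), c(1, 1), tolerance = 1e-6)
  # composition shift: 10% of genes 8-fold up in sample B
  shifted <- cbind(a = base, b = base)
  up <- seq_len(50)
  shifted[up, "b"] <- shifted[up, "b"] * 8L
  f <- tmm_size_factors(shifted)
  expect_equal(unname(f), oracle_tmm(shifted), tolerance = 1e-6)
  expect_lt(f["b"], 1)   # B's inflated library is corrected downwards
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  expect_error(tmm_size_factors(matrix(1:5, ncol = 1)), "two samples")
})

test_that("moderated test reduces to the ordinary test at threshold 0 and is monotone in the threshold", {
  sim <- simulate_pseudobulk(n_genes = 800, n_de = 60, n_per_group = 3, seed = 3)
  d0 <- moderated_de(sim$counts, sim$group, logfc_threshold = 0)
  d15 <- moderated_de(sim$counts, sim$group, logfc_threshold = 0.15)
  d40 <- moderated_de(sim$counts, sim$group, logfc_threshold = 0.4)
  # identical estimates, only the test changes
  expect_equal(d15$logFC, d0$logFC)
  # p-values are non-decreasing in the threshold for every gene
  expect_true(all(d15$p >= d0$p - 1e-12))
  expect_true(all(d40$p >= d15$p - 1e-12))
  # threshold-0 equals the two-sided moderated t
  idx <- abs(d0$logFC) > 1e-6
  p_ord <- 2 * pt(-abs(d0$t[idx]), df = attr(d0, "df_total"))
  expect_equal(d0$p[idx], p_ord, tolerance = 1e-9)
  # a gene with identical group means is not significant
  flat <- sim$counts
  flat[1, ] <- 1000L
  df <- moderated_de(flat, sim$group)
  expect_false(df$significant[1])
  expect_lt(abs(df$logFC[1]), 0.2)
})

test_that("planted effects are recovered with controlled false positives across seeds", {
  rec <- fp <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_pseudobulk(seed = s)
    de <- moderated_de(sim$counts, sim$group)
    rec[s] <- mean(de$significant[sim$truth$is_de])
    fp[s] <- mean(de$significant[!sim$truth$is_de])
  }
  expect_gte(mean(rec), 0.7)
  expect_lte(mean(fp), 0.05)
})

test_that("null simulations keep the discovery fraction at the nominal level", {
  frac <- numeric(40)
  for (s in 1:40) {
    sim <- simulate_pseudobulk(n_genes = 400, n_de = 0, n_per_group = 3,
                               seed = 1000 + s)
    de <- moderated_de(sim$counts, sim$group)
    frac[s] <- mean(de$significant)
  }
  expect_lte(mean(frac), 0.05)
})

test_that("direction of treatment effects from sections matches the planted programmes", {
  two <- make_two_sample_sections()
  # duplicate each condition so both groups have 2 samples
  more <- make_two_sample_sections(seeds = c(11, 12))
  ds <- c(two$ds[1], more$ds[1], two$ds[2], more$ds[2])
  calls <- c(two$calls[1], more$calls[1], two$calls[2], more$calls[2])
  pb <- pseudobulk(ds, calls, "human",
                   c("control", "control", "treated", "treated"))
  pb <- suppressMessages(filter_low_expression(pb))
  de <- moderated_de(pb)
  tg <- two$truth[[1]]$genes
  prog <- tg$programme[match(de$gene, tg$gene_id)]
  expect_lt(mean(de$logFC[which(prog == "cycling")]), 0)
  expect_gt(mean(de$logFC[which(prog == "neuronal")]), 0)
  # estimated logFC associates positively with the generator's analytic
  # truth (each section draws its own baseline, so the association is
  # directional rather than calibrated)
  truth_lfc <- tg$true_logfc[match(de$gene, tg$gene_id)]
  expect_gt(cor(de$logFC, truth_lfc), 0.4)
})

test_that("moderated results broadly agree with an established moderated pipeline", {
  skip_if_not_installed("limma")
  skip_if_not_installed("edgeR")
  sim <- simulate_pseudobulk(n_genes = 600, n_de = 50, n_per_group = 3, seed = 8)
  de <- moderated_de(sim$counts, sim$group, logfc_threshold = 0.15)
  dge <- edgeR::DGEList(sim$counts, group = sim$group)
  dge <- edgeR::calcNormFactors(dge)
  design <- model.matrix(~sim$group)
  v <- limma::voom(dge, design)
  fit <- limma::eBayes(limma::lmFit(v, design))
  tr <- limma::treat(limma::lmFit(v, design), lfc = 0.15)
  tt <- limma::topTreat(tr, coef = 2, number = Inf, sort.by = "none")
  expect_gt(cor(de$logFC, tt$logFC), 0.98)
  expect_gt(cor(rank(de$p), rank(tt$P.Value)), 0.9)
})

test_that("RLE medians sit near zero for well-behaved libraries", {
  sim <- simulate_pseudobulk(n_genes = 500, n_de = 0, n_per_group = 3, seed = 2)
  r <- rle_stats(sim$counts)
  expect_lt(max(abs(r)), 0.1)
})
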