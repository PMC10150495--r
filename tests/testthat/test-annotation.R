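ref_fixture <- function(seed = 1) {
  ref <- simulate_reference(seed = seed)
  logref <- log1p(1e6 * sweep(ref$counts, 2, colSums(ref$counts), "/"))
  list(raw = ref, log = logref)
}

test_that("reference aggregation handles single cells, identical cells and separated sub-blobs", {
  # one cell per label: its own profile
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- paste0("G", 1:3)
  pr <- aggregate_reference(m, c("T1", "T2"), ncenters = 3)
  expect_equal(unname(pr$profiles[, pr$profile_labels == "T1"]), c(1, 2, 3))
  # identical cells within a label: all centres equal the common profile
  m2 <- matrix(rep(c(1, 2, 3), 6), 3, 6)
  rownames(m2) <- paste0("G", 1:3)
  pr2 <- aggregate_reference(m2, rep("T", 6), ncenters = 3)
  for (j in seq_len(ncol(pr2$profiles)))
    expect_equal(unname(pr2$profiles[, j]), c(1, 2, 3))
  # two well-separated sub-blobs: centres match the blob means
  set.seed(2)
  blob <- cbind(matrix(rnorm(4 * 10, 0, 0.01), 4, 10),
                matrix(rnorm(4 * 10, 5, 0.01), 4, 10))
  rownames(blob) <- paste0("G", 1:4)
  pr3 <- aggregate_reference(blob, rep("T", 20), ncenters = 2)
  centre_means <- unname(apply(pr3$profiles, 2, mean))
  expect_equal(sort(round(centre_means)), c(0, 5))
  blob_means <- c(mean(blob[, 1:10]), mean(blob[, 11:20]))
  expect_equal(sort(centre_means), sort(blob_means), tolerance = 0.01)
  expect_error(aggregate_reference(m, c("T1", NA)), "zero cells|labels")
})

test_that("marker selection recovers disjoint blocks and respects de_n capping", {
  fx <- ref_fixture()
  pr <- aggregate_reference(fx$log, fx$raw$labels, ncenters = 3)
  sel <- select_marker_genes(pr, de_n = 25, method = "classic_lfc")
  # every type's planted marker block is recovered in the union
  for (ty in names(fx$raw$markers))
    expect_true(all(fx$raw$markers[[ty]] %in% sel$selected_genes))
  # de_n equal to the gene count returns everything
  sel_all <- select_marker_genes(pr, de_n = nrow(fx$log))
  expect_setequal(sel_all$selected_genes, rownames(fx$log))
  expect_warning(select_marker_genes(pr, de_n = 1e5), "capped")
  # 3-label pairwise brute-force oracle for classic_lfc
  small <- matrix(c(5, 1, 1,  1, 5, 1,  1, 1, 5), 3, 3,
                  dimnames = list(paste0("G", 1:3), NULL))
  prs <- aggregate_reference(small, c("A", "B", "C"), ncenters = 1)
  s1 <- select_marker_genes(prs, de_n = 1)
  oracle <- character(0)
  for (a in c("A", "B", "C")) for (b in setdiff(c("A", "B", "C"), a)) {
    diffv <- small[, match(a, c("A", "B", "C"))] - small[, match(b, c("A", "B", "C"))]
    oracle <- union(oracle, names(which.max(diffv)))
  }
  expect_setequal(s1$selected_genes, oracle)
})

test_that("spot classification is a Spearman nearest-label rule with rank invariance", {
  fx <- ref_fixture()
  pr <- aggregate_reference(fx$log, fx$raw$labels, ncenters = 3)
  pr <- select_marker_genes(pr, de_n = 40)
  # a spot equal to a profile gets that label with score 1
  prof1 <- pr$profiles[, 1]
  q <- rbind(prof1, exp(prof1))       # second row: monotone transform
  colnames(q) <- rownames(pr$profiles)
  ann <- classify_spots_by_reference(q, pr)
  expect_equal(ann$label, rep(pr$profile_labels[1], 2))
  expect_equal(ann$score, c(1, 1), tolerance = 1e-9)
  # constant spot is unassigned and flagged
  qc <- rbind(rep(1, nrow(pr$profiles)))
  colnames(qc) <- rownames(pr$profiles)
  annc <- classify_spots_by_reference(qc, pr)
  expect_true(is.na(annc$label))
})

test_that("classification scores equal a direct rank-then-Pearson oracle", {
  set.seed(14)
  genes <- paste0("G", 1:20)
  profiles <- matrix(rnorm(20 * 3), 20, 3,
                     dimnames = list(genes, c("A", "B", "C")))
  pr <- structure(list(profiles = profiles,
                       profile_labels = c("A", "B", "C"),
                       ncenters = 1, selected_genes = genes),
                  class = "reference_profiles")
  q <- matrix(rnorm(5 * 20), 5, 20, dimnames = list(NULL, genes))
  ann <- classify_spots_by_reference(q, pr)
  sc <- attr(ann, "scores")
  for (i in 1:5) for (j in 1:3) {
    oracle <- cor(rank(q[i, ]), rank(profiles[, j]))
    expect_equal(unname(sc[i, j]), oracle, tolerance = 1e-9)
  }
})

test_that("pure synthetic spots are annotated accurately at the stated noise level", {
  accs <- numeric(3)
  for (s in 1:3) {
    fx <- ref_fixture(seed = s)
    pr <- aggregate_reference(fx$log, fx$raw$labels, ncenters = 3)
    pr <- select_marker_genes(pr, de_n = 50)
    set.seed(100 + s)
    types <- unique(fx$raw$labels)
    type_means <- sapply(types, function(ty)
      rowMeans(fx$raw$counts[, fx$raw$labels == ty]))
    qlab <- sample(types, 80, replace = TRUE)
    q <- sapply(qlab, function(ty)
      rnbinom(nrow(type_means), mu = 2000 * type_means[, ty] / sum(type_means[, ty]),
              size = 1 / 0.5))
    qn <- t(log1p(1e6 * sweep(q, 2, colSums(q), "/")))
    colnames(qn) <- rownames(fx$raw$counts)
    ann <- classify_spots_by_reference(qn, pr)
    accs[s] <- mean(ann$label == qlab)
  }
  expect_gte(mean(accs), 0.95)
})

test_that("species-aware annotation maps each compartment to its own reference", {
  sim <- simulate_section(simulation_config(
    grid_rows = 30, grid_cols = 30, tumour_centre = c(15, 15),
    tumour_radius = 7, n_genes_per_species = 160, programme_size = 20,
    stratum_marker_size = 20, stratum_width = 3, seed = 5))
  ds <- sim$dataset
  call <- suggested_call(ds)
  hg <- ds$genes$gene_id[ds$genes$species == "human"]
  mg <- ds$genes$gene_id[ds$genes$species == "mouse"]
  h_ref <- simulate_reference(n_types = 2, n_genes = length(hg),
                              gene_ids = hg, type_names = c("Tumour", "Neuron"),
                              seed = 2)
  m_ref <- simulate_reference(n_types = 3, n_genes = length(mg),
                              gene_ids = mg,
                              type_names = c("Astro", "Granule", "Oligo"),
                              seed = 3)
  prep <- function(r) {
    lg <- log1p(1e6 * sweep(r$counts, 2, colSums(r$counts), "/"))
    select_marker_genes(aggregate_reference(lg, r$labels), de_n = 40)
  }
  ann <- annotate_dataset(ds, call, prep(h_ref), prep(m_ref))
  n_mix <- sum(call$label == "mix")
  expect_equal(nrow(ann$human), sum(call$label == "human") + n_mix)
  expect_equal(nrow(ann$mouse), sum(call$label == "mouse") + n_mix)
  # mix spots carry annotations from both references
  mix_bc <- call$barcode[call$label == "mix"]
  expect_true(all(mix_bc %in% ann$human$barcode))
  expect_true(all(mix_bc %in% ann$mouse$barcode))
  expect_true(all(ann$human$label %in% c("Tumour", "Neuron", NA)))
  expect_true(all(ann$mouse$label %in% c("Astro", "Granule", "Oligo", NA)))
  # a missing reference for a present species is an error
  expect_error(annotate_dataset(ds, call, prep(h_ref), NULL), "missing mouse")
})
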