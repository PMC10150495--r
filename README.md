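# xenohet

Species-stratified analysis of xenograft spatial transcriptomics in R.

Patient-derived orthotopic xenograft (PDOX) brain tumours are hybrid
tissues: human tumour cells grow inside mouse brain, and a spatial
transcriptomics section mapped against a combined GRCh38+mm10 reference
yields, for every ~55 µm array spot, UMI counts over both species' genes.
`xenohet` implements the analysis stack such an experiment needs:

* **Species classification.** Each spot gets a human score
  `h = Σ_human genes x̃_g` and mouse score `m = Σ_mouse genes x̃_g` (sums of
  normalised, unscaled expression). With per-sample cutoffs, a spot is
  *human* iff `h > h_c1 ∧ m < m_c1`, *mouse* iff `m > m_c2 ∧ h < h_c2`,
  and *mix* otherwise — mixed spots trace the tumour–brain interface.
  A KDE valley finder proposes cutoffs; configured values always win.
* **Clustering heterogeneity.** Louvain partitions over a resolution grid
  (0.1–1.2, step 0.05; 23 resolutions) on a 50-NN graph built from the
  top 50 PCs, scored per resolution by Shannon entropy
  `H = −Σ p_c ln p_c`, Simpson index `D = Σ p_c²`, Newman–Girvan
  modularity, and the Handl–Knowles connectivity index
  `CI = Σ_i Σ_{j≤L} 1/j · [nn_j(i) ∉ cluster(i)]`, plus cluster-tree
  edges, per-spot neighbourhood entropy at a reference resolution (0.8),
  and base-2 Jensen–Shannon divergence between samples' entropy
  distributions.
* **Per-spot gene-set activity (PAGE).** For a set of `m` genes with mean
  fold change `S_m` in a spot, `E = (S_m − μ)·√m / δ`, where `μ` and `δ`
  are the mean and population SD of that spot's fold changes over all
  genes.
* **Pseudobulk differential expression.** Per-sample, per-compartment
  summed counts (human / mouse / mix×human / mix×mouse), max-log-cpm
  gene filtering (defaults 2/2/3/3), TMM size factors, and a moderated
  test with mean–variance precision weights, empirical-Bayes variance
  shrinkage and a fold-change threshold (`|logFC| > 0.15` at FDR 0.05).
* **Reference annotation.** Per-type aggregated profiles (k-means,
  `ncenters = 3`), pairwise marker selection, Spearman nearest-label
  classification; mixed spots are annotated against both species'
  references.
* **Interface enrichment.** The border = mixed spots with both human and
  mouse neighbours; one-sided Fisher exact test (hypergeometric tail)
  for cell-type enrichment in the border versus the remaining mouse
  tissue (or the tumour).
* **Synthetic sections.** A seeded generator producing a hybrid section —
  human tumour disk, mixed interface ring, layered mouse strata,
  negative-binomial counts — with full ground truth, so everything above
  is testable without any download.

## Worked example

```r
library(xenohet)

sim  <- simulate_section(simulation_config(seed = 1))
ds   <- filter_low_quality_spots(sim$dataset, min_genes = 200)
sc   <- species_scores(ds)
cuts <- suggest_cutoffs(sc$h_scores, sc$m_scores)$cutoffs
call <- classify_spots(sc$h_scores, sc$m_scores, cuts)
table(call$label)
#> human   mix mouse
#>   317   124  1159

hum  <- which(call$label == "human")
norm <- normalise_counts(ds[hum, ], "logcpm")
emb  <- build_embedding_graph(norm, n_pcs = 50, k = 50)
scan <- resolution_scan(emb, seed = 0, coords = ds$array_coords[hum, ])
scan
#> resolution_scan: 23 resolutions (0.10-1.20), ci_total = 1103.0
```

The 1600-spot section splits cleanly into 317 human, 124 interface (mix)
and 1159 mouse spots — here identical to the generator's ground truth —
and the untreated tumour's 23-resolution scan accumulates a total
connectivity of ~1100 (treated sections land near 0, reflecting their
collapsed heterogeneity; see the methods vignette).

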