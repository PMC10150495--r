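---
title: "Methods: species-stratified analysis of xenograft spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-stratified analysis of xenograft spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`xenohet` analyses spatial transcriptomics sections of orthotopic
xenografts in which human tumour tissue grows inside mouse brain and
reads are mapped to a hybrid GRCh38+mm10 reference. This vignette is the
package's account of the underlying models, the parameters that matter,
and the design decisions taken where the methodology was genuinely open.

## Species classification

Every gene carries a species tag derived from its reference prefix
(`GRCh38_` / `mm10_`, configurable). For each spot we sum the
*normalised, unscaled* expression over each species' genes:

$$h_i = \sum_{g \in \text{human}} \tilde{x}_{ig}, \qquad
  m_i = \sum_{g \in \text{mouse}} \tilde{x}_{ig}.$$

Summing unscaled values (no per-gene z-scaling) keeps a single
over-abundant gene from dominating a score. The default normaliser is
`log1p` of median-library-scaled counts; the normaliser is pluggable so a
variance-stabilised residual matrix can be supplied instead when one is
available — we deliberately do not re-implement model-based residual
normalisation.

Labels come from per-sample cutoffs:

* human: $h_i > h_{c1} \wedge m_i < m_{c1}$
* mouse: $m_i > m_{c2} \wedge h_i < h_{c2}$
* mix: everything else.

Cutoff validity ($m_{c1} \le m_{c2}$, $h_{c2} \le h_{c1}$) guarantees the
first two predicates are mutually exclusive, so the three labels always
partition the spots. Inequalities are strict; a score exactly at a cutoff
drifts to *mix*, the conservative class. Note a spot with moderate scores
on both axes can legitimately satisfy the mouse predicate — the mix class
is the complement of the two predicates, not a band around the diagonal.

Cutoff choice is fundamentally per-sample and, in practice, manual.
`suggest_cutoffs()` automates the common case: it finds the deepest
valley of each score's kernel density estimate (the gap between the
"absent" and "present" modes) and places the paired cutoffs symmetrically
at ± half the KDE bandwidth around it. A unimodal score yields a proposal
flagged `manual_review`; configured cutoffs always override suggestions.
`apply_region_override()` supports histology-driven relabelling (e.g.
declaring low-level human signal outside any tumour region to be mouse);
overrides are recorded with provenance and do not survive
re-classification, which stays a pure function of scores and cutoffs.

## Preprocessing

* `logcpm`: $\log_2(10^6 x/\text{lib} + 0.5)$. The offset keeps zeros
  finite; base 2 follows the dominant convention for log-cpm even though
  "log" is often written unqualified — only relative comparisons are
  affected.
* Gene filter: total count ≥ 50; spot filter: ≥ 200 detected genes.
* `spatial_smooth()` is an expression+location surrogate for
  morphology-aware smoothing: each spot is blended with the mean of its
  Chebyshev-radius grid neighbours,
  $(1-\alpha)\,x_i + \alpha\,\bar{x}_{N(i)}$. Histology images are out of
  scope, so the morphology term of the original correction is absent —
  the surrogate preserves the operator's interface and its spatial
  locality, not its exact output.
* `build_embedding_graph()`: exact SVD-based PCA (deterministic; no
  randomised solver at these sizes), k nearest neighbours in PC space,
  union-symmetrised edges weighted by shared-neighbour similarity
  $(|N_i \cap N_j| + 1)/(k+1)$ — the +1 keeps every retained edge's
  weight positive, which downstream modularity requires.

## Heterogeneity across a resolution scan

Louvain community detection runs once per resolution on the grid 0.1–1.2
(step 0.05, 23 values), with the quality
$Q(\gamma)=\sum_c [e_c/m - \gamma (K_c/2m)^2]$. The RNG seed is re-set
before each resolution, so the scan is deterministic and insensitive to
grid order. Per resolution we report:

* Shannon entropy $H=-\sum_c p_c \ln p_c$ (nats): uncertainty of cluster
  membership; high = heterogeneous.
* Simpson index $D=\sum_c p_c^2$: probability two random spots share a
  cluster; low = heterogeneous.
* Modularity at $\gamma=1$ on the embedding graph.
* Connectivity index (Handl–Knowles):
  $CI=\sum_i \sum_{j=1}^{L} \tfrac{1}{j}\,[\text{nn}_j(i) \notin c(i)]$
  with $L=10$ PC-space neighbours; it penalises partitions that split
  similar spots.

Two quantities required interpretive decisions that the source
methodology leaves open:

* **CI aggregation.** One connectivity value is reported per sample for
  a whole resolution scan without a stated aggregation; we report
  per-resolution values *and* define the headline `ci_total` as their sum
  over the 23-point grid. Users comparing absolute CI magnitudes across
  studies should be aware of this choice.
* **Per-spot entropy.** Hard Louvain labels admit no per-spot
  uncertainty, so the per-spot entropy at the reference resolution
  (default 0.8) is defined over *spatial* neighbourhoods: the entropy of
  cluster labels among a spot's `k_neigh = 20` nearest array neighbours,
  itself included. This is the largest interpretive decision in the
  package; a soft-assignment entropy would need a different clustering
  algorithm.

Between-sample similarity of per-spot entropy distributions uses the
Jensen–Shannon divergence on 50 shared equal-width bins, base 2 (so
JSD ∈ [0, 1]); empty bins contribute nothing and a degenerate pooled
range returns 0 with a warning. Entropy uses natural logs, JSD base 2 —
the two conventions serve different comparisons and are not mixed.

## Per-spot gene-set activity (PAGE)

Fold changes are per-gene centred log expression,
$f_{ig} = \tilde{x}_{ig} - \overline{\tilde{x}_{\cdot g}}$. For a gene
set with $m$ resolved members,

$$E_i = \frac{(S_m - \mu_i)\sqrt{m}}{\delta_i},$$

where $S_m$ is the mean member fold change in spot $i$ and $\mu_i,
\delta_i$ are the mean and **population** standard deviation of the fold
changes over *all* genes in the spot. The "all genes" scoping of
$\mu,\delta$ is essential: taken over set members alone the statistic is
identically zero, so the only self-consistent reading is the published
parametric enrichment z-statistic, which we follow. The population
(rather than $n-1$) denominator matches that statistic's derivation; at
genome scale the difference is negligible. Sets with no resolved members
give `NA` (never a silent 0), as do spots with zero dispersion.
DE-restricted scoring is available by intersecting each set with a
supplied gene list before scoring.

## Pseudobulk differential expression

Counts are summed over all spots of one compartment per sample. The
compartment fixes both the spots and the genes: human spots/human genes,
mouse spots/mouse genes, and the mixed interface analysed twice (human
genes, mouse genes). Filtering removes genes that are all-zero and genes
whose *maximum* log-cpm across samples is below the threshold — defaults
2, 2, 3, 3 for human, mouse, mix-human, mix-mouse, the mixed thresholds
being higher because their low-expression mode sits at higher log-cpm.
`suggest_expression_threshold()` reports the antimode of the per-gene max
log-cpm density as an advisory value; `rle_stats()` reports median
relative log expression per sample as a diagnostic, with no automated
pass/fail.

Size factors are trimmed-mean-of-M-values (TMM; delegated to the
established count-normalisation implementation behind the package's own
surface). The moderated test is authored in the package as a simplified
counterpart of the precision-weighted moderated-t stack:

1. log-cpm on TMM-adjusted effective library sizes
   ($\log_2((x+0.5)/(\text{lib}\cdot f+1)\cdot 10^6)$);
2. observation-level precision weights from a lowess trend of
   $\sqrt{\text{residual SD}}$ on mean log-cpm, evaluated at fitted
   values (weights $=\text{trend}^{-4}$);
3. weighted two-group fits; empirical-Bayes shrinkage of residual
   variances via a method-of-moments fit of a scaled inverse-chi-square
   prior on the log scale (trigamma inversion yields the prior df $d_0$
   and prior variance $s_0^2$);
4. a fold-change threshold test:
   $p = P(T \ge \tfrac{|\widehat{\beta}|-\tau}{se}) +
        P(T \ge \tfrac{|\widehat{\beta}|+\tau}{se})$
   with $T \sim t_{d_0+df}$ and $\tau = 0.15$ by default, then
   Benjamini–Hochberg FDR at 0.05.

At $\tau = 0$ this reduces exactly to the two-sided moderated t-test, and
$p$ is non-decreasing in $\tau$ for every gene. Exact numerical parity
with the published stack is explicitly not a goal; correctness is
asserted against simulation ground truth, and one test cross-checks
broad agreement (logFC correlation > 0.98, p-value rank correlation >
0.9) with the established pipeline. With two samples per group, no
sample-level blocking is used.

## Reference-based annotation

A labelled reference is aggregated per cell type by seeded k-means
(`ncenters = 3`) on top PCs of that type's cells, each centre averaged
into one log-expression profile. Marker genes are selected per ordered
label pair by mean-difference ranking (`classic_lfc`, top 350 by
default) or a two-sample t statistic across centre profiles (`t_stat`,
top 200), unioned. Spots are assigned the label whose profiles maximise
Spearman correlation on the selected genes; the per-label score is the
max over that label's ≤ 3 profiles (with so few profiles the reference
tool's 0.8-quantile effectively degenerates to the max — recorded as a
deviation). Classification is single-pass (no iterative fine-tuning) and
invariant to any per-spot monotone transform; constant spots are left
unassigned and ties are flagged. Species-aware orchestration maps
human/mix spots against the human reference on human genes only and
mouse/mix spots against the mouse reference on mouse genes; mixed spots
retain both annotations.

## Interface analysis

The border region is the set of mix-labelled spots with at least one
human *and* one mouse neighbour within a Chebyshev radius (default 1 on
the square lattice); isolated mixed spots deep in the bulk are excluded.
Enrichment of a cell type in the border uses the one-sided (greater)
Fisher exact test computed as the hypergeometric tail of the 2×2 table;
odds ratios use a Haldane 0.5 correction only when a cell is zero, and
only for reporting. The source methods name two different comparison
regions in adjacent sentences; we follow the contingency-table sentence
and default to the **remaining mouse tissue**, with the tumour region
available via `comparison = "tumour"` — the discrepancy is surfaced
rather than hidden.

## The synthetic-section generator

`simulate_section()` emulates the structure such an experiment produces:
a pure-human tumour disk (radius 10 on a 40×40 lattice), a mixed
interface ring (width 2; human fraction falling linearly 0.8 → 0.2
across the ring), and three concentric mouse strata with 40-gene marker
programmes (5×). Counts are negative binomial (dispersion 0.5) around
fraction-weighted species profiles scaled by log-normal library sizes
(meanlog log 5000, sdlog 0.3); a 0.5% ambient cross-species leak makes
cutoff selection non-trivial. A square lattice with Chebyshev adjacency
replaces the hexagonal array — neighbour enumeration is simpler and
nothing downstream depends on hex geometry.

The two treatment configurations encode opposite heterogeneity regimes:

* **Untreated:** the cycling programme (50 genes, 6×) is active across
  the whole tumour, and the core is overlaid with three *graded* angular
  territories (von Mises soft assignment, sharpness 8) activating the
  progenitor and neuronal programmes at peak 10×. The intergrading
  territory boundaries produce spots that are genuinely intermediate, so
  multi-resolution clustering keeps splitting similar spots — high
  Shannon entropy, low Simpson index, high connectivity.
* **Treated:** cycling is suppressed to 0.25× in the core only (the
  interface keeps cycling at 6×) and the neuronal programme becomes
  dominant (18×) in a sharply bounded island covering half the core. Few
  well-separated states give low entropy, high Simpson, and a
  connectivity near zero.

This design was chosen deliberately: a spatially *uniform* treated core
is unrealistic — resolution-parameterised Louvain shreds a structureless
point cloud into arbitrary fragments, maximising the connectivity
penalty — whereas real treated tumours retain sharply bounded
differentiated regions. Conversely, untreated tumour heterogeneity is an
intergrading continuum of transcriptional states, not three disjoint
blocks. Per-gene ground truth includes the exact expected
human-pseudobulk log2 fold change implied by the mean model over the
section's own geometry. Mouse-containing spots also carry a true cell
type, with astrocytes planted at probability 0.45 in the interface ring
versus 0.15 elsewhere (a 3× enrichment) to exercise the Fisher stage.

Two companion generators scale specific stages: `simulate_reference()`
(5 cell types × 50 cells, disjoint 25-gene marker blocks at 8×, NB
dispersion 0.5) for the annotation stage, and `simulate_pseudobulk()`
(2000 genes, 2 vs 2 samples, 100 planted |log2FC| = 1 effects, library
3 × 10⁶, NB dispersion 0.01) for DE calibration. The pseudobulk
dispersion corresponds to a biological CV of 0.1 between replicate
libraries — the low end of published ranges, appropriate for pseudobulks
aggregating ~10³ spots from inbred xenograft hosts.

What the generator does **not** emulate: hexagonal spot packing, spot
segmentation/doublet structure, histology images, gene–gene correlation
beyond programme blocks, zero-inflation beyond NB sampling, batch or
section-placement effects, and any platform-specific noise. Passing
tests therefore demonstrate algorithmic correctness and directional
behaviour under controlled conditions, not performance on real Visium
data.

## Numerical choices and problem sizes

Exact SVD everywhere (deterministic); seeded k-means and Louvain;
Matrix-Market indices converted 1- to 0-based on IO; ties in Spearman
ranks mid-ranked; KDE valley depth must be strictly positive to count as
bimodal. Tests and the acceptance script use 40×40-spot sections
(~1600 spots, 600 genes), 5–10 seeded replicates per directional claim,
and 200 null replicates for the type-I error check — sizes at which every
stage is exercised end-to-end while the full suite runs in about a
minute.

## Known limitations

* The species-score normaliser is a stand-in for model-based residual
  normalisation; absolute score scales (and hence cutoff values) are not
  comparable to residual-based scores.
* `ci_total` depends on the resolution grid; compare only across scans
  with identical grids.
* The moderated DE test approximates, not replicates, the published
  precision-weighted stack; with n = 2 per group its variance prior is
  fitted from few residual degrees of freedom.
* Reference aggregation assumes the reference is already log-scale and
  reasonably balanced across types; no cross-reference label
  harmonisation is attempted.
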