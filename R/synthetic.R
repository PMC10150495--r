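#' Configuration for a synthetic hybrid two-species section
#'
#' Describes the geometry and expression model of a simulated xenograft
#' section: a spatially contiguous human tumour disk, a mixed-species
#' interface ring where the human fraction decays towards the host, and
#' concentric mouse-brain strata each carrying its own marker programme.
#' Counts are negative binomial with log-normal library sizes, which gives
#' downstream stages realistic UMI overdispersion.
#'
#' The human tumour carries three 50-gene transcriptional programmes
#' (cycling, progenitor, neuronal). In the untreated configuration the
#' cycling programme is active across the whole tumour (core and the
#' human component of the interface) and the core is overlaid with
#' `n_patches` *graded* angular territories (von Mises soft assignment,
#' sharpness `territory_kappa`) activating the progenitor and neuronal
#' programmes at `territory_fold`; the intergrading territory boundaries
#' are what makes untreated tumours heterogeneous. Under
#' `treatment = TRUE` the cycling programme is multiplied by
#' `cycling_suppression` in the core only (the interface keeps cycling)
#' and the neuronal programme becomes dominant
#' (`programme_fold * neuronal_amplification`) in a sharply bounded
#' island covering half the core — few well-separated states, emulating
#' the collapse of transcriptional diversity under a spatially
#' restricted drug response.
#'
#' @param grid_rows,grid_cols Array grid size (square lattice).
#' @param tumour_centre Integer (row, col) of the tumour disk centre.
#' @param tumour_radius Radius (array units) of the pure-human core.
#' @param interface_width Width of the mixed interface ring.
#' @param n_strata Number of concentric mouse strata beyond the interface.
#' @param stratum_width Width of each mouse stratum band.
#' @param n_genes_per_species Genes simulated per species.
#' @param programme_size Genes per human programme.
#' @param programme_fold Activation fold of a programme in its domain.
#' @param stratum_marker_size,stratum_marker_fold Mouse stratum markers.
#' @param n_patches Spatial programme territories in the untreated core.
#' @param territory_fold Peak activation of the graded territory
#'   programmes in the untreated core.
#' @param territory_kappa Von Mises sharpness of the angular territory
#'   boundaries (higher = narrower intergrading zones).
#' @param treatment Logical; apply the treatment effect?
#' @param cycling_suppression Multiplier applied to the cycling programme
#'   in core spots under treatment (< 1 suppresses).
#' @param neuronal_amplification Extra multiplier on the neuronal
#'   programme in core spots under treatment.
#' @param mix_fraction_profile Function mapping relative depth into the
#'   interface ring (0, 1] to the human fraction of a mixed spot.
#' @param leak Ambient cross-species leak rate (fraction of the opposite
#'   species' profile present in pure spots).
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size parameters.
#' @param dispersion Per-gene negative-binomial dispersion (scalar).
#' @param astro_prob_interface,astro_prob_bulk Probability that a
#'   mouse-containing spot is truly an astrocyte/Bergmann-glia spot, in
#'   the interface ring versus elsewhere.
#' @param seed Integer seed; the draw is fully deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(grid_rows = 40, grid_cols = 40,
                              tumour_centre = NULL, tumour_radius = 10,
                              interface_width = 2,
                              n_strata = 3, stratum_width = 5,
                              n_genes_per_species = 300,
                              programme_size = 50, programme_fold = 6,
                              stratum_marker_size = 40,
                              stratum_marker_fold = 5,
                              n_patches = 3,
                              territory_fold = 10,
                              territory_kappa = 8,
                              treatment = FALSE,
                              cycling_suppression = 0.25,
                              neuronal_amplification = 3,
                              mix_fraction_profile = function(t) 0.8 - 0.6 * t,
                              leak = 0.005,
                              libsize_meanlog = log(5000),
                              libsize_sdlog = 0.3,
                              dispersion = 0.5,
                              astro_prob_interface = 0.45,
                              astro_prob_bulk = 0.15,
                              seed = 1) {
  if (is.null(tumour_centre))
    tumour_centre <- c(floor(grid_rows / 2), floor(grid_cols / 2))
  cfg <- list(grid_rows = grid_rows, grid_cols = grid_cols,
              tumour_centre = tumour_centre, tumour_radius = tumour_radius,
              interface_width = interface_width, n_strata = n_strata,
              stratum_width = stratum_width,
              n_genes_per_species = n_genes_per_species,
              programme_size = programme_size,
              programme_fold = programme_fold,
              stratum_marker_size = stratum_marker_size,
              stratum_marker_fold = stratum_marker_fold,
              n_patches = n_patches, territory_fold = territory_fold,
              territory_kappa = territory_kappa, treatment = treatment,
              cycling_suppression = cycling_suppression,
              neuronal_amplification = neuronal_amplification,
              mix_fraction_profile = mix_fraction_profile,
              leak = leak, libsize_meanlog = libsize_meanlog,
              libsize_sdlog = libsize_sdlog, dispersion = dispersion,
              astro_prob_interface = astro_prob_interface,
              astro_prob_bulk = astro_prob_bulk, seed = seed)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$grid_rows > 0, cfg$grid_cols > 0,
            cfg$tumour_radius > 0, cfg$interface_width >= 0,
            cfg$n_genes_per_species > 0, cfg$dispersion > 0,
            cfg$leak >= 0, cfg$leak < 1,
            cfg$cycling_suppression > 0, cfg$neuronal_amplification > 0)
  r_out <- cfg$tumour_radius + cfg$interface_width
  if (cfg$tumour_centre[1] - r_out < 0 ||
      cfg$tumour_centre[1] + r_out > cfg$grid_rows - 1 ||
      cfg$tumour_centre[2] - r_out < 0 ||
      cfg$tumour_centre[2] + r_out > cfg$grid_cols - 1)
    stop("tumour disk (radius + interface) must fit inside the grid")
  if (cfg$n_patches != 3)
    stop("the programme-territory model is defined for exactly 3 territories")
  if (3 * cfg$programme_size > cfg$n_genes_per_species)
    stop("human programmes exceed the human gene count")
  if (cfg$n_strata * cfg$stratum_marker_size > cfg$n_genes_per_species)
    stop("mouse stratum markers exceed the mouse gene count")
  if (cfg$interface_width > 0) {
    geo <- section_geometry(cfg)
    if (!any(geo$region == "interface"))
      stop("geometry yields zero interface spots although interface_width > 0")
  }
  invisible(cfg)
}

# Deterministic geometry: regions, human fractions and species labels on
# the array grid. Pure function of the config (no RNG).
section_geometry <- function(cfg) {
  rows <- rep(0:(cfg$grid_rows - 1), each = cfg$grid_cols)
  cols <- rep(0:(cfg$grid_cols - 1), times = cfg$grid_rows)
  d <- sqrt((rows - cfg$tumour_centre[1])^2 + (cols - cfg$tumour_centre[2])^2)
  r <- cfg$tumour_radius; w <- cfg$interface_width
  region <- ifelse(d <= r, "core",
                   ifelse(d <= r + w, "interface", "stratum"))
  stratum <- rep(NA_integer_, length(d))
  outer <- region == "stratum"
  stratum[outer] <- pmin(cfg$n_strata,
                         floor((d[outer] - r - w) / cfg$stratum_width) + 1L)
  region[outer] <- paste0("stratum_", stratum[outer])
  fraction <- numeric(length(d))
  fraction[region == "core"] <- 1
  ifc <- region == "interface"
  if (any(ifc)) {
    t_rel <- (d[ifc] - r) / max(w, 1e-9)
    fr <- cfg$mix_fraction_profile(t_rel)
    if (any(fr < 0 | fr > 1)) stop("mix_fraction_profile must stay in [0, 1]")
    fraction[ifc] <- fr
  }
  label <- ifelse(fraction == 1, "human", ifelse(fraction == 0, "mouse", "mix"))
  data.frame(row = rows, col = cols, dist = d, region = region,
             human_fraction = fraction, species_label = label,
             stringsAsFactors = FALSE)
}

#' Simulate a hybrid two-species spatial section
#'
#' Draws a seeded negative-binomial count matrix over the geometry encoded
#' in the config and returns it together with the full ground truth
#' (per-spot species labels and regions, per-gene programme membership and
#' the exact expected treatment log fold-change in the human compartment).
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `dataset` (a [spot_dataset()]) and `truth`
#'   (list of `spots` and `genes` data frames plus the config).
#' @export
simulate_section <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  geo <- section_geometry(cfg)
  n_spots <- nrow(geo)

  ng <- cfg$n_genes_per_species
  human_ids <- sprintf("GRCh38_HG%04d", seq_len(ng))
  mouse_ids <- sprintf("mm10_MG%04d", seq_len(ng))
  gene_ids <- c(human_ids, mouse_ids)
  genes <- data.frame(gene_id = gene_ids,
                      symbol = sub("^(GRCh38_|mm10_)", "", gene_ids),
                      species = rep(c("human", "mouse"), each = ng),
                      stringsAsFactors = FALSE)

  programme <- rep(NA_character_, 2 * ng)
  ps <- cfg$programme_size
  prog_idx <- list(cycling = 1:ps, progenitor = ps + 1:ps,
                   neuronal = 2 * ps + 1:ps)
  for (p in names(prog_idx)) programme[prog_idx[[p]]] <- p
  sm <- cfg$stratum_marker_size
  for (k in seq_len(cfg$n_strata)) {
    idx <- ng + (k - 1) * sm + 1:sm
    programme[idx] <- paste0("stratum_", k, "_marker")
  }
  genes$programme <- programme

  base_h <- rlnorm(ng, meanlog = 0, sdlog = 1)
  base_m <- rlnorm(ng, meanlog = 0, sdlog = 1)

  # graded angular programme territories over the tumour (control) and a
  # sharply bounded neuronal island over half the core (treated)
  theta <- atan2(geo$row - cfg$tumour_centre[1],
                 geo$col - cfg$tumour_centre[2])
  rot <- runif(1, 0, 2 * pi)
  wt <- vapply(seq_len(cfg$n_patches) - 1, function(k)
    exp(cfg$territory_kappa *
          cos(theta - rot - 2 * pi * k / cfg$n_patches)),
    numeric(n_spots))
  terr_w <- wt / rowSums(wt)
  territory <- max.col(terr_w, ties.method = "first")
  island_angle <- runif(1, 0, pi)
  island <- ((geo$row - cfg$tumour_centre[1]) * cos(island_angle) +
               (geo$col - cfg$tumour_centre[2]) * sin(island_angle)) > 0

  human_mult <- function(i) {
    m <- rep(1, ng)
    region <- geo$region[i]
    if (startsWith(region, "stratum")) return(m)
    if (!cfg$treatment) {
      m[prog_idx$cycling] <- cfg$programme_fold
      if (region == "core") {
        m[prog_idx$progenitor] <- 1 + (cfg$territory_fold - 1) * terr_w[i, 2]
        m[prog_idx$neuronal] <- 1 + (cfg$territory_fold - 1) * terr_w[i, 3]
      }
    } else {
      if (region == "core") {
        m[prog_idx$cycling] <- cfg$programme_fold * cfg$cycling_suppression
        if (island[i])
          m[prog_idx$neuronal] <- cfg$programme_fold * cfg$neuronal_amplification
      } else {
        m[prog_idx$cycling] <- cfg$programme_fold
      }
    }
    m
  }

  mouse_mult_for <- function(region) {
    m <- rep(1, ng)
    if (startsWith(region, "stratum_")) {
      k <- as.integer(sub("stratum_", "", region))
      m[(k - 1) * sm + 1:sm] <- cfg$stratum_marker_fold
    }
    m
  }

  # expected relative expression per spot (2*ng columns), then NB draw
  rel <- matrix(0, n_spots, 2 * ng)
  for (i in seq_len(n_spots)) {
    f <- geo$human_fraction[i]
    wh <- f + cfg$leak * (1 - f)
    wm <- (1 - f) + cfg$leak * f
    hv <- base_h * human_mult(i)
    mv <- base_m * mouse_mult_for(geo$region[i])
    v <- c(wh * hv / sum(hv), wm * mv / sum(mv))
    rel[i, ] <- v / sum(v)
  }

  libsize <- rlnorm(n_spots, cfg$libsize_meanlog, cfg$libsize_sdlog)
  mu <- rel * libsize
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = 1 / cfg$dispersion),
                   n_spots, 2 * ng)

  # ground-truth mouse cell type for mouse-containing spots (astrocyte
  # frequency planted higher in the interface ring)
  cell_type <- rep(NA_character_, n_spots)
  has_mouse <- geo$human_fraction < 1
  p_astro <- ifelse(geo$region == "interface", cfg$astro_prob_interface,
                    cfg$astro_prob_bulk)
  other_types <- c("Granule", "Oligodendrocyte", "Microglia", "Purkinje")
  is_astro <- runif(n_spots) < p_astro
  cell_type[has_mouse] <- ifelse(
    is_astro[has_mouse], "Astrocyte_Bergmann_glia",
    other_types[1 + (sample.int(length(other_types), sum(has_mouse),
                                replace = TRUE) - 1)])

  barcodes <- sprintf("SPOT_%05d", seq_len(n_spots))
  ds <- spot_dataset(counts, barcodes, genes,
                     data.frame(row = geo$row, col = geo$col),
                     sample_id = sprintf("sim_seed%d_%s", cfg$seed,
                                         if (cfg$treatment) "treated" else "control"))

  genes$true_logfc <- expected_treatment_logfc(cfg, geo, terr_w, island,
                                               base_h, prog_idx)
  tumour <- !startsWith(geo$region, "stratum")
  truth <- list(
    spots = data.frame(barcode = barcodes, row = geo$row, col = geo$col,
                       region = geo$region,
                       species_label = geo$species_label,
                       human_fraction = geo$human_fraction,
                       territory = ifelse(tumour, territory, NA_integer_),
                       island = ifelse(tumour, island, NA),
                       cell_type = cell_type,
                       stringsAsFactors = FALSE),
    genes = genes, config = cfg)
  class(truth) <- "ground_truth"
  list(dataset = ds, truth = truth)
}

# Exact expected log2 fold-change (treated vs control) of each human gene
# in the human-compartment pseudobulk, computed from the deterministic
# mean model over the section's own geometry; mouse genes get 0.
expected_treatment_logfc <- function(cfg, geo, terr_w, island, base_h,
                                     prog_idx) {
  human_spots <- which(geo$human_fraction == 1)
  total_for <- function(treated) {
    tot <- rep(0, cfg$n_genes_per_species)
    for (i in human_spots) {
      m <- rep(1, cfg$n_genes_per_species)
      if (!treated) {
        m[prog_idx$cycling] <- cfg$programme_fold
        m[prog_idx$progenitor] <- 1 + (cfg$territory_fold - 1) * terr_w[i, 2]
        m[prog_idx$neuronal] <- 1 + (cfg$territory_fold - 1) * terr_w[i, 3]
      } else {
        m[prog_idx$cycling] <- cfg$programme_fold * cfg$cycling_suppression
        if (island[i])
          m[prog_idx$neuronal] <- cfg$programme_fold * cfg$neuronal_amplification
      }
      v <- base_h * m
      tot <- tot + v / sum(v)
    }
    tot
  }
  lfc_h <- log2(total_for(TRUE) / total_for(FALSE))
  c(lfc_h, rep(0, cfg$n_genes_per_species))
}

#' Simulate a labelled single-cell reference
#'
#' Generates per-cell-type mean profiles with disjoint marker blocks and
#' within-type negative-binomial noise — a synthetic stand-in for an
#' annotated scRNA-seq reference atlas.
#'
#' @param n_types Number of cell types (or supply `type_names`).
#' @param cells_per_type Cells drawn per type (must be >= `ncenters` used
#'   downstream).
#' @param n_genes Total genes; marker blocks are carved from the front.
#' @param markers_per_type Marker genes per type.
#' @param marker_fold Fold elevation of a type's markers.
#' @param libsize Expected counts per cell.
#' @param dispersion NB dispersion of within-type noise.
#' @param gene_ids Optional gene ids (default `G0001`...), e.g. to share a
#'   namespace with a simulated section.
#' @param type_names Optional type labels.
#' @param seed Integer seed.
#' @return List with `counts` (genes x cells), `labels`, and `markers`
#'   (list of marker gene ids per type).
#' @export
simulate_reference <- function(n_types = 5, cells_per_type = 50,
                               n_genes = 250, markers_per_type = 25,
                               marker_fold = 8, libsize = 2000,
                               dispersion = 0.5, gene_ids = NULL,
                               type_names = NULL, seed = 1) {
  if (is.null(type_names))
    type_names <- c("Astrocyte_Bergmann_glia", "Granule", "Oligodendrocyte",
                    "Microglia", "Purkinje")[seq_len(n_types)]
  n_types <- length(type_names)
  if (cells_per_type < 1) stop("need at least one cell per type")
  if (n_types * markers_per_type > n_genes)
    stop("marker blocks exceed the gene count")
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  set.seed(seed)
  base <- rlnorm(n_genes, 0, 1)
  markers <- lapply(seq_len(n_types), function(k)
    gene_ids[(k - 1) * markers_per_type + 1:markers_per_type])
  names(markers) <- type_names
  counts <- matrix(0L, n_genes, n_types * cells_per_type)
  labels <- rep(type_names, each = cells_per_type)
  for (k in seq_len(n_types)) {
    mv <- base
    mv[(k - 1) * markers_per_type + 1:markers_per_type] <-
      mv[(k - 1) * markers_per_type + 1:markers_per_type] * marker_fold
    mu <- libsize * mv / sum(mv)
    idx <- (k - 1) * cells_per_type + 1:cells_per_type
    counts[, idx] <- rnbinom(n_genes * cells_per_type,
                             mu = rep(mu, cells_per_type),
                             size = 1 / dispersion)
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- sprintf("CELL_%04d", seq_len(ncol(counts)))
  list(counts = counts, labels = labels, markers = markers)
}

#' Simulate species-stratified pseudobulk libraries with planted effects
#'
#' Generates gene x sample negative-binomial pseudobulk counts for a
#' two-group design with a set of genes carrying a planted log2
#' fold-change (half up, half down), for calibrating the differential
#' expression stage.
#'
#' @param n_genes Total genes.
#' @param n_de Number of genes with a planted effect.
#' @param lfc Absolute planted log2 fold-change.
#' @param n_per_group Samples per group.
#' @param libsize Expected library size per sample.
#' @param dispersion NB dispersion (pseudobulk scale).
#' @param seed Integer seed.
#' @return List with `counts`, `group` (factor control/treated) and
#'   `truth` data.frame (`gene`, `true_lfc`, `is_de`).
#' @export
simulate_pseudobulk <- function(n_genes = 2000, n_de = 100, lfc = 1,
                                n_per_group = 2, libsize = 3e6,
                                dispersion = 0.01, seed = 1) {
  set.seed(seed)
  base <- rlnorm(n_genes, 0, 1.2)
  true_lfc <- rep(0, n_genes)
  de_idx <- sample.int(n_genes, n_de)
  signs <- rep(c(1, -1), length.out = n_de)
  true_lfc[de_idx] <- signs * lfc
  group <- factor(rep(c("control", "treated"), each = n_per_group),
                  levels = c("control", "treated"))
  counts <- matrix(0, n_genes, 2 * n_per_group)
  for (s in seq_along(group)) {
    mv <- if (group[s] == "treated") base * 2^true_lfc else base
    mu <- libsize * mv / sum(mv)
    counts[, s] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  rownames(counts) <- sprintf("G%05d", seq_len(n_genes))
  colnames(counts) <- paste0(group, "_", rep(seq_len(n_per_group), 2))
  list(counts = counts, group = group,
       truth = data.frame(gene = rownames(counts), true_lfc = true_lfc,
                          is_de = true_lfc != 0))
}
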