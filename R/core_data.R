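#' @importFrom Matrix readMM writeMM sparseMatrix rowSums colSums
#' @importFrom methods as is
#' @importFrom stats density median prcomp p.adjust pt phyper rnbinom rlnorm
#'   t.test approx lowess var sd cor kmeans setNames runif dist wilcox.test
#' @importFrom utils read.csv write.csv read.delim head
NULL

DEFAULT_SPECIES_PREFIXES <- c("GRCh38_" = "human", "mm10_" = "mouse")

#' Tag genes by species from a reference-prefix convention
#'
#' Hybrid-reference pipelines (e.g. SpaceRanger run on a combined
#' GRCh38+mm10 genome) prefix every feature id with the genome it came
#' from. This maps each gene id to a species via a configurable prefix
#' table.
#'
#' @param ids Character vector of gene ids.
#' @param prefixes Named character vector mapping id prefixes to species
#'   names, default `c("GRCh38_" = "human", "mm10_" = "mouse")`.
#' @return Character vector of species, same length as `ids`.
#' @export
tag_species <- function(ids, prefixes = DEFAULT_SPECIES_PREFIXES) {
  species <- rep(NA_character_, length(ids))
  for (p in names(prefixes)) {
    hit <- startsWith(ids, p)
    clash <- hit & !is.na(species)
    if (any(clash)) {
      stop("gene ids match more than one species prefix: ",
           paste(utils::head(ids[clash], 5), collapse = ", "))
    }
    species[hit] <- prefixes[[p]]
  }
  if (anyNA(species)) {
    bad <- ids[is.na(species)]
    stop("gene ids with unknown species prefix: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" ... (%d total)", length(bad)) else "")
  }
  species
}

#' Construct a spot dataset
#'
#' The central container: a spots x genes UMI count matrix plus barcodes,
#' species-tagged gene records, and array coordinates. Counts are kept
#' sparse; rows are spots, columns genes.
#'
#' @param counts Non-negative integer matrix or sparse Matrix, spots x genes.
#' @param barcodes Character vector of spot barcodes (unique).
#' @param genes data.frame with columns `gene_id`, `symbol`, `species`.
#' @param array_coords Integer matrix/data.frame with columns `row`, `col`
#'   (0-based array grid), one row per spot.
#' @param micron_coords Optional numeric matrix with columns `x`, `y`.
#' @param sample_id Sample identifier string.
#' @return An object of class `spot_dataset`.
#' @export
spot_dataset <- function(counts, barcodes, genes, array_coords,
                         micron_coords = NULL, sample_id = "sample") {
  counts <- methods::as(counts, "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  if (nrow(counts) != length(barcodes))
    stop("counts rows (", nrow(counts), ") != number of barcodes (",
         length(barcodes), ")")
  if (ncol(counts) != nrow(genes))
    stop("counts columns (", ncol(counts), ") != number of genes (",
         nrow(genes), ")")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  array_coords <- as.matrix(array_coords[, c("row", "col")])
  storage.mode(array_coords) <- "integer"
  if (nrow(array_coords) != length(barcodes))
    stop("array coordinates must cover every spot")
  if (anyNA(array_coords)) stop("missing array coordinates")
  rownames(counts) <- barcodes
  colnames(counts) <- genes$gene_id
  rownames(array_coords) <- barcodes
  structure(list(counts = counts, barcodes = barcodes,
                 genes = as.data.frame(genes, stringsAsFactors = FALSE),
                 array_coords = array_coords,
                 micron_coords = micron_coords, sample_id = sample_id),
            class = "spot_dataset")
}

#' @exportS3Method base::print
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset '%s': %d spots x %d genes (%d human, %d mouse)\n",
              x$sample_id, nrow(x$counts), ncol(x$counts),
              sum(x$genes$species == "human"), sum(x$genes$species == "mouse")))
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) dim(x$counts)

#' Subset a spot dataset by spots and/or genes
#' @param x A `spot_dataset`.
#' @param i Spot index (integer, logical or barcode).
#' @param j Gene index (integer, logical or gene id).
#' @param ... Ignored.
#' @export
`[.spot_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$barcodes)
  if (missing(j)) j <- seq_len(nrow(x$genes))
  if (is.character(i)) i <- match(i, x$barcodes)
  if (is.character(j)) j <- match(j, x$genes$gene_id)
  spot_dataset(x$counts[i, j, drop = FALSE], x$barcodes[i],
               x$genes[j, , drop = FALSE],
               x$array_coords[i, , drop = FALSE],
               if (!is.null(x$micron_coords)) x$micron_coords[i, , drop = FALSE],
               x$sample_id)
}

read_lines_maybe_gz <- function(path) {
  con <- file(path, "r")            # file() transparently decompresses gzip
  on.exit(close(con))
  readLines(con)
}

#' Read a 10x-style triplet spot dataset
#'
#' Reads a Matrix-Market count matrix with its barcode and feature sidecar
#' files plus a Visium-style positions table. The MTX may be laid out
#' either genes x spots (SpaceRanger convention) or spots x genes; the
#' orientation is resolved against the sidecar lengths (genes x spots wins
#' when square). Both the headered `tissue_positions` and the headerless
#' `tissue_positions_list` dialects are accepted, auto-detected by header
#' sniffing.
#'
#' @param matrix_path Path to the `.mtx` file (coordinate integer format).
#' @param barcodes_path Path to barcodes (one per line, optionally gz).
#' @param features_path Path to features TSV (id, symbol[, type]).
#' @param positions_path Path to positions CSV.
#' @param sample_id Sample identifier.
#' @param prefixes Species prefix map, see [tag_species()].
#' @return A [spot_dataset()].
#' @export
read_spot_dataset <- function(matrix_path, barcodes_path, features_path,
                              positions_path, sample_id = "sample",
                              prefixes = DEFAULT_SPECIES_PREFIXES) {
  m <- Matrix::readMM(matrix_path)
  barcodes <- read_lines_maybe_gz(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  feat_lines <- read_lines_maybe_gz(features_path)
  feat_lines <- feat_lines[nzchar(feat_lines)]
  feats <- do.call(rbind, strsplit(feat_lines, "\t"))
  gene_ids <- feats[, 1]
  symbols <- if (ncol(feats) >= 2) feats[, 2] else gene_ids
  nb <- length(barcodes); ng <- length(gene_ids)
  if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)               # SpaceRanger genes x spots layout
  } else if (nrow(m) == nb && ncol(m) == ng) {
    # already spots x genes
  } else {
    stop(sprintf("matrix dimensions %dx%d match neither %d genes x %d barcodes nor the transpose",
                 nrow(m), ncol(m), ng, nb))
  }
  species <- tag_species(gene_ids, prefixes)
  genes <- data.frame(gene_id = gene_ids, symbol = symbols,
                      species = species, stringsAsFactors = FALSE)
  pos <- read_positions(positions_path)
  idx <- match(barcodes, pos$barcode)
  if (anyNA(idx)) {
    stop("spots absent from positions table: ",
         paste(utils::head(barcodes[is.na(idx)], 5), collapse = ", "))
  }
  pos <- pos[idx, , drop = FALSE]
  micron <- NULL
  if (all(c("pxl_col_in_fullres", "pxl_row_in_fullres") %in% names(pos))) {
    micron <- cbind(x = pos$pxl_col_in_fullres, y = pos$pxl_row_in_fullres)
  }
  spot_dataset(m, barcodes, genes,
               data.frame(row = pos$array_row, col = pos$array_col),
               micron_coords = micron, sample_id = sample_id)
}

read_positions <- function(path) {
  first <- read_lines_maybe_gz(path)[1]
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  pos <- utils::read.csv(path, header = has_header,
                         stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(pos) < 4) stop("positions table needs >= 4 columns")
    names(pos) <- cols[seq_len(ncol(pos))]
  }
  if (!all(c("barcode", "array_row", "array_col") %in% names(pos)))
    stop("positions table lacks barcode/array_row/array_col columns")
  pos
}

#' Write a spot dataset in 10x-style triplet layout
#'
#' Inverse of [read_spot_dataset()]: writes `matrix.mtx` (genes x spots),
#' `barcodes.tsv`, `features.tsv` and a headered `tissue_positions.csv`.
#'
#' @param ds A `spot_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spot_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(ds$counts), file.path(dir, "matrix.mtx"))
  writeLines(ds$barcodes, file.path(dir, "barcodes.tsv"))
  writeLines(paste(ds$genes$gene_id, ds$genes$symbol, "Gene Expression",
                   sep = "\t"),
             file.path(dir, "features.tsv"))
  pos <- data.frame(barcode = ds$barcodes, in_tissue = 1L,
                    array_row = ds$array_coords[, "row"],
                    array_col = ds$array_coords[, "col"])
  if (!is.null(ds$micron_coords)) {
    pos$pxl_row_in_fullres <- ds$micron_coords[, "y"]
    pos$pxl_col_in_fullres <- ds$micron_coords[, "x"]
  }
  utils::write.csv(pos, file.path(dir, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' One set per tab-delimited line: name, description, then members.
#' Duplicate members within a set are de-duplicated with a warning giving
#' the total duplicate count.
#'
#' @param gmt_path Path to the GMT file.
#' @return Named list of character vectors (member gene ids), with per-set
#'   descriptions in `attr(, "description")`.
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- read_lines_maybe_gz(gmt_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t")
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, "", 1)
  n_dup <- sum(vapply(sets, function(m) sum(duplicated(m)), 0L))
  if (n_dup > 0) {
    warning(n_dup, " duplicate gene-set member(s) removed")
    sets <- lapply(sets, unique)
  }
  attr(sets, "description") <- vapply(fields, `[`, "", 2)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description")
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  }
  lines <- mapply(function(n, d, m) paste(c(n, d, m), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Resolve gene-set members against a dataset's gene list
#'
#' Unresolvable members are dropped but counted, never silently ignored.
#'
#' @param sets Named list of character vectors.
#' @param gene_ids Character vector of dataset gene ids.
#' @return List with `sets` (resolved members) and `n_unresolved` per set.
#' @export
resolve_gene_sets <- function(sets, gene_ids) {
  resolved <- lapply(sets, function(m) intersect(m, gene_ids))
  n_unres <- vapply(seq_along(sets),
                    function(i) length(sets[[i]]) - length(resolved[[i]]), 0L)
  names(n_unres) <- names(sets)
  list(sets = resolved, n_unresolved = n_unres)
}

#' Remove low-quality spots
#'
#' Drops spots with fewer than `min_genes` genes detected (count > 0),
#' the standard Visium QC rule.
#'
#' @param ds A `spot_dataset`.
#' @param min_genes Minimum detected-gene count to keep a spot (default 200).
#' @return Filtered `spot_dataset`; removal count is reported via `message`.
#' @export
filter_low_quality_spots <- function(ds, min_genes = 200) {
  stopifnot(min_genes >= 0)
  detected <- Matrix::rowSums(ds$counts > 0)
  keep <- detected >= min_genes
  if (!any(keep)) stop("all spots removed by the min_genes filter")
  n_rm <- sum(!keep)
  if (n_rm > 0)
    message(n_rm, " low-quality spot(s) removed (< ", min_genes,
            " genes detected)")
  ds[keep, ]
}
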