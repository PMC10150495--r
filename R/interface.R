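#' Define the tumour-brain border region
#'
#' The border is the set of mix-labelled spots that have at least one
#' human and at least one mouse neighbour within a Chebyshev radius on
#' the array grid. Mixed spots without both-species neighbours (e.g.
#' mouse infiltration deep in the tumour bulk) are excluded.
#'
#' @param call A `species_call`.
#' @param coords Array coordinates aligned with the call (row, col).
#' @param radius Chebyshev neighbourhood radius (default 1 = 8
#'   neighbours).
#' @return A `border_region`: list with `border_spots` (barcodes),
#'   `radius`, and the index vector `idx`.
#' @export
define_border <- function(call, coords, radius = 1) {
  stopifnot(inherits(call, "species_call"), nrow(call) == nrow(coords))
  labels <- call$label
  if (!any(labels == "mix")) {
    warning("no mix spots: empty border region")
    return(structure(list(border_spots = character(0), radius = radius,
                          idx = integer(0)), class = "border_region"))
  }
  nb <- chebyshev_neighbours(as.matrix(coords), radius)
  is_border <- vapply(seq_along(labels), function(i) {
    if (labels[i] != "mix") return(FALSE)
    nl <- labels[nb[[i]]]
    any(nl == "human") && any(nl == "mouse")
  }, FALSE)
  structure(list(border_spots = call$barcode[is_border], radius = radius,
                 idx = which(is_border)), class = "border_region")
}

#' One-sided Fisher enrichment of a cell type in the border
#'
#' Builds the 2x2 contingency table (target / other cell types, border /
#' comparison region) and computes the one-sided (greater) Fisher exact
#' p-value as the hypergeometric tail. The odds ratio uses a Haldane 0.5
#' correction when any cell is zero (reported only; the p-value always
#' comes from the uncorrected table).
#'
#' @param labels Named character vector: cell-type label per spot
#'   (names = barcodes).
#' @param border A `border_region` or character vector of border
#'   barcodes.
#' @param comparison Character vector of comparison-region barcodes
#'   (must be disjoint from the border, non-empty).
#' @param target Target cell-type label.
#' @return An `enrichment_table`: list with counts `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p` and the region sizes.
#' @export
fisher_enrichment <- function(labels, border, comparison, target) {
  border_ids <- if (inherits(border, "border_region")) border$border_spots else border
  if (length(comparison) == 0) stop("empty comparison region")
  if (length(intersect(border_ids, comparison)) > 0)
    stop("comparison region overlaps the border")
  lb <- labels[border_ids]
  lc <- labels[comparison]
  a <- sum(lb == target, na.rm = TRUE)
  b <- length(lb) - a
  cc <- sum(lc == target, na.rm = TRUE)
  d <- length(lc) - cc
  p <- phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
  num <- a * d; den <- b * cc
  odds <- if (num == 0 || den == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else num / den
  structure(list(a = a, b = b, c = cc, d = d, odds_ratio = odds, p = p,
                 target = target, n_border = a + b,
                 n_comparison = cc + d),
            class = "enrichment_table")
}

#' @exportS3Method base::print
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table: %s — a=%d b=%d c=%d d=%d, OR=%.3f, one-sided p=%.4g\n",
              x$target, x$a, x$b, x$c, x$d, x$odds_ratio, x$p))
  invisible(x)
}

#' Test cell-type enrichment at the tumour-brain interface
#'
#' Convenience wrapper: defines the border from the species call, picks
#' the comparison region — the remaining mouse tissue by default, or the
#' tumour (human) region — and runs the one-sided Fisher test for the
#' target type.
#'
#' @param call A `species_call`.
#' @param coords Array coordinates aligned with the call.
#' @param anno_labels Named character vector of per-spot cell-type labels.
#' @param target Target cell type.
#' @param comparison "mouse_rest" (default) or "tumour".
#' @param radius Border neighbourhood radius (default 1).
#' @return An `enrichment_table` (with the `border_region` attached as
#'   attribute `border`).
#' @export
interface_enrichment <- function(call, coords, anno_labels, target,
                                 comparison = c("mouse_rest", "tumour"),
                                 radius = 1) {
  comparison <- match.arg(comparison)
  border <- define_border(call, coords, radius = radius)
  comp_ids <- if (comparison == "mouse_rest") {
    setdiff(call$barcode[call$label == "mouse"], border$border_spots)
  } else {
    setdiff(call$barcode[call$label == "human"], border$border_spots)
  }
  out <- fisher_enrichment(anno_labels, border, comp_ids, target)
  attr(out, "border") <- border
  attr(out, "comparison") <- comparison
  out
}
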