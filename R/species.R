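#' Per-spot species scores
#'
#' For each spot, sums the normalised, unscaled expression over human
#' genes and over mouse genes separately. Summing unscaled values keeps a
#' single over-abundant gene from dominating the score. The default
#' normaliser is `log1p` of median-library-scaled counts; any
#' pre-computed matrix (e.g. variance-stabilised residuals clipped at 0)
#' can be supplied instead.
#'
#' @param ds A [spot_dataset()] with species-tagged genes.
#' @param normalised Optional spots x genes normalised matrix matching
#'   `ds`; defaults to `normalise_counts(ds, "log1p_median")`.
#' @return List with numeric vectors `h_scores` and `m_scores` (named by
#'   barcode).
#' @export
species_scores <- function(ds, normalised = NULL) {
  if (is.null(normalised)) normalised <- normalise_counts(ds, "log1p_median")
  stopifnot(nrow(normalised) == nrow(ds$counts),
            ncol(normalised) == ncol(ds$counts))
  hg <- ds$genes$species == "human"
  mg <- ds$genes$species == "mouse"
  if (!any(hg)) stop("dataset has no human genes")
  if (!any(mg)) stop("dataset has no mouse genes")
  h <- Matrix::rowSums(normalised[, hg, drop = FALSE])
  m <- Matrix::rowSums(normalised[, mg, drop = FALSE])
  names(h) <- names(m) <- ds$barcodes
  list(h_scores = as.numeric(h) |> setNames(ds$barcodes),
       m_scores = as.numeric(m) |> setNames(ds$barcodes))
}

#' Validate species cutoffs
#'
#' Cutoff validity (`m_c1 <= m_c2` and `h_c2 <= h_c1`) guarantees the
#' human and mouse predicates can never both fire on the same spot.
#'
#' @param cutoffs List with numeric `h_c1`, `h_c2`, `m_c1`, `m_c2`.
#' @return The cutoffs, invisibly; errors on invalid input.
#' @export
validate_cutoffs <- function(cutoffs) {
  need <- c("h_c1", "h_c2", "m_c1", "m_c2")
  if (!all(need %in% names(cutoffs))) stop("cutoffs must name h_c1, h_c2, m_c1, m_c2")
  v <- vapply(cutoffs[need], as.numeric, 0)
  if (any(!is.finite(v))) stop("cutoffs must be finite numbers")
  if (v["m_c1"] > v["m_c2"]) stop("invalid cutoffs: m_c1 > m_c2")
  if (v["h_c2"] > v["h_c1"]) stop("invalid cutoffs: h_c2 > h_c1")
  invisible(cutoffs)
}

#' Classify spots as human / mix / mouse
#'
#' A spot is `human` iff its human score strictly exceeds `h_c1` while its
#' mouse score is strictly below `m_c1`; `mouse` iff the mouse score
#' exceeds `m_c2` while the human score is below `h_c2`; everything else
#' (including ties at a cutoff) is `mix`. The three labels always
#' partition the spots.
#'
#' @param h_scores,m_scores Numeric score vectors (same length).
#' @param cutoffs List with `h_c1`, `h_c2`, `m_c1`, `m_c2`; see
#'   [validate_cutoffs()].
#' @param barcodes Optional spot ids (default from score names).
#' @return A `species_call`: data.frame with columns `barcode`, `h_score`,
#'   `m_score`, `label`, `override`, carrying the cutoffs as an attribute.
#' @export
classify_spots <- function(h_scores, m_scores, cutoffs, barcodes = NULL) {
  validate_cutoffs(cutoffs)
  stopifnot(length(h_scores) == length(m_scores))
  if (is.null(barcodes)) barcodes <- names(h_scores)
  if (is.null(barcodes)) barcodes <- as.character(seq_along(h_scores))
  is_h <- (h_scores > cutoffs$h_c1) & (m_scores < cutoffs$m_c1)
  is_m <- (m_scores > cutoffs$m_c2) & (h_scores < cutoffs$h_c2)
  label <- ifelse(is_h, "human", ifelse(is_m, "mouse", "mix"))
  call <- data.frame(barcode = barcodes, h_score = as.numeric(h_scores),
                     m_score = as.numeric(m_scores), label = label,
                     override = FALSE, stringsAsFactors = FALSE)
  attr(call, "cutoffs") <- cutoffs
  attr(call, "provenance") <- list()
  class(call) <- c("species_call", "data.frame")
  call
}

# deepest density valley of a 1-D sample; NULL when unimodal
kde_valley <- function(x) {
  d <- density(x)
  y <- d$y
  dy <- diff(y)
  sign_change <- diff(sign(dy))
  minima <- which(sign_change > 0) + 1L
  maxima <- which(sign_change < 0) + 1L
  if (length(minima) == 0 || length(maxima) < 2) return(NULL)
  best <- NULL; best_depth <- -Inf
  for (i in minima) {
    left <- maxima[maxima < i]; right <- maxima[maxima > i]
    if (length(left) == 0 || length(right) == 0) next
    depth <- min(max(y[left]), max(y[right])) - y[i]
    if (depth > best_depth) { best_depth <- depth; best <- i }
  }
  if (is.null(best) || best_depth <= 0) return(NULL)
  list(valley = d$x[best], bw = d$bw, depth = best_depth)
}

#' Suggest species-score cutoffs from the score distributions
#'
#' Proposes cutoffs at the deepest valley of each score's kernel-density
#' estimate, with the paired cutoffs placed symmetrically around the
#' valley at plus/minus half the KDE bandwidth. Proposals are advisory:
#' they stand in for the per-sample manual choice and configured values
#' always take precedence. A unimodal (valley-free) score yields a
#' degenerate proposal flagged for manual review.
#'
#' @param h_scores,m_scores Numeric score vectors, >= 100 spots.
#' @return List with `cutoffs` (h_c1, h_c2, m_c1, m_c2), per-score valley
#'   details, and `manual_review` flag.
#' @export
suggest_cutoffs <- function(h_scores, m_scores) {
  if (length(h_scores) < 100 || length(m_scores) < 100)
    stop("need at least 100 spots to estimate score densities")
  vh <- kde_valley(h_scores)
  vm <- kde_valley(m_scores)
  degenerate <- is.null(vh) || is.null(vm)
  if (is.null(vh)) vh <- list(valley = median(h_scores), bw = 0)
  if (is.null(vm)) vm <- list(valley = median(m_scores), bw = 0)
  cutoffs <- list(h_c1 = vh$valley + vh$bw / 2,
                  h_c2 = vh$valley - vh$bw / 2,
                  m_c1 = vm$valley - vm$bw / 2,
                  m_c2 = vm$valley + vm$bw / 2)
  if (degenerate)
    warning("unimodal score distribution: degenerate cutoff proposal, manual review required")
  list(cutoffs = cutoffs, h_valley = vh, m_valley = vm,
       manual_review = degenerate)
}

#' Override species labels inside a region
#'
#' Relabels the selected spots (e.g. histology-negative outliers outside
#' the tumour) and records the override provenance. Classification itself
#' stays pure: re-running [classify_spots()] on the scores discards the
#' override unless re-applied.
#'
#' @param call A `species_call`.
#' @param region_mask Logical vector over spots, or barcodes to select.
#' @param new_label One of "human", "mix", "mouse".
#' @return The updated `species_call`.
#' @export
apply_region_override <- function(call, region_mask, new_label = "mouse") {
  stopifnot(inherits(call, "species_call"),
            new_label %in% c("human", "mix", "mouse"))
  if (is.character(region_mask)) {
    idx <- match(region_mask, call$barcode)
    if (anyNA(idx)) stop("region mask names spots absent from the call")
    mask <- rep(FALSE, nrow(call)); mask[idx] <- TRUE
  } else {
    stopifnot(length(region_mask) == nrow(call))
    mask <- as.logical(region_mask)
  }
  if (!any(mask)) {
    warning("empty region mask: no spots relabelled")
    return(call)
  }
  call$label[mask] <- new_label
  call$override[mask] <- TRUE
  prov <- attr(call, "provenance")
  prov[[length(prov) + 1]] <- list(barcodes = call$barcode[mask],
                                   new_label = new_label)
  attr(call, "provenance") <- prov
  call
}
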