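#' Build an annotation catalog from a gene/term table
#'
#' @param annotations Data frame with columns \code{gene_id}, \code{term_id}.
#' @param universe Optional gene ids; annotations are restricted to it and
#'   terms left with no annotated gene are dropped.
#' @return Named list term_id -> character vector of gene ids.
#' @export
annotation_catalog <- function(annotations, universe = NULL) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotations)))
  ann <- unique(annotations[, c("gene_id", "term_id")])
  if (!is.null(universe)) ann <- ann[ann$gene_id %in% universe, ]
  cat <- split(ann$gene_id, ann$term_id)
  cat[lengths(cat) > 0L]
}

#' Hypergeometric (Fisher-type) over-representation analysis
#'
#' One-sided enrichment p-value per term from the 2x2 table of DEG
#' membership against term membership within the measured gene universe,
#' followed by Benjamini-Hochberg step-up control at the chosen FDR. The
#' optional EASE variant subtracts one from the observed overlap before
#' computing the tail, giving a more conservative score.
#'
#' @param degs Character vector of differentially expressed genes (subset of
#'   \code{universe}).
#' @param universe Character vector: all genes surviving expression filters.
#' @param catalog Named list term -> genes (see [annotation_catalog()]) or an
#'   annotation data frame.
#' @param fdr FDR level for the enriched flag (study convention 0.05).
#' @param ease Logical; use the EASE-score variant (default FALSE = Fisher).
#' @return Data frame per term: overlap counts (\code{k},
#'   \code{term_size}, \code{n_degs}, \code{universe_size}), \code{p},
#'   \code{padj}, \code{enriched}. Attribute \code{enriched_terms} holds the
#'   ids passing the FDR cut.
#' @export
fisher_enrichment <- function(degs, universe, catalog, fdr = 0.05,
                              ease = FALSE) {
  if (is.data.frame(catalog)) catalog <- annotation_catalog(catalog, universe)
  if (!all(degs %in% universe))
    stop("degs must be a subset of the universe")
  catalog <- lapply(catalog, intersect, universe)
  catalog <- catalog[lengths(catalog) > 0L]
  N <- length(universe); nd <- length(degs)
  if (length(catalog) == 0L || nd == 0L) {
    out <- data.frame(term_id = character(0), k = integer(0),
                      term_size = integer(0), n_degs = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      padj = numeric(0), enriched = logical(0))
    attr(out, "enriched_terms") <- character(0)
    return(out)
  }
  ts <- lengths(catalog)
  k <- vapply(catalog, function(g) length(intersect(g, degs)), integer(1))
  k_eff <- if (ease) pmax(k - 1L, 0L) else k
  p <- stats::phyper(k_eff - 1L, ts, N - ts, nd, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term_id = names(catalog), k = unname(k),
                    term_size = unname(ts), n_degs = nd, universe_size = N,
                    p = unname(p), padj = unname(padj),
                    enriched = unname(padj < fdr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "enriched_terms") <- out$term_id[out$enriched]
  out
}

# integer rounding, half away from zero (matches printed percentages)
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Overlap between transcriptome- and translatome-enriched term sets
#'
#' Splits the union of the two enriched-term sets into common,
#' transcriptome-specific and translatome-specific parts, with percentages
#' over the union size (integer-rounded, half away from zero).
#'
#' @param transcriptome_terms,translatome_terms Character vectors of term
#'   ids.
#' @return List: counts \code{n_common}, \code{n_transcriptome_only},
#'   \code{n_translatome_only}, \code{n_total}, and matching \code{pct_*}
#'   (NA when both sets are empty).
#' @export
term_overlap_summary <- function(transcriptome_terms, translatome_terms) {
  a <- unique(transcriptome_terms); b <- unique(translatome_terms)
  common <- length(intersect(a, b))
  only_a <- length(setdiff(a, b))
  only_b <- length(setdiff(b, a))
  tot <- common + only_a + only_b
  pct <- function(x) if (tot > 0) .round_half_up(100 * x / tot) else NA_real_
  list(n_common = common, n_transcriptome_only = only_a,
       n_translatome_only = only_b, n_total = tot,
       pct_common = pct(common), pct_transcriptome_only = pct(only_a),
       pct_translatome_only = pct(only_b))
}

#' Translatome network specificity degree of cellular functions
#'
#' For each function annotated to interaction networks at both levels, the
#' degree is the number of associated translatome networks minus the number
#' of associated transcriptome networks, divided by the total; it ranges
#' from -1 (purely transcriptome-associated) to 1 (purely
#' translatome-associated). Functions whose total association count does not
#' exceed \code{min_networks} are excluded.
#'
#' @param associations Data frame with columns \code{fun} (function label),
#'   \code{n_translatome}, \code{n_transcriptome} (nonnegative counts).
#' @param min_networks Exclusion threshold: keep functions with total count
#'   strictly greater than this (default 5).
#' @return Data frame \code{fun}, \code{n_translatome},
#'   \code{n_transcriptome}, \code{total}, \code{degree}, sorted by degree
#'   descending.
#' @export
network_specificity_degree <- function(associations, min_networks = 5L) {
  stopifnot(all(c("fun", "n_translatome", "n_transcriptome") %in%
                  names(associations)))
  if (any(associations$n_translatome < 0 | associations$n_transcriptome < 0))
    stop("network counts must be nonnegative")
  a <- associations
  a$total <- a$n_translatome + a$n_transcriptome
  a <- a[a$total > min_networks, , drop = FALSE]
  a$degree <- (a$n_translatome - a$n_transcriptome) / a$total
  a <- a[order(-a$degree), , drop = FALSE]
  rownames(a) <- NULL
  a
}
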