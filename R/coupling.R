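#' Classify genes into coupling/uncoupling classes
#'
#' A gene is \code{coupled} when significant at both levels with the same
#' direction; \code{antidirectional} when significant at both levels with
#' opposite directions; \code{transcriptome_only} / \code{translatome_only}
#' when significant at exactly one level; \code{unchanged} otherwise.
#' Direction is taken from the caller's per-gene direction column.
#'
#' @param transcriptome,translatome DEG tables over the same gene universe
#'   with columns \code{gene_id}, \code{significant}, \code{direction}.
#' @param fold_changes Optional data frame from [compute_fold_changes()]; its
#'   columns are carried into the output.
#' @return Data frame (a coupling table): \code{gene_id}, \code{class},
#'   per-level significance and direction, and fold changes when supplied.
#' @export
classify_coupling <- function(transcriptome, translatome,
                              fold_changes = NULL) {
  if (!setequal(transcriptome$gene_id, translatome$gene_id)) {
    diff <- c(setdiff(transcriptome$gene_id, translatome$gene_id),
              setdiff(translatome$gene_id, transcriptome$gene_id))
    stop("gene universes differ; symmetric difference: ",
         paste(utils::head(diff, 10L), collapse = ", "),
         if (length(diff) > 10L) " ...")
  }
  translatome <- translatome[match(transcriptome$gene_id,
                                   translatome$gene_id), ]
  sig_tr <- transcriptome$significant
  sig_tl <- translatome$significant
  same_dir <- transcriptome$direction == translatome$direction
  cls <- rep("unchanged", nrow(transcriptome))
  cls[sig_tr & sig_tl & same_dir] <- "coupled"
  cls[sig_tr & sig_tl & !same_dir] <- "antidirectional"
  cls[sig_tr & !sig_tl] <- "transcriptome_only"
  cls[!sig_tr & sig_tl] <- "translatome_only"
  out <- data.frame(gene_id = transcriptome$gene_id,
                    class = factor(cls, levels = COUPLING_CLASSES),
                    significant_transcriptome = sig_tr,
                    significant_translatome = sig_tl,
                    direction_transcriptome = transcriptome$direction,
                    direction_translatome = translatome$direction,
                    stringsAsFactors = FALSE)
  if (!is.null(fold_changes))
    out <- merge(out, fold_changes, by = "gene_id", sort = FALSE)
  out
}

#' Summarize coupling-class counts and the degree of uncoupling
#'
#' Percentages are computed over differentially expressed genes only
#' (\code{unchanged} excluded); the uncoupled percentage pools the
#' antidirectional, transcriptome-only and translatome-only classes. Also
#' reports the translatome-only to transcriptome-only count ratio.
#'
#' @param coupling_table Output of [classify_coupling()].
#' @return List: \code{counts} (named, all five classes), \code{n_degs},
#'   \code{pct} (named percentages over DEGs, NA when there are no DEGs),
#'   \code{uncoupled_pct}, \code{coupled_pct},
#'   \code{translatome_to_transcriptome_ratio}.
#' @export
summarize_uncoupling <- function(coupling_table) {
  stopifnot(nrow(coupling_table) > 0L)
  counts <- table(factor(coupling_table$class, levels = COUPLING_CLASSES))
  counts <- stats::setNames(as.integer(counts), COUPLING_CLASSES)
  deg_classes <- setdiff(COUPLING_CLASSES, "unchanged")
  n_degs <- sum(counts[deg_classes])
  pct <- if (n_degs == 0L) stats::setNames(rep(NA_real_, 4L), deg_classes)
         else 100 * counts[deg_classes] / n_degs
  uncoupled <- sum(counts[c("antidirectional", "transcriptome_only",
                            "translatome_only")])
  ratio <- if (counts[["transcriptome_only"]] > 0L)
    counts[["translatome_only"]] / counts[["transcriptome_only"]]
  else NA_real_
  list(counts = counts, n_degs = n_degs, pct = pct,
       uncoupled_pct = if (n_degs == 0L) NA_real_ else 100 * uncoupled / n_degs,
       coupled_pct = if (n_degs == 0L) NA_real_
                     else 100 * counts[["coupled"]] / n_degs,
       translatome_to_transcriptome_ratio = ratio)
}

#' Coupling-class proportions across a grid of significance thresholds
#'
#' Re-runs the classification at each threshold using the per-gene minimum
#' pfp (or adjusted p) and direction of each level's DEG table.
#'
#' @param transcriptome,translatome DEG tables with \code{gene_id},
#'   \code{pfp} (or \code{padj}) and \code{direction}.
#' @param thresholds Numeric grid within (0, 1].
#' @return Tidy data frame: \code{threshold}, \code{class}, \code{count},
#'   \code{pct_of_degs}.
#' @export
threshold_sweep <- function(transcriptome, translatome,
                            thresholds = c(0.01, 0.05, 0.1, 0.2, 0.3,
                                           0.4, 0.5)) {
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  do.call(rbind, lapply(thresholds, function(th) {
    tab <- classify_coupling(call_degs(transcriptome, th),
                             call_degs(translatome, th))
    s <- summarize_uncoupling(tab)
    data.frame(threshold = th, class = names(s$counts),
               count = unname(s$counts),
               pct_of_degs = unname(ifelse(names(s$counts) == "unchanged",
                                           NA_real_,
                                           s$pct[names(s$counts)])),
               stringsAsFactors = FALSE)
  }))
}

#' Count translationally enhanced and buffered genes
#'
#' A gene is translationally enhanced when its polysomal (translatome) log2
#' fold change strictly exceeds its total-mRNA (transcriptome) fold change,
#' and buffered when it falls strictly short; exactly equal fold changes are
#' counted as tied and belong to neither class.
#'
#' @param fold_changes Data frame from [compute_fold_changes()].
#' @param genes Optional gene ids restricting the scope (e.g. the union of
#'   DEGs); default is every gene in the table.
#' @return List: \code{n_enhanced}, \code{n_buffered}, \code{n_tied},
#'   \code{enhanced_pct}, \code{buffered_pct} (percentages over
#'   enhanced + buffered).
#' @export
buffering_counts <- function(fold_changes, genes = NULL) {
  fc <- fold_changes
  if (!is.null(genes)) {
    missing <- setdiff(genes, fc$gene_id)
    if (length(missing))
      stop("fold changes missing for: ",
           paste(utils::head(missing, 10L), collapse = ", "))
    fc <- fc[fc$gene_id %in% genes, ]
  }
  enhanced <- sum(fc$fc_translatome > fc$fc_transcriptome)
  buffered <- sum(fc$fc_translatome < fc$fc_transcriptome)
  tied <- nrow(fc) - enhanced - buffered
  tot <- enhanced + buffered
  list(n_enhanced = enhanced, n_buffered = buffered, n_tied = tied,
       enhanced_pct = if (tot > 0) 100 * enhanced / tot else NA_real_,
       buffered_pct = if (tot > 0) 100 * buffered / tot else NA_real_)
}
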