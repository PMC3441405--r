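#' Filter features with repeated "absent" detection calls
#'
#' Removes a feature when it is called absent in more than
#' \code{majority_fraction} of the arrays within every one of the four
#' level/condition groups (the AND over groups: a feature present in a
#' majority of arrays of any group is kept). Without detection calls the set
#' is returned unchanged with a warning.
#'
#' @param set A \code{PairedExpressionSet}.
#' @param majority_fraction Fraction in [0.5, 1]; a feature is
#'   majority-absent in a group when its absent fraction strictly exceeds
#'   this value. Default 0.5 (strict majority).
#' @return Filtered \code{PairedExpressionSet} with attribute
#'   \code{n_removed}.
#' @export
filter_low_signal <- function(set, majority_fraction = 0.5) {
  stopifnot(inherits(set, "PairedExpressionSet"))
  if (majority_fraction < 0.5 || majority_fraction > 1)
    stop("majority_fraction must lie in [0.5, 1]")
  if (is.null(set$detection)) {
    warning("no detection calls: low-signal filter is a pass-through")
    attr(set, "n_removed") <- 0L
    return(set)
  }
  absent_majority <- vapply(set$detection, function(d) {
    rowMeans(!d) > majority_fraction
  }, logical(n_features(set)))
  drop <- rowSums(absent_majority) == length(set$detection)
  out <- paired_expression_set(
    lapply(set$matrices, function(m) m[!drop, , drop = FALSE]),
    detection = lapply(set$detection, function(d) d[!drop, , drop = FALSE]))
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Quantile normalization of a log2 intensity matrix
#'
#' Forces every column to the identical sorted value vector (the rank-wise
#' mean across columns); tied input values receive the mean of the tied
#' ranks' target values. Delegates to \code{limma::normalizeQuantiles}.
#'
#' @param mat Numeric matrix, features x samples, >= 2 columns, no missing
#'   values.
#' @return Normalized matrix with the input's dimnames.
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2L) stop("need >= 2 columns")
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)
    lab <- apply(utils::head(idx, 10L), 1L, function(r)
      paste0("[", rownames(mat)[r[1L]] %||% r[1L], ", ",
             colnames(mat)[r[2L]] %||% r[2L], "]"))
    stop("missing values at: ", paste(lab, collapse = ", "),
         if (nrow(idx) > 10L) " ...")
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile-normalize a paired expression set jointly
#'
#' Applies [quantile_normalize()] across all arrays of all four
#' level/condition groups at once, so the groups share one intensity
#' distribution and fold changes are comparable across levels.
#'
#' @param set A \code{PairedExpressionSet}.
#' @return Normalized \code{PairedExpressionSet}.
#' @export
normalize_paired_set <- function(set) {
  stopifnot(inherits(set, "PairedExpressionSet"))
  sizes <- vapply(set$matrices, ncol, integer(1))
  joint <- do.call(cbind, set$matrices)
  norm <- quantile_normalize(joint)
  splits <- rep(names(sizes), sizes)
  mats <- lapply(names(sizes), function(g) {
    m <- norm[, splits == g, drop = FALSE]
    colnames(m) <- colnames(set$matrices[[g]])
    m
  })
  names(mats) <- names(sizes)
  paired_expression_set(mats, detection = set$detection)
}

#' Collapse probe-level rows to gene-level rows by averaging
#'
#' @param mat Numeric matrix with probe rownames.
#' @param probe_gene_map Data frame with columns \code{probe_id},
#'   \code{gene_id}; each probe may map to at most one gene. Probes absent
#'   from the map are dropped and counted (attribute \code{n_unmapped}).
#' @return Matrix keyed by gene: each gene row is the arithmetic mean of its
#'   probes' rows.
#' @export
collapse_probes_to_genes <- function(mat, probe_gene_map) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_gene_map)))
  map <- unique(probe_gene_map[, c("probe_id", "gene_id")])
  dup <- unique(map$probe_id[duplicated(map$probe_id)])
  if (length(dup))
    stop("probes mapped to more than one gene: ",
         paste(utils::head(dup, 10L), collapse = ", "))
  idx <- match(rownames(mat), map$probe_id)
  unmapped <- is.na(idx)
  m <- mat[!unmapped, , drop = FALSE]
  genes <- map$gene_id[idx[!unmapped]]
  sums <- rowsum(m, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

#' Per-gene log2 fold changes at both levels
#'
#' Mean(treated) minus mean(control) per gene, separately for the
#' transcriptome and translatome matrices (log2 units).
#'
#' @param set A normalized, collapsed \code{PairedExpressionSet}.
#' @return Data frame: \code{gene_id}, \code{fc_transcriptome},
#'   \code{fc_translatome}.
#' @export
compute_fold_changes <- function(set) {
  stopifnot(inherits(set, "PairedExpressionSet"))
  fc <- function(level) {
    rowMeans(set$matrices[[paste0(level, "_treated")]]) -
      rowMeans(set$matrices[[paste0(level, "_control")]])
  }
  data.frame(gene_id = set$feature_ids,
             fc_transcriptome = unname(fc("transcriptome")),
             fc_translatome = unname(fc("translatome")),
             stringsAsFactors = FALSE)
}
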