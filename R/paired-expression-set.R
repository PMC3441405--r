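#' Coupling class labels
#'
#' The five per-gene classes used throughout the package: \code{coupled}
#' (significant and homodirectional at both levels), \code{antidirectional}
#' (significant at both levels with opposite signs), \code{transcriptome_only},
#' \code{translatome_only}, and \code{unchanged} (significant at neither
#' level).
#'
#' @export
COUPLING_CLASSES <- c("coupled", "antidirectional", "transcriptome_only",
                      "translatome_only", "unchanged")

.LEVELS <- c("transcriptome", "translatome")
.CONDITIONS <- c("control", "treated")
.GROUPS <- c("transcriptome_control", "transcriptome_treated",
             "translatome_control", "translatome_treated")

#' Construct a paired expression set
#'
#' Container for log2 intensity matrices of the two RNA fractions
#' (total mRNA = transcriptome, polysome-associated mRNA = translatome)
#' profiled in two conditions over a shared gene (or probe) universe.
#'
#' @param matrices Named list with elements \code{transcriptome_control},
#'   \code{transcriptome_treated}, \code{translatome_control},
#'   \code{translatome_treated}; each a numeric matrix (features x replicates)
#'   with identical rownames across the four matrices.
#' @param detection Optional named list with the same shape holding logical
#'   matrices (\code{TRUE} = "present" detection call).
#' @return An object of class \code{PairedExpressionSet}.
#' @export
paired_expression_set <- function(matrices, detection = NULL) {
  if (!all(.GROUPS %in% names(matrices)))
    stop("matrices must contain: ", paste(.GROUPS, collapse = ", "))
  matrices <- matrices[.GROUPS]
  ids <- rownames(matrices[[1L]])
  if (is.null(ids)) stop("matrices must carry feature rownames")
  for (g in .GROUPS) {
    m <- matrices[[g]]
    if (!is.matrix(m) || !identical(rownames(m), ids))
      stop("matrix '", g, "' does not share the feature universe")
    if (ncol(m) < 2L)
      stop("matrix '", g, "' has fewer than 2 replicates")
  }
  if (!is.null(detection)) {
    if (!all(.GROUPS %in% names(detection)))
      stop("detection must mirror the four expression matrices")
    detection <- detection[.GROUPS]
    for (g in .GROUPS) {
      d <- detection[[g]]
      if (!is.matrix(d) || !identical(dim(d), dim(matrices[[g]])) ||
          !is.logical(d))
        stop("detection matrix '", g, "' must be logical and match '", g, "'")
      rownames(d) <- ids
      detection[[g]] <- d
    }
  }
  structure(list(matrices = matrices, detection = detection,
                 feature_ids = ids),
            class = "PairedExpressionSet")
}

#' @export
print.PairedExpressionSet <- function(x, ...) {
  reps <- vapply(x$matrices, ncol, integer(1))
  cat("PairedExpressionSet:", length(x$feature_ids), "features\n")
  cat("  replicates:", paste(sprintf("%s=%d", names(reps), reps),
                             collapse = ", "), "\n")
  cat("  detection calls:", if (is.null(x$detection)) "absent" else "present",
      "\n")
  invisible(x)
}

#' Number of features in a paired expression set
#' @param x A \code{PairedExpressionSet}.
#' @export
n_features <- function(x) length(x$feature_ids)

#' Sample sheet describing the arrays of a paired expression set
#'
#' @param set A \code{PairedExpressionSet}.
#' @return Data frame with columns \code{sample_id}, \code{level},
#'   \code{condition}, \code{replicate}.
#' @export
sample_sheet <- function(set) {
  do.call(rbind, lapply(.GROUPS, function(g) {
    n <- ncol(set$matrices[[g]])
    parts <- strsplit(g, "_", fixed = TRUE)[[1L]]
    data.frame(sample_id = sprintf("%s_r%d", g, seq_len(n)),
               level = parts[1L], condition = parts[2L],
               replicate = seq_len(n), stringsAsFactors = FALSE)
  }))
}

#' Write a paired expression set to TSV files
#'
#' Writes one tab-separated matrix per level/condition group plus a sample
#' sheet (\code{samples.tsv}) into \code{dir}.
#'
#' @param set A \code{PairedExpressionSet}.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_paired_expression_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in .GROUPS) {
    p <- file.path(dir, paste0(g, ".tsv"))
    df <- data.frame(feature_id = set$feature_ids, set$matrices[[g]],
                     check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  sp <- file.path(dir, "samples.tsv")
  utils::write.table(sample_sheet(set), sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, sp))
}

#' Read a paired expression set written by [write_paired_expression_set()]
#'
#' @param dir Directory holding the four group TSVs.
#' @return A \code{PairedExpressionSet}.
#' @export
read_paired_expression_set <- function(dir) {
  mats <- lapply(.GROUPS, function(g) {
    df <- utils::read.delim(file.path(dir, paste0(g, ".tsv")),
                            check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  })
  names(mats) <- .GROUPS
  paired_expression_set(mats)
}
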