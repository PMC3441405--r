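#' Rank-product statistic for a two-group comparison
#'
#' Two-class rank product over K disjoint replicate pairings: control
#' replicate k is compared with treated replicate k
#' (K = min(n_control, n_treated)); in each comparison genes are ranked by
#' log2 fold change in the stated direction (rank 1 = strongest change, ties
#' get average ranks) and the statistic is the geometric mean of a gene's K
#' ranks. Disjoint pairings keep the per-comparison noise independent, so
#' the gene-label permutation null of [estimate_pfp()] matches the observed
#' rankings' null distribution exactly. Being rank-based, the statistic is
#' invariant under any monotone transform of the expression values.
#'
#' @param control,treated Numeric matrices (genes x replicates, >= 2 each)
#'   with identical rownames.
#' @param direction \code{"up"} (treated > control) or \code{"down"}.
#' @return List of class \code{rank_product}: \code{rp} (named per-gene
#'   statistic), \code{ranks} (genes x K rank matrix), \code{direction},
#'   \code{constant_genes} (genes flagged for zero fold-change variance
#'   across all comparisons).
#' @export
rank_product_statistic <- function(control, treated,
                                   direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!identical(rownames(control), rownames(treated)))
    stop("control and treated must share the gene universe")
  if (ncol(control) < 2L || ncol(treated) < 2L)
    stop("need >= 2 replicates per group")
  n <- nrow(control)
  K <- min(ncol(control), ncol(treated))
  ranks <- vapply(seq_len(K), function(k) {
    fc <- treated[, k] - control[, k]
    if (direction == "up") rank(-fc, ties.method = "average")
    else rank(fc, ties.method = "average")
  }, numeric(n))
  rownames(ranks) <- rownames(control)
  rp <- exp(rowMeans(log(ranks)))
  fc_all <- vapply(seq_len(K), function(k)
    treated[, k] - control[, k], numeric(n))
  const <- rownames(control)[apply(fc_all, 1L, function(v)
    max(v) - min(v) == 0 && v[1L] == 0)]
  structure(list(rp = rp, ranks = ranks, direction = direction,
                 constant_genes = const),
            class = "rank_product")
}

#' Permutation estimate of the percentage of false prediction (pfp)
#'
#' The null shuffles gene labels independently within each of the K
#' replicate-pair rankings and recomputes the rank product. For a gene at
#' position r in the observed rank-product order, pfp is the expected number
#' of permuted rank products at least as extreme as the gene's, divided by r
#' (expected false predictions per prediction). Monotonicity in r is
#' enforced by a cumulative maximum down the ranking (step-down smoothing).
#'
#' @param rp_obj A \code{rank_product} object.
#' @param n_permutations Number of permutation rounds (>= 100 recommended; a
#'   warning is raised below that).
#' @param seed Integer RNG seed.
#' @return Named per-gene pfp vector (same order as \code{rp_obj$rp}).
#' @export
estimate_pfp <- function(rp_obj, n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(rp_obj, "rank_product"))
  if (n_permutations < 100L)
    warning("n_permutations < 100: pfp estimates will be unstable")
  set.seed(seed)
  ranks <- rp_obj$ranks
  n <- nrow(ranks)
  log_obs <- rowMeans(log(ranks))
  counts <- numeric(n)
  for (b in seq_len(n_permutations)) {
    perm <- vapply(seq_len(ncol(ranks)),
                   function(k) ranks[sample.int(n), k], numeric(n))
    log_star <- sort(rowMeans(log(perm)))
    counts <- counts + findInterval(log_obs + 1e-12, log_star)
  }
  expected <- counts / n_permutations
  r <- rank(rp_obj$rp, ties.method = "first")
  pfp <- expected / r
  ord <- order(rp_obj$rp)
  pfp[ord] <- cummax(pfp[ord])
  stats::setNames(pfp, names(rp_obj$rp))
}

#' Full rank-product differential-expression table for one level
#'
#' Runs [rank_product_statistic()] and [estimate_pfp()] in both directions
#' and combines them per gene by the minimum pfp.
#'
#' @param control,treated Replicate matrices (genes x replicates).
#' @param n_permutations,seed Passed to [estimate_pfp()] (same seed for both
#'   directions).
#' @return Data frame (a DEG table): \code{gene_id}, \code{log2fc},
#'   \code{rp_up}, \code{pfp_up}, \code{rp_down}, \code{pfp_down},
#'   \code{direction} (argmin pfp), \code{pfp} (min over directions).
#' @export
rank_product_table <- function(control, treated, n_permutations = 1000L,
                               seed = 1L) {
  up <- rank_product_statistic(control, treated, "up")
  down <- rank_product_statistic(control, treated, "down")
  pfp_up <- estimate_pfp(up, n_permutations, seed)
  pfp_down <- estimate_pfp(down, n_permutations, seed)
  data.frame(gene_id = rownames(control),
             log2fc = unname(rowMeans(treated) - rowMeans(control)),
             rp_up = unname(up$rp), pfp_up = unname(pfp_up),
             rp_down = unname(down$rp), pfp_down = unname(pfp_down),
             direction = ifelse(pfp_up <= pfp_down, "up", "down"),
             pfp = unname(pmin(pfp_up, pfp_down)),
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes from a DEG table
#'
#' A gene is significant when its minimum-direction pfp (or adjusted p, for
#' the t-test caller) falls strictly below the threshold.
#'
#' @param deg_table Data frame with columns \code{gene_id}, \code{pfp} (or
#'   \code{padj}) and \code{direction}.
#' @param threshold Significance cutoff (the study convention is
#'   \code{pfp < 0.2}).
#' @return The table with a logical \code{significant} column added;
#'   attribute \code{degs} holds the significant gene ids.
#' @export
call_degs <- function(deg_table, threshold = 0.2) {
  stat <- deg_table$pfp %||% deg_table$padj
  if (is.null(stat)) stop("deg_table needs a 'pfp' or 'padj' column")
  deg_table$significant <- stat < threshold
  attr(deg_table, "degs") <- deg_table$gene_id[deg_table$significant]
  deg_table
}

#' Two-sample t-test caller with Benjamini-Hochberg correction
#'
#' Per-gene two-sided pooled-variance Student t-test of treated vs control
#' (exact type-I control under equal group variances, the natural choice at
#' the 2-4 replicates typical of these designs), BH step-up on the p-value
#' vector, significance at adjusted p below \code{alpha}. Genes with zero
#' variance in both groups get p = 1 when the group means are equal;
#' otherwise the standard error is floored at a small positive value
#' (reported via attribute \code{n_variance_floored}).
#'
#' @param control,treated Replicate matrices (genes x replicates, >= 2 each).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Data frame: \code{gene_id}, \code{log2fc}, \code{t}, \code{p},
#'   \code{padj}, \code{direction}, \code{significant}.
#' @export
ttest_bh_caller <- function(control, treated, alpha = 0.05) {
  if (!identical(rownames(control), rownames(treated)))
    stop("control and treated must share the gene universe")
  if (ncol(control) < 2L || ncol(treated) < 2L)
    stop("need >= 2 replicates per group")
  n1 <- ncol(control); n2 <- ncol(treated)
  m1 <- rowMeans(control); m2 <- rowMeans(treated)
  v1 <- apply(control, 1L, stats::var); v2 <- apply(treated, 1L, stats::var)
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se2 <- pooled * (1 / n1 + 1 / n2)
  zero <- se2 == 0
  eq_means <- zero & (m1 == m2)
  floor_se2 <- if (any(se2 > 0)) min(se2[se2 > 0]) * 1e-8 else 1e-16
  se2[zero] <- floor_se2
  tstat <- (m2 - m1) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
  p[eq_means] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = rownames(control),
                    log2fc = unname(m2 - m1), t = unname(tstat),
                    p = unname(p), padj = unname(padj),
                    direction = ifelse(m2 >= m1, "up", "down"),
                    significant = unname(padj < alpha),
                    stringsAsFactors = FALSE)
  attr(out, "n_variance_floored") <- sum(zero & !eq_means)
  out
}
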