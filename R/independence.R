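#' Likelihood ratio test for equal DEG proportions at the two levels
#'
#' Models the transcriptome and translatome DEG counts as two binomial draws
#' over the same N-gene universe. Under the null both share one proportion
#' p0 = (n1 + n2) / (2N); under the alternative each level keeps its own
#' proportion. The statistic G = 2 (l1 - l0) is referred to a chi-square
#' distribution with 1 degree of freedom.
#'
#' @param n1,n2 Transcriptome and translatome DEG counts.
#' @param N Gene-universe size (> 0).
#' @return List: \code{statistic} (G), \code{p}, \code{p0}, \code{p1},
#'   \code{p2}.
#' @export
likelihood_ratio_test <- function(n1, n2, N) {
  if (N <= 0) stop("N must be positive")
  if (n1 < 0 || n2 < 0 || n1 > N || n2 > N)
    stop("counts must satisfy 0 <= n <= N")
  loglik <- function(k, p) {
    if (p <= 0) { if (k == 0) 0 else -Inf }
    else if (p >= 1) { if (k == N) 0 else -Inf }
    else k * log(p) + (N - k) * log(1 - p)
  }
  p0 <- (n1 + n2) / (2 * N)
  p1 <- n1 / N; p2 <- n2 / N
  l0 <- loglik(n1, p0) + loglik(n2, p0)
  l1 <- loglik(n1, p1) + loglik(n2, p2)
  g <- max(0, 2 * (l1 - l0))
  list(statistic = g, p = stats::pchisq(g, df = 1, lower.tail = FALSE),
       p0 = p0, p1 = p1, p2 = p2)
}

#' Exact hypergeometric tail probability of a list overlap
#'
#' Probability that two independent uniform draws of n1 and n2 genes from an
#' N-gene population share at least k genes; the closed-form oracle for
#' [random_overlap_test()].
#'
#' @param n1,n2 List sizes; \code{N} population size; \code{k} observed
#'   overlap (0 <= k <= min(n1, n2)).
#' @return P(X >= k) for X ~ Hypergeometric(N, n1, n2).
#' @export
hypergeometric_overlap_pvalue <- function(n1, n2, N, k) {
  if (any(c(n1, n2, k) < 0) || n1 > N || n2 > N || k > min(n1, n2))
    stop("invalid counts: need 0 <= k <= min(n1, n2) <= N")
  stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
}

#' Random-overlap bootstrap test
#'
#' Repeatedly draws n1 and n2 genes without replacement from the N-gene
#' population, records the intersection size, and reports the add-one
#' corrected upper-tail p-value of the observed overlap:
#' p = (#\{random >= k\} + 1) / (n_iter + 1).
#'
#' @param n1,n2,N List and population sizes.
#' @param k_observed Observed overlap.
#' @param n_iter Number of random extractions (>= 1e4 recommended).
#' @param seed Integer RNG seed.
#' @return List: \code{p}, \code{k_observed}, \code{null_mean},
#'   \code{null_sd}, \code{null_quantiles} (0/25/50/75/100%).
#' @export
random_overlap_test <- function(n1, n2, N, k_observed, n_iter = 1e5L,
                                seed = 1L) {
  if (k_observed > min(n1, n2))
    stop("k_observed cannot exceed min(n1, n2)")
  set.seed(seed)
  overlaps <- integer(n_iter)
  member <- logical(N)
  for (b in seq_len(n_iter)) {
    member[] <- FALSE
    member[sample.int(N, n1)] <- TRUE
    overlaps[b] <- sum(member[sample.int(N, n2)])
  }
  list(p = (sum(overlaps >= k_observed) + 1) / (n_iter + 1),
       k_observed = k_observed,
       null_mean = mean(overlaps), null_sd = stats::sd(overlaps),
       null_quantiles = stats::quantile(overlaps))
}

#' Plug-in mutual information of two binary vectors (bits)
#'
#' Mutual information of the empirical 2x2 joint distribution, log base 2,
#' with the 0 log 0 = 0 convention. Zero exactly when the table is in
#' product form.
#'
#' @param x,y Binary (0/1 or logical) vectors of equal length.
#' @return MI in bits (>= 0).
#' @export
mutual_information_binary <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) == 0L) stop("vectors must be non-empty")
  x <- as.integer(as.logical(x)); y <- as.integer(as.logical(y))
  tab <- table(factor(x, 0:1), factor(y, 0:1)) / length(x)
  .mi_table(as.matrix(tab))
}

.mi_table <- function(pt) {
  px <- rowSums(pt); py <- colSums(pt)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    if (pt[i, j] > 0)
      mi <- mi + pt[i, j] * log2(pt[i, j] / (px[i] * py[j]))
  }
  max(0, mi)
}

.mi_from_counts <- function(both, only_x, only_y, N) {
  pt <- matrix(c(N - both - only_x - only_y, only_y,
                 only_x, both), nrow = 2, byrow = TRUE) / N
  .mi_table(pt)
}

#' Feasibility bounds on the mutual information of two DEG indicator vectors
#'
#' With n1 transcriptome and n2 translatome DEGs over N genes, the reference
#' minimum is the MI of lists as disjoint as possible (overlap
#' max(0, n1 + n2 - N)) and the maximum the MI of completely overlapping
#' lists of size floor((n1 + n2) / 2), which equals the marginal entropy
#' H(s / N). Note the zero-overlap reference is not a strict lower bound:
#' MI is U-shaped in the overlap and reaches (near) zero at the
#' independence point n1 n2 / N, so tables close to independence can fall
#' slightly below \code{mi_min}; under positive association (overlap at or
#' above its independence expectation, the regime of coupled DEG lists) the
#' observed MI lies within the interval.
#'
#' @param n1,n2,N DEG counts and universe size.
#' @return List: \code{mi_min}, \code{mi_max} (bits), \code{forced_overlap}
#'   (nonzero when n1 + n2 > N).
#' @export
mi_bounds <- function(n1, n2, N) {
  if (n1 < 0 || n2 < 0 || n1 > N || n2 > N) stop("invalid counts")
  forced <- max(0L, n1 + n2 - N)
  mi_min <- .mi_from_counts(forced, n1 - forced, n2 - forced, N)
  s <- floor((n1 + n2) / 2)
  mi_max <- .mi_from_counts(s, 0L, 0L, N)
  list(mi_min = mi_min, mi_max = mi_max, forced_overlap = forced)
}

#' Mutual information bootstrap test with feasibility bounds
#'
#' Computes the observed MI between the two binary DEG indicator vectors,
#' then repeatedly reassigns the n1 and n2 DEG labels to random genes
#' (preserving the marginal counts) and reports the add-one corrected
#' probability of a random MI at least as large. The midrange position
#' locates the observed MI inside the feasibility interval of [mi_bounds()].
#'
#' @param x,y Binary DEG indicator vectors of equal length.
#' @param n_iter Number of random label reassignments.
#' @param seed Integer RNG seed.
#' @return List: \code{mi_observed}, \code{p}, \code{mi_min}, \code{mi_max},
#'   \code{midrange_position} (NA when the bounds coincide), \code{n1},
#'   \code{n2}, \code{N}.
#' @export
mi_test <- function(x, y, n_iter = 1e4L, seed = 1L) {
  if (length(x) != length(y)) stop("length mismatch")
  x <- as.logical(x); y <- as.logical(y)
  N <- length(x); n1 <- sum(x); n2 <- sum(y)
  mi_obs <- mutual_information_binary(x, y)
  set.seed(seed)
  count <- 0L
  member <- logical(N)
  for (b in seq_len(n_iter)) {
    member[] <- FALSE
    member[sample.int(N, n1)] <- TRUE
    k <- sum(member[sample.int(N, n2)])
    if (.mi_from_counts(k, n1 - k, n2 - k, N) >= mi_obs)
      count <- count + 1L
  }
  b <- mi_bounds(n1, n2, N)
  rng <- b$mi_max - b$mi_min
  list(mi_observed = mi_obs, p = (count + 1) / (n_iter + 1),
       mi_min = b$mi_min, mi_max = b$mi_max,
       midrange_position = if (rng > 0) (mi_obs - b$mi_min) / rng
                           else NA_real_,
       n1 = n1, n2 = n2, N = N)
}

#' All three transcriptome-translatome independence tests at once
#'
#' Runs the likelihood ratio test on the DEG counts, the random-overlap
#' bootstrap (with its exact hypergeometric oracle), and the mutual
#' information test with feasibility bounds, from the two DEG indicator
#' vectors over a shared gene universe.
#'
#' @param transcriptome_degs,translatome_degs Character vectors of DEG ids.
#' @param universe Character vector of all measured genes.
#' @param n_iter Bootstrap iterations for the overlap and MI tests.
#' @param seed Integer RNG seed.
#' @return List of class \code{IndependenceResult} with fields \code{N},
#'   \code{n1}, \code{n2}, \code{k}, \code{lrt_stat}, \code{lrt_p},
#'   \code{overlap_p}, \code{overlap_p_exact}, \code{mi_observed},
#'   \code{mi_min}, \code{mi_max}, \code{mi_midrange_position}, \code{mi_p}.
#' @export
independence_tests <- function(transcriptome_degs, translatome_degs,
                               universe, n_iter = 1e5L, seed = 1L) {
  if (!all(transcriptome_degs %in% universe) ||
      !all(translatome_degs %in% universe))
    stop("DEG lists must be subsets of the universe")
  N <- length(universe)
  x <- universe %in% transcriptome_degs
  y <- universe %in% translatome_degs
  n1 <- sum(x); n2 <- sum(y)
  k <- length(intersect(transcriptome_degs, translatome_degs))
  lrt <- likelihood_ratio_test(n1, n2, N)
  ov <- random_overlap_test(n1, n2, N, k, n_iter = n_iter, seed = seed)
  mi <- mi_test(x, y, n_iter = n_iter, seed = seed + 1L)
  structure(list(N = N, n1 = n1, n2 = n2, k = k,
                 lrt_stat = lrt$statistic, lrt_p = lrt$p,
                 overlap_p = ov$p,
                 overlap_p_exact = hypergeometric_overlap_pvalue(n1, n2, N, k),
                 mi_observed = mi$mi_observed, mi_min = mi$mi_min,
                 mi_max = mi$mi_max,
                 mi_midrange_position = mi$midrange_position,
                 mi_p = mi$p),
            class = "IndependenceResult")
}

#' @export
print.IndependenceResult <- function(x, ...) {
  cat(sprintf("IndependenceResult: N=%d, n1=%d, n2=%d, overlap k=%d\n",
              x$N, x$n1, x$n2, x$k))
  cat(sprintf("  LRT: G=%.3f, p=%.3g\n", x$lrt_stat, x$lrt_p))
  cat(sprintf("  overlap: bootstrap p=%.3g (exact %.3g)\n",
              x$overlap_p, x$overlap_p_exact))
  cat(sprintf("  MI: %.4f bits in [%.4f, %.4f], midrange %.3f, p=%.3g\n",
              x$mi_observed, x$mi_min, x$mi_max,
              x$mi_midrange_position, x$mi_p))
  invisible(x)
}
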