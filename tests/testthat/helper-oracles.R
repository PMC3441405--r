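# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive enumeration / direct
# formulas, never the code paths they check.

# Max-over-paths product of edge weights from `term` up to every ancestor,
# by exhaustive path enumeration over the child->parent edge list.
oracle_svalues <- function(term, graph) {
  edges <- graph$edges
  w <- graph$weights
  best <- new.env()
  assign(term, 1, envir = best)
  walk <- function(node, value) {
    idx <- which(edges$child == node)
    for (i in idx) {
      p <- edges$parent[i]
      v <- value * w[[edges$relation[i]]]
      cur <- if (exists(p, envir = best)) get(p, envir = best) else -Inf
      if (v > cur) assign(p, v, envir = best)
      walk(p, v)
    }
  }
  walk(term, 1)
  vals <- mget(ls(best), envir = best)
  unlist(vals)
}

oracle_similarity <- function(a, b, graph) {
  sa <- oracle_svalues(a, graph)
  sb <- oracle_svalues(b, graph)
  common <- intersect(names(sa), names(sb))
  (sum(sa[common]) + sum(sb[common])) / (sum(sa) + sum(sb))
}

# Exact P(overlap >= k) for two uniform draws of sizes n1, n2 from N genes,
# by enumerating every possible second draw against a fixed first draw.
oracle_overlap_tail <- function(n1, n2, N, k) {
  first <- seq_len(n1)
  draws <- utils::combn(N, n2)
  hits <- apply(draws, 2L, function(d) sum(d %in% first) >= k)
  mean(hits)
}

# Exhaustive pfp on a small instance: every pair of column permutations of
# the observed rank matrix (K = 2) is a permutation "round".
oracle_pfp_exhaustive <- function(ranks, rp) {
  stopifnot(ncol(ranks) == 2L)
  n <- nrow(ranks)
  perms <- all_permutations(n)
  counts <- numeric(n)
  n_rounds <- 0L
  for (p1 in seq_len(nrow(perms))) {
    c1 <- ranks[perms[p1, ], 1L]
    for (p2 in seq_len(nrow(perms))) {
      rp_star <- sqrt(c1 * ranks[perms[p2, ], 2L])
      counts <- counts + vapply(rp, function(x)
        sum(rp_star <= x + 1e-12), numeric(1))
      n_rounds <- n_rounds + 1L
    }
  }
  expected <- counts / n_rounds
  r <- rank(rp, ties.method = "first")
  pfp <- expected / r
  ord <- order(rp)
  pfp[ord] <- cummax(pfp[ord])
  pfp
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# Direct plug-in mutual information (bits) from a 2x2 count table.
oracle_mi <- function(n11, n10, n01, n00) {
  N <- n11 + n10 + n01 + n00
  p <- c(n11, n10, n01, n00) / N
  px <- c(n11 + n10, n01 + n00) / N   # x = 1, 0
  py <- c(n11 + n01, n10 + n00) / N   # y = 1, 0
  marg <- c(px[1] * py[1], px[1] * py[2], px[2] * py[1], px[2] * py[2])
  sum(ifelse(p > 0, p * log2(p / marg), 0))
}

# Binomial log-likelihood ratio statistic via dbinom (independent route).
oracle_lrt_g <- function(n1, n2, N) {
  p0 <- (n1 + n2) / (2 * N)
  2 * (stats::dbinom(n1, N, n1 / N, log = TRUE) +
         stats::dbinom(n2, N, n2 / N, log = TRUE) -
         stats::dbinom(n1, N, p0, log = TRUE) -
         stats::dbinom(n2, N, p0, log = TRUE))
}

# Exact one-sided enrichment p by enumerating all possible DEG draws of the
# observed size from the universe (feasible for universes <= 12 genes).
oracle_enrichment_p <- function(term_genes, degs, universe) {
  nd <- length(degs)
  k_obs <- length(intersect(term_genes, degs))
  draws <- utils::combn(universe, nd)
  mean(apply(draws, 2L, function(d) length(intersect(term_genes, d)) >= k_obs))
}

# small deterministic expression fixture: genes x reps with planted shifts
make_groups <- function(n_genes, n_reps, effects = 0, sd = 0.3, seed = 1L) {
  set.seed(seed)
  base <- stats::runif(n_genes, 6, 14)
  ctrl <- matrix(base, n_genes, n_reps) +
    matrix(stats::rnorm(n_genes * n_reps, sd = sd), n_genes)
  trt <- matrix(base + effects, n_genes, n_reps) +
    matrix(stats::rnorm(n_genes * n_reps, sd = sd), n_genes)
  rownames(ctrl) <- rownames(trt) <- sprintf("g%03d", seq_len(n_genes))
  list(control = ctrl, treated = trt)
}

# three-term sibling graph: root with two children, configurable weight
sibling_graph <- function(w = 0.8) {
  ontology_graph(
    data.frame(id = c("R", "A", "B"), name = c("root", "a", "b"),
               namespace = "ns", stringsAsFactors = FALSE),
    data.frame(child = c("A", "B"), parent = c("R", "R"),
               relation = "is_a", stringsAsFactors = FALSE),
    weights = c(is_a = w, part_of = 0.6))
}
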