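#' Configuration for the synthetic paired-expression generator
#'
#' Defines the study conditions emulated by [generate_paired_dataset()]: a
#' replicated two-group comparison (treated vs control) measured at two RNA
#' levels (total mRNA and polysomal mRNA) on a log2 intensity scale, with a
#' chosen fraction of genes planted in each coupling class.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per condition per level (>= 2).
#' @param class_fractions Named fractions over the five coupling classes
#'   (see [COUPLING_CLASSES]); must be nonnegative and sum to 1. The default
#'   mix mirrors the class proportions observed after EGF stimulation of
#'   HeLa cells (about 4.6% DEGs, heavily translatome-dominated: roughly
#'   nine purely translatome DEGs for every purely transcriptome one).
#' @param effect_size Absolute planted log2 fold change for differentially
#'   expressed genes.
#' @param noise_sd Replicate-level Gaussian standard deviation in log2 units
#'   (>= 0; 0 gives the noiseless limit).
#' @param baseline_range Numeric length-2: low/high of the uniform log2
#'   baseline intensity range (default 6-14, a typical microarray dynamic
#'   range).
#' @param seed Integer RNG seed.
#' @return A validated list of class \code{SyntheticConfig}.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             n_replicates = 3L,
                             class_fractions = c(coupled = 0.0025,
                                                 antidirectional = 0.0005,
                                                 transcriptome_only = 0.004,
                                                 translatome_only = 0.039,
                                                 unchanged = 0.954),
                             effect_size = 2.0,
                             noise_sd = 0.3,
                             baseline_range = c(6, 14),
                             seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  if (!all(COUPLING_CLASSES %in% names(class_fractions)))
    stop("class_fractions must name all of: ",
         paste(COUPLING_CLASSES, collapse = ", "))
  class_fractions <- class_fractions[COUPLING_CLASSES]
  if (any(class_fractions < 0))
    stop("class_fractions must be nonnegative")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1 (got ", sum(class_fractions), ")")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (length(baseline_range) != 2L || baseline_range[2L] < baseline_range[1L])
    stop("baseline_range must be (low, high)")
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 class_fractions = class_fractions,
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# Largest-remainder apportionment of n among fractions (deterministic).
.apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Generate a paired transcriptome/translatome dataset with planted truth
#'
#' Draws per-gene log2 baselines uniformly within \code{baseline_range}
#' (independently per level), plants signed log2 effects in the treated
#' condition according to each gene's coupling class, and adds i.i.d.
#' Gaussian replicate noise. Effect signs are random (fair coin) per gene;
#' antidirectional genes receive effects of opposite sign at the two levels.
#'
#' @param config A [synthetic_config()].
#' @return List with elements \code{set} (a \code{PairedExpressionSet}) and
#'   \code{truth} (data frame: \code{gene_id}, \code{class},
#'   \code{effect_transcriptome}, \code{effect_translatome}).
#' @export
generate_paired_dataset <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    config <- do.call(synthetic_config, config)
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  counts <- .apportion(n, config$class_fractions)
  classes <- rep(COUPLING_CLASSES, counts)
  classes <- sample(classes)           # shuffle gene order of classes

  sign_trans <- sample(c(-1, 1), n, replace = TRUE)
  sign_transl <- sample(c(-1, 1), n, replace = TRUE)
  e <- config$effect_size
  eff_trans <- ifelse(classes %in% c("coupled", "antidirectional",
                                     "transcriptome_only"),
                      sign_trans * e, 0)
  eff_transl <- numeric(n)
  eff_transl[classes == "coupled"] <- eff_trans[classes == "coupled"]
  eff_transl[classes == "antidirectional"] <-
    -eff_trans[classes == "antidirectional"]
  eff_transl[classes == "translatome_only"] <-
    (sign_transl * e)[classes == "translatome_only"]

  k <- config$n_replicates
  lo <- config$baseline_range[1L]; hi <- config$baseline_range[2L]
  make_group <- function(baseline, shift) {
    m <- matrix(baseline + shift, nrow = n, ncol = k) +
      matrix(stats::rnorm(n * k, sd = config$noise_sd), nrow = n)
    rownames(m) <- genes
    colnames(m) <- sprintf("r%d", seq_len(k))
    m
  }
  base_trans <- stats::runif(n, lo, hi)
  base_transl <- stats::runif(n, lo, hi)
  mats <- list(
    transcriptome_control = make_group(base_trans, 0),
    transcriptome_treated = make_group(base_trans, eff_trans),
    translatome_control   = make_group(base_transl, 0),
    translatome_treated   = make_group(base_transl, eff_transl))

  truth <- data.frame(gene_id = genes, class = classes,
                      effect_transcriptome = eff_trans,
                      effect_translatome = eff_transl,
                      stringsAsFactors = FALSE)
  list(set = paired_expression_set(mats), truth = truth)
}

#' Write planted truth labels to TSV
#' @param truth Truth data frame from [generate_paired_dataset()].
#' @param path Output file.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate a toy rooted DAG ontology with gene annotations and a slim map
#'
#' Builds a single-rooted acyclic ontology: terms attach to a parent in a
#' balanced \code{branching}-ary tree via \code{is_a} or \code{part_of}
#' edges; occasional extra \code{part_of} edges to earlier non-ancestor terms
#' turn the tree into a proper DAG. Every term annotates at least one gene.
#' The slim mapping assigns each term to the child-of-root lineage it
#' descends from (the root maps to itself).
#'
#' @param n_terms Number of terms (>= 1).
#' @param branching Maximum children per parent in the backbone tree.
#' @param seed Integer RNG seed.
#' @param n_genes Size of the annotated gene pool (default \code{2 * n_terms}).
#' @return List with \code{graph} (an \code{OntologyGraph}),
#'   \code{annotations} (data frame \code{gene_id}, \code{term_id}) and
#'   \code{slim} (data frame \code{term_id}, \code{slim_category}).
#' @export
generate_toy_ontology <- function(n_terms, branching = 2L, seed = 1L,
                                  n_genes = 2L * n_terms) {
  if (n_terms < 1L) stop("n_terms must be >= 1")
  set.seed(seed)
  ids <- sprintf("TOY:%07d", seq_len(n_terms))
  terms <- data.frame(id = ids,
                      name = sprintf("toy term %d", seq_len(n_terms)),
                      namespace = "toy_process",
                      stringsAsFactors = FALSE)
  edges <- NULL
  if (n_terms > 1L) {
    parent_idx <- ((seq_len(n_terms - 1L) - 1L) %/% branching) + 1L
    rel <- sample(c("is_a", "part_of"), n_terms - 1L, replace = TRUE,
                  prob = c(0.8, 0.2))
    edges <- data.frame(child = ids[-1L], parent = ids[parent_idx],
                        relation = rel, stringsAsFactors = FALSE)
    # extra cross edges: child -> earlier term, skipping its backbone ancestors
    for (i in seq_len(n_terms)[-c(1L, 2L)]) {
      if (stats::runif(1) > 0.15) next
      backbone <- i
      j <- i
      while (j > 1L) { j <- parent_idx[j - 1L]; backbone <- c(backbone, j) }
      cand <- setdiff(seq_len(i - 1L), backbone)
      if (!length(cand)) next
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      edges <- rbind(edges, data.frame(child = ids[i], parent = ids[p],
                                       relation = "part_of",
                                       stringsAsFactors = FALSE))
    }
    edges <- unique(edges)
  }
  graph <- ontology_graph(terms, edges)

  gene_pool <- sprintf("G%05d", seq_len(max(1L, n_genes)))
  ann <- do.call(rbind, lapply(ids, function(tid) {
    k <- sample.int(3L, 1L)
    data.frame(gene_id = sample(gene_pool, min(k, length(gene_pool))),
               term_id = tid, stringsAsFactors = FALSE)
  }))
  ann <- unique(ann[order(ann$term_id, ann$gene_id), ])
  rownames(ann) <- NULL

  slim_cat <- character(n_terms)
  slim_cat[1L] <- ids[1L]
  if (n_terms > 1L) {
    for (i in seq_len(n_terms)[-1L]) {
      j <- i
      while (parent_idx[j - 1L] != 1L) j <- parent_idx[j - 1L]
      slim_cat[i] <- ids[j]
    }
  }
  slim <- data.frame(term_id = ids, slim_category = slim_cat,
                     stringsAsFactors = FALSE)
  list(graph = graph, annotations = ann, slim = slim)
}

#' Annotate ontology terms with planted differential-expression structure
#'
#' Builds a gene/term annotation table over a synthetic dataset's gene
#' universe in which chosen terms are enriched for planted translatome or
#' transcriptome DEGs, emulating the situation where biological themes (for
#' instance translation-related terms) are regulated specifically at one
#' level. Remaining terms draw genes uniformly.
#'
#' @param truth Truth data frame from [generate_paired_dataset()].
#' @param term_ids Character vector of term ids to annotate.
#' @param translatome_terms,transcriptome_terms Term ids (subsets of
#'   \code{term_ids}) biased towards planted translatome / transcriptome
#'   DEGs.
#' @param genes_per_term Annotation-set size per term.
#' @param bias Fraction of each biased term's genes drawn from the planted
#'   DEG pool (default 0.7).
#' @param seed Integer RNG seed.
#' @return Data frame \code{gene_id}, \code{term_id}.
#' @export
annotate_planted_terms <- function(truth, term_ids,
                                   translatome_terms = character(0),
                                   transcriptome_terms = character(0),
                                   genes_per_term = 15L, bias = 0.7,
                                   seed = 1L) {
  set.seed(seed)
  pools <- list(translatome = truth$gene_id[truth$effect_translatome != 0],
                transcriptome = truth$gene_id[truth$effect_transcriptome != 0])
  draw <- function(pool) {
    n_bias <- min(round(bias * genes_per_term), length(pool))
    c(sample(pool, n_bias),
      sample(truth$gene_id, genes_per_term - n_bias))
  }
  ann <- lapply(term_ids, function(tid) {
    genes <- if (tid %in% translatome_terms) draw(pools$translatome)
    else if (tid %in% transcriptome_terms) draw(pools$transcriptome)
    else sample(truth$gene_id, genes_per_term)
    data.frame(gene_id = unique(genes), term_id = tid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, ann)
  rownames(out) <- NULL
  out
}
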