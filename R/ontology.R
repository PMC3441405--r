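#' Construct an ontology graph
#'
#' A rooted directed acyclic graph of terms with typed child-to-parent edges
#' (\code{is_a}, \code{part_of}). Each relation type carries a semantic
#' contribution weight in (0, 1) used by the graph-based similarity measure.
#'
#' @param terms Data frame with columns \code{id}, \code{name},
#'   \code{namespace}.
#' @param edges Data frame with columns \code{child}, \code{parent},
#'   \code{relation}, or NULL for an edgeless (single-term) ontology.
#' @param weights Named numeric semantic contribution per relation type.
#' @return An object of class \code{OntologyGraph}.
#' @export
ontology_graph <- function(terms, edges = NULL,
                           weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  if (anyDuplicated(terms$id)) stop("duplicate term ids")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown))
    stop("edges reference unknown terms: ", paste(unknown, collapse = ", "))
  if (!all(edges$relation %in% names(weights)))
    stop("edge relations must be among: ", paste(names(weights),
                                                 collapse = ", "))
  if (any(weights <= 0 | weights >= 1))
    stop("relation weights must lie in (0, 1)")
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = terms$id)
  if (!igraph::is_dag(g)) {
    cyc <- tryCatch(
      igraph::girth(igraph::as_undirected(g))$circle, error = function(e) NULL)
    stop("ontology contains a cycle",
         if (!is.null(cyc)) paste0(" involving: ",
                                   paste(names(cyc), collapse = " -> ")))
  }
  roots <- terms$id[!(terms$id %in% edges$child)]
  if (!length(roots)) stop("ontology has no root")
  structure(list(terms = terms, edges = edges, weights = weights,
                 roots = roots, igraph = g),
            class = "OntologyGraph")
}

#' @export
print.OntologyGraph <- function(x, ...) {
  cat("OntologyGraph:", nrow(x$terms), "terms,", nrow(x$edges), "edges,",
      length(x$roots), "root(s)\n")
  cat("  namespaces:", paste(unique(x$terms$namespace), collapse = ", "), "\n")
  invisible(x)
}

#' Write an ontology graph as an OBO 1.2 file
#'
#' @param graph An \code{OntologyGraph}.
#' @param path Output file.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    lines <- c("[Term]",
               paste0("id: ", id),
               paste0("name: ", graph$terms$name[i]),
               paste0("namespace: ", graph$terms$namespace[i]))
    e <- graph$edges[graph$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, if (e$relation[j] == "is_a")
        paste0("is_a: ", e$parent[j])
        else paste0("relationship: ", e$relation[j], " ", e$parent[j]))
    }
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

#' Parse an OBO 1.2 file into an ontology graph
#'
#' Reads \code{[Term]} stanzas with \code{id}, \code{name}, \code{namespace},
#' \code{is_a} and \code{relationship:} lines. Obsolete terms are dropped and
#' counted (attribute \code{n_obsolete}).
#'
#' @param path OBO file.
#' @param weights Relation weights passed to [ontology_graph()].
#' @return An \code{OntologyGraph}.
#' @export
parse_obo <- function(path, weights = c(is_a = 0.8, part_of = 0.6)) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  terms <- list(); edges <- list(); n_obsolete <- 0L
  for (s in seq_along(starts)) {
    block <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    field <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      sub(paste0("^", key, ": "), "", v)
    }
    if (any(field("is_obsolete") == "true")) { n_obsolete <- n_obsolete + 1L; next }
    id <- field("id")[1L]
    if (is.na(id)) next
    terms[[length(terms) + 1L]] <- data.frame(
      id = id,
      name = if (length(field("name"))) field("name")[1L] else id,
      namespace = if (length(field("namespace"))) field("namespace")[1L]
                  else "default",
      stringsAsFactors = FALSE)
    for (p in field("is_a"))
      edges[[length(edges) + 1L]] <- data.frame(
        child = id, parent = sub(" !.*$", "", p), relation = "is_a",
        stringsAsFactors = FALSE)
    for (r in field("relationship")) {
      parts <- strsplit(sub(" !.*$", "", r), " ")[[1L]]
      edges[[length(edges) + 1L]] <- data.frame(
        child = id, parent = parts[2L], relation = parts[1L],
        stringsAsFactors = FALSE)
    }
  }
  terms <- do.call(rbind, terms)
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  # drop edges to obsolete (absent) parents
  if (!is.null(edges)) edges <- edges[edges$parent %in% terms$id &
                                        edges$child %in% terms$id, ]
  g <- ontology_graph(terms, edges, weights)
  attr(g, "n_obsolete") <- n_obsolete
  g
}

#' Semantic values of a term's ancestors
#'
#' For a term \code{a}, every ancestor \code{t} (including \code{a} itself)
#' receives an S-value: the maximum over directed paths from \code{a} up to
#' \code{t} of the product of edge weights along the path, with
#' \code{S(a) = 1}. Computed by dynamic programming in topological order.
#'
#' @param term Term id.
#' @param graph An \code{OntologyGraph}.
#' @return Named numeric vector of S-values over the term's ancestor closure.
#' @export
term_svalues <- function(term, graph) {
  if (!term %in% graph$terms$id) stop("unknown term: ", term)
  anc <- names(igraph::subcomponent(graph$igraph, term, mode = "out"))
  sub <- igraph::induced_subgraph(graph$igraph, anc)
  ord <- names(igraph::topo_sort(sub, mode = "out"))  # children before parents
  s <- stats::setNames(numeric(length(anc)), anc)
  s[term] <- 1
  e <- graph$edges[graph$edges$child %in% anc & graph$edges$parent %in% anc, ,
                   drop = FALSE]
  w <- graph$weights[e$relation]
  for (t in ord) {
    if (t == term) next
    idx <- which(e$parent == t)
    if (length(idx)) s[t] <- max(w[idx] * s[e$child[idx]])
  }
  s
}

#' Graph-based semantic similarity between two terms
#'
#' Aggregate semantic-value similarity: each term's ancestors (self included)
#' carry S-values ([term_svalues()]); the similarity is the sum of both
#' terms' S-values over their common ancestors, divided by the sum of all
#' S-values of the two terms. Ranges in (0, 1]; \code{sim(a, a) = 1}.
#'
#' @param a,b Term ids (same namespace).
#' @param graph An \code{OntologyGraph}.
#' @return Similarity in (0, 1].
#' @export
pairwise_similarity <- function(a, b, graph) {
  ns <- graph$terms$namespace[match(c(a, b), graph$terms$id)]
  if (anyNA(ns)) stop("unknown term(s): ",
                      paste(c(a, b)[is.na(ns)], collapse = ", "))
  if (ns[1L] != ns[2L])
    stop("cross-namespace pair: ", a, " (", ns[1L], ") vs ", b,
         " (", ns[2L], ")")
  sa <- term_svalues(a, graph)
  sb <- term_svalues(b, graph)
  common <- intersect(names(sa), names(sb))
  (sum(sa[common]) + sum(sb[common])) / (sum(sa) + sum(sb))
}

# max similarity of each term in `terms` against any term in `others`;
# cross-namespace pairs contribute 0 when cross_namespace = "zero".
.max_similarities <- function(terms, others, graph,
                              cross_namespace = c("zero", "error")) {
  cross_namespace <- match.arg(cross_namespace)
  ns <- stats::setNames(graph$terms$namespace, graph$terms$id)
  vapply(terms, function(a) {
    sims <- vapply(others, function(b) {
      if (ns[[a]] != ns[[b]]) {
        if (cross_namespace == "error") stop("cross-namespace pair")
        return(0)
      }
      pairwise_similarity(a, b, graph)
    }, numeric(1))
    max(sims)
  }, numeric(1))
}

#' Semantic transcriptome/translatome specificity of two enriched-term lists
#'
#' The translatome specificity is 1 minus the mean, over the m translatome
#' terms, of each term's maximum similarity to any of the n transcriptome
#' terms; the transcriptome specificity swaps the roles (divisor n). Both lie
#' in [0, 1]; identical lists give 0 (no specificity).
#'
#' @param translatome_terms,transcriptome_terms Character vectors of term ids
#'   (both non-empty for a defined result).
#' @param graph An \code{OntologyGraph}.
#' @param cross_namespace \code{"zero"} (default) scores cross-namespace
#'   pairs as similarity 0; \code{"error"} refuses them.
#' @return List of class \code{SpecificityResult}: \code{m}, \code{n},
#'   \code{translatome_specificity}, \code{transcriptome_specificity},
#'   per-term max-similarity vectors, and \code{reason} (NA unless the result
#'   is undefined because a list is empty).
#' @export
semantic_specificity <- function(translatome_terms, transcriptome_terms,
                                 graph, cross_namespace = "zero") {
  m <- length(translatome_terms); n <- length(transcriptome_terms)
  if (m == 0L || n == 0L) {
    return(structure(list(m = m, n = n,
                          translatome_specificity = NA_real_,
                          transcriptome_specificity = NA_real_,
                          max_sim_translatome = numeric(0),
                          max_sim_transcriptome = numeric(0),
                          reason = "empty term list at one level"),
                     class = "SpecificityResult"))
  }
  ms_tl <- .max_similarities(translatome_terms, transcriptome_terms, graph,
                             cross_namespace)
  ms_tr <- .max_similarities(transcriptome_terms, translatome_terms, graph,
                             cross_namespace)
  structure(list(m = m, n = n,
                 translatome_specificity = 1 - mean(ms_tl),
                 transcriptome_specificity = 1 - mean(ms_tr),
                 max_sim_translatome = ms_tl,
                 max_sim_transcriptome = ms_tr,
                 reason = NA_character_),
            class = "SpecificityResult")
}

#' @export
print.SpecificityResult <- function(x, ...) {
  if (!is.na(x$reason)) {
    cat("SpecificityResult: undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "SpecificityResult: m=%d translatome terms, n=%d transcriptome terms\n",
      x$m, x$n))
    cat(sprintf("  translatome specificity:   %.4f\n",
                x$translatome_specificity))
    cat(sprintf("  transcriptome specificity: %.4f\n",
                x$transcriptome_specificity))
  }
  invisible(x)
}

#' Cross-dataset reference distribution of semantic specificities
#'
#' For each dataset i, computes the specificity of its transcriptome term
#' list against the transcriptome list of every other dataset j (orientation:
#' 1 minus mean max-similarity of list i's terms to list j). Heterogeneous
#' datasets yield high values; the within-pair transcriptome-vs-translatome
#' specificity can then be located relative to this distribution.
#'
#' @param transcriptome_lists Named list (>= 3) of character term vectors.
#' @param graph An \code{OntologyGraph}.
#' @param observed Optional named numeric: within-pair specificity per
#'   dataset, to be positioned against the reference distribution.
#' @return Data frame per dataset: \code{dataset}, \code{n_ref},
#'   \code{ref_min}, \code{ref_median}, \code{ref_max}, and (when
#'   \code{observed} is given) \code{observed}, \code{below_median},
#'   \code{below_min}.
#' @export
reference_distribution <- function(transcriptome_lists, graph,
                                   observed = NULL) {
  keep <- lengths(transcriptome_lists) > 0L
  if (any(!keep))
    message("skipping datasets with empty term lists: ",
            paste(names(transcriptome_lists)[!keep], collapse = ", "))
  lists <- transcriptome_lists[keep]
  if (length(lists) < 3L) stop("need >= 3 datasets with non-empty lists")
  nm <- names(lists)
  out <- lapply(seq_along(lists), function(i) {
    vals <- vapply(seq_along(lists)[-i], function(j) {
      1 - mean(.max_similarities(lists[[i]], lists[[j]], graph))
    }, numeric(1))
    row <- data.frame(dataset = nm[i], n_ref = length(vals),
                      ref_min = min(vals), ref_median = stats::median(vals),
                      ref_max = max(vals), stringsAsFactors = FALSE)
    if (!is.null(observed)) {
      obs <- observed[[nm[i]]]
      row$observed <- if (is.null(obs)) NA_real_ else obs
      row$below_median <- row$observed < row$ref_median
      row$below_min <- row$observed < row$ref_min
    }
    row
  })
  do.call(rbind, out)
}

#' GOslim-style specificity degrees across datasets
#'
#' For every term over-represented in at least one dataset, the transcriptome
#' specificity degree is the fraction of datasets (among those where the term
#' is over-represented at either level) in which it is transcriptome-specific
#' (enriched only at the transcriptome level); the translatome degree is
#' symmetric. Terms are rolled up to slim categories by median degree, and
#' categories ranked by translatome minus transcriptome degree. Also returns
#' the per-dataset normalized difference between translatome-only and
#' transcriptome-only term counts, ranging -1 (all transcriptome-specific)
#' to 1 (all translatome-specific).
#'
#' @param enrichment_lists Named list; each element a list with character
#'   vectors \code{transcriptome} and \code{translatome} of enriched terms.
#' @param slim_map Data frame \code{term_id}, \code{slim_category}.
#' @return List with data frames \code{term_degrees} (term_id,
#'   n_overrepresented, transcriptome_degree, translatome_degree),
#'   \code{category_degrees} (slim_category, n_terms, median degrees, delta,
#'   sorted by delta descending), and \code{dataset_balance} (dataset,
#'   n_transcriptome_only, n_translatome_only, normalized_difference).
#' @export
goslim_specificity_degrees <- function(enrichment_lists, slim_map) {
  all_terms <- unique(unlist(lapply(enrichment_lists, unlist),
                             use.names = FALSE))
  per_term <- lapply(all_terms, function(t) {
    in_tr <- vapply(enrichment_lists, function(d) t %in% d$transcriptome,
                    logical(1))
    in_tl <- vapply(enrichment_lists, function(d) t %in% d$translatome,
                    logical(1))
    n_over <- sum(in_tr | in_tl)
    data.frame(term_id = t, n_overrepresented = n_over,
               transcriptome_degree = sum(in_tr & !in_tl) / n_over,
               translatome_degree = sum(in_tl & !in_tr) / n_over,
               stringsAsFactors = FALSE)
  })
  empty_terms <- data.frame(term_id = character(0),
                            n_overrepresented = integer(0),
                            transcriptome_degree = numeric(0),
                            translatome_degree = numeric(0))
  term_degrees <- if (length(per_term)) do.call(rbind, per_term)
                  else empty_terms
  term_degrees <- term_degrees[term_degrees$n_overrepresented > 0L, ,
                               drop = FALSE]

  td <- merge(term_degrees, slim_map, by = "term_id")
  cats <- split(td, td$slim_category)
  category_degrees <- do.call(rbind, lapply(names(cats), function(cn) {
    d <- cats[[cn]]
    data.frame(slim_category = cn, n_terms = nrow(d),
               median_transcriptome_degree =
                 stats::median(d$transcriptome_degree),
               median_translatome_degree = stats::median(d$translatome_degree),
               stringsAsFactors = FALSE)
  }))
  if (is.null(category_degrees)) {
    category_degrees <- data.frame(slim_category = character(0),
                                   n_terms = integer(0),
                                   median_transcriptome_degree = numeric(0),
                                   median_translatome_degree = numeric(0),
                                   delta = numeric(0))
  } else {
    category_degrees$delta <- category_degrees$median_translatome_degree -
      category_degrees$median_transcriptome_degree
    category_degrees <-
      category_degrees[order(-category_degrees$delta), , drop = FALSE]
    rownames(category_degrees) <- NULL
  }

  dataset_balance <- do.call(rbind, lapply(names(enrichment_lists),
                                           function(nm) {
    d <- enrichment_lists[[nm]]
    n_tr <- length(setdiff(d$transcriptome, d$translatome))
    n_tl <- length(setdiff(d$translatome, d$transcriptome))
    tot <- n_tr + n_tl
    data.frame(dataset = nm, n_transcriptome_only = n_tr,
               n_translatome_only = n_tl,
               normalized_difference = if (tot > 0) (n_tl - n_tr) / tot
                                       else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(term_degrees = term_degrees, category_degrees = category_degrees,
       dataset_balance = dataset_balance)
}
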