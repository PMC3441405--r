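test_that("OBO writing and parsing round-trip the graph", {
  o <- generate_toy_ontology(10, branching = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(o$graph, path)
  back <- parse_obo(path)
  expect_setequal(back$terms$id, o$graph$terms$id)
  key <- function(e) sort(paste(e$child, e$parent, e$relation))
  expect_equal(key(back$edges), key(o$graph$edges))
})

test_that("a tiny OBO file parses with obsolete terms dropped", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:1", "name: root", "namespace: ns", "",
    "[Term]", "id: T:2", "name: a", "namespace: ns", "is_a: T:1 ! root", "",
    "[Term]", "id: T:3", "name: b", "namespace: ns",
    "relationship: part_of T:1", "",
    "[Term]", "id: T:4", "name: gone", "namespace: ns", "is_a: T:1",
    "is_obsolete: true", ""), path)
  g <- parse_obo(path)
  expect_equal(nrow(g$terms), 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(attr(g, "n_obsolete"), 1L)
  expect_equal(g$edges$relation[g$edges$child == "T:3"], "part_of")
})

test_that("cyclic ontologies are refused", {
  terms <- data.frame(id = c("A", "B"), name = c("a", "b"), namespace = "ns")
  edges <- data.frame(child = c("A", "B"), parent = c("B", "A"),
                      relation = "is_a")
  expect_error(ontology_graph(terms, edges), "cycle|root")
})

test_that("similarity of siblings under one root matches the hand value", {
  g <- sibling_graph(w = 0.8)
  expect_equal(pairwise_similarity("A", "A", g), 1)
  # S-values: A -> {A: 1, R: 0.8}; B likewise; common ancestor R only
  expect_equal(pairwise_similarity("A", "B", g), 1.6 / 3.6, tolerance = 1e-12)
  expect_equal(pairwise_similarity("A", "B", g),
               pairwise_similarity("B", "A", g))
})

test_that("cross-namespace pairs error in pairwise similarity", {
  terms <- data.frame(id = c("A", "B"), name = c("a", "b"),
                      namespace = c("ns1", "ns2"))
  g <- ontology_graph(terms, NULL)
  expect_error(pairwise_similarity("A", "B", g), "cross-namespace")
})

test_that("similarity equals the exhaustive-path oracle on small DAGs", {
  for (seed in 1:6) {
    o <- generate_toy_ontology(8, branching = 2, seed = seed)
    ids <- o$graph$terms$id
    for (a in ids[c(2, 5, 8)]) for (b in ids[c(3, 7)]) {
      expect_equal(pairwise_similarity(a, b, o$graph),
                   oracle_similarity(a, b, o$graph), tolerance = 1e-12)
    }
    # bounds and root positivity
    sims <- vapply(ids, pairwise_similarity, numeric(1), b = ids[1],
                   graph = o$graph)
    expect_true(all(sims > 0 & sims <= 1))
  }
})

test_that("semantic specificity reproduces the hand-computed fixtures", {
  g <- sibling_graph(w = 0.8)
  ident <- semantic_specificity(c("A", "B"), c("A", "B"), g)
  expect_equal(ident$translatome_specificity, 0)
  expect_equal(ident$transcriptome_specificity, 0)

  ab <- semantic_specificity("A", "B", g)
  expect_equal(ab$translatome_specificity, 1 - 1.6 / 3.6, tolerance = 1e-12)
  expect_equal(ab$transcriptome_specificity, 1 - 1.6 / 3.6, tolerance = 1e-12)

  asym <- semantic_specificity("A", c("A", "B"), g)
  expect_equal(asym$translatome_specificity, 0)
  expect_equal(asym$transcriptome_specificity, (0 + (1 - 1.6 / 3.6)) / 2,
               tolerance = 1e-12)

  undef <- semantic_specificity(character(0), "A", g)
  expect_true(is.na(undef$translatome_specificity))
  expect_match(undef$reason, "empty")
})

test_that("adding a copied term to the other list cannot raise its specificity", {
  for (seed in 1:4) {
    o <- generate_toy_ontology(10, branching = 2, seed = seed)
    ids <- o$graph$terms$id
    tl <- ids[2:4]; tr <- ids[5:7]
    before <- semantic_specificity(tl, tr, o$graph)$translatome_specificity
    after <- semantic_specificity(tl, c(tr, tl[1]),
                                  o$graph)$translatome_specificity
    expect_lte(after, before + 1e-12)
    both <- semantic_specificity(tl, tr, o$graph)
    expect_true(both$translatome_specificity >= 0 &&
                  both$translatome_specificity <= 1)
  }
})

test_that("reference distributions behave on degenerate and sibling fixtures", {
  g <- sibling_graph(w = 0.8)
  shared <- list(d1 = c("A", "B"), d2 = c("A", "B"), d3 = c("A", "B"))
  ref <- reference_distribution(shared, g)
  expect_true(all(ref$ref_min == 0 & ref$ref_max == 0))

  # terms: root + 3 siblings; three datasets with one distinct sibling each
  terms <- data.frame(id = c("R", "A", "B", "C"),
                      name = c("r", "a", "b", "c"), namespace = "ns")
  edges <- data.frame(child = c("A", "B", "C"), parent = "R",
                      relation = "is_a")
  g4 <- ontology_graph(terms, edges)
  sib <- 1 - 1.6 / 3.6
  ref2 <- reference_distribution(list(d1 = "A", d2 = "B", d3 = "C"), g4,
                                 observed = c(d1 = 0, d2 = sib, d3 = 0.9))
  expect_equal(ref2$ref_min, rep(sib, 3), tolerance = 1e-12)
  expect_equal(ref2$ref_max, rep(sib, 3), tolerance = 1e-12)
  expect_equal(ref2$below_min, c(TRUE, FALSE, FALSE))
})

test_that("slim specificity degrees and dataset balance follow the ratios", {
  lists <- list(
    d1 = list(transcriptome = c("T1", "T2"), translatome = c("T2", "T3")),
    d2 = list(transcriptome = "T1", translatome = c("T3", "T4")),
    d3 = list(transcriptome = c("T1", "T3"), translatome = "T3"),
    d4 = list(transcriptome = "T1", translatome = character(0)))
  slim <- data.frame(term_id = paste0("T", 1:4),
                     slim_category = c("S1", "S1", "S2", "S2"))
  out <- goslim_specificity_degrees(lists, slim)
  t1 <- out$term_degrees[out$term_degrees$term_id == "T1", ]
  # T1 over-represented in 4 datasets, transcriptome-specific in all 4
  expect_equal(t1$transcriptome_degree, 1)
  t3 <- out$term_degrees[out$term_degrees$term_id == "T3", ]
  # T3 in d1, d2 translatome-only; in d3 both levels -> 2 of 3
  expect_equal(t3$translatome_degree, 2 / 3, tolerance = 1e-12)
  # d2: 1 transcriptome-only vs 2 translatome-only
  bal <- out$dataset_balance
  expect_equal(bal$normalized_difference[bal$dataset == "d2"], 1 / 3)
  # d4: only transcriptome-specific terms -> boundary value -1
  expect_equal(bal$normalized_difference[bal$dataset == "d4"], -1)
  expect_true(all(diff(out$category_degrees$delta) <= 0))
})

test_that("slim degrees cope with no over-represented terms", {
  out <- goslim_specificity_degrees(
    list(d1 = list(transcriptome = character(0),
                   translatome = character(0)),
         d2 = list(transcriptome = character(0),
                   translatome = character(0))),
    data.frame(term_id = "T1", slim_category = "S1"))
  expect_equal(nrow(out$term_degrees), 0L)
  expect_equal(nrow(out$category_degrees), 0L)
  expect_true(all(is.na(out$dataset_balance$normalized_difference)))
})
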