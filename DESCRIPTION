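Package: uncoupleR
Title: Transcriptome-Translatome Uncoupling Analysis for Paired Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Paired differential-expression analysis of total (transcriptome)
    and polysome-associated (translatome) mRNA profiles. Implements a
    rank-product caller with permutation-based percentage of false prediction
    (pfp) and a t-test/Benjamini-Hochberg alternative, classification of genes
    into coupled, antidirectional, transcriptome-only and translatome-only
    classes, hypergeometric term enrichment with FDR control, graph-based
    ontology semantic similarity and transcriptome/translatome semantic
    specificity statistics, and three tests of transcriptome-translatome
    independence (likelihood ratio on DEG counts, random-overlap bootstrap
    with exact hypergeometric oracle, and mutual information with feasibility
    bounds). Includes a synthetic paired-expression generator with planted
    coupling structure and a toy ontology generator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
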