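#!/usr/bin/env Rscript
# Step 4 -- ontological enrichment and semantic specificity.
#
# Runs hypergeometric over-representation of the transcriptome and
# translatome DEG lists against the toy ontology's annotation catalog (BH
# FDR 5%), summarizes the overlap of enriched terms, and computes the
# graph-based semantic transcriptome/translatome specificity. A small batch
# of additional simulated datasets then provides the cross-dataset reference
# distribution and GOslim-style specificity degrees.

suppressPackageStartupMessages(library(uncoupleR))

graph <- parse_obo("results/data/toy_ontology.obo")
ann <- read.delim("results/data/annotations.tsv")
slim <- read.delim("results/data/slim_map.tsv")
trans <- read.delim("results/degs_transcriptome_rankprod.tsv")
transl <- read.delim("results/degs_translatome_rankprod.tsv")
universe <- trans$gene_id
catalog <- annotation_catalog(ann, universe)

enr <- lapply(list(transcriptome = trans, translatome = transl), function(d)
  fisher_enrichment(d$gene_id[d$significant], universe, catalog, fdr = 0.05))
for (lv in names(enr))
  write.table(enr[[lv]], sprintf("results/enrichment_%s.tsv", lv),
              sep = "\t", quote = FALSE, row.names = FALSE)

tr_terms <- attr(enr$transcriptome, "enriched_terms")
tl_terms <- attr(enr$translatome, "enriched_terms")
ov <- term_overlap_summary(tr_terms, tl_terms)
message(sprintf("enriched terms: %d transcriptome-only (%s%%), %d translatome-only (%s%%), %d common (%s%%)",
                ov$n_transcriptome_only, ov$pct_transcriptome_only,
                ov$n_translatome_only, ov$pct_translatome_only,
                ov$n_common, ov$pct_common))

if (length(tr_terms) && length(tl_terms)) {
  spec <- semantic_specificity(tl_terms, tr_terms, graph)
  message(sprintf("semantic specificity: translatome %.3f, transcriptome %.3f (m=%d, n=%d)",
                  spec$translatome_specificity,
                  spec$transcriptome_specificity, spec$m, spec$n))
} else {
  spec <- NULL
  message("semantic specificity undefined: an enriched-term list is empty")
}

# --- cross-dataset batch: reference distribution and slim degrees ---------
# each simulated dataset gets its own biased annotation (different term
# blocks), emulating heterogeneous experiments with distinct regulated themes
ids <- graph$terms$id
batch <- lapply(1:5, function(i) {
  d <- generate_paired_dataset(synthetic_config(n_genes = 1000,
                                                seed = 400L + i))
  tl_block <- ids[(5 + 6 * (i - 1)):(10 + 6 * (i - 1))]
  tr_block <- ids[(35 + 4 * (i - 1)):(37 + 4 * (i - 1))]
  a <- annotate_planted_terms(d$truth, ids, translatome_terms = tl_block,
                              transcriptome_terms = tr_block,
                              genes_per_term = 15L, bias = 0.7,
                              seed = 400L + i)
  cat_i <- annotation_catalog(a, d$set$feature_ids)
  lapply(c(transcriptome = "effect_transcriptome",
           translatome = "effect_translatome"), function(col) {
    degs <- d$truth$gene_id[d$truth[[col]] != 0]
    attr(fisher_enrichment(degs, d$set$feature_ids, cat_i, fdr = 0.05),
         "enriched_terms")
  })
})
names(batch) <- sprintf("sim%02d", 1:5)

tr_lists <- lapply(batch, `[[`, "transcriptome")
keep <- lengths(tr_lists) > 0
if (sum(keep) >= 3) {
  ref <- reference_distribution(tr_lists[keep], graph)
  write.table(ref, "results/reference_distribution.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("reference distribution over %d datasets: median specificity %.3f-%.3f",
                  sum(keep), min(ref$ref_median), max(ref$ref_median)))
}

degrees <- goslim_specificity_degrees(batch, slim)
write.table(degrees$category_degrees, "results/goslim_degrees.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(degrees$dataset_balance, "results/dataset_balance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d slim categories ranked; dataset balance range %.2f to %.2f",
                nrow(degrees$category_degrees),
                min(degrees$dataset_balance$normalized_difference, na.rm = TRUE),
                max(degrees$dataset_balance$normalized_difference, na.rm = TRUE)))
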