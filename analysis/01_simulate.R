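#!/usr/bin/env Rscript
# Step 1 -- simulate a paired transcriptome/translatome study.
#
# Generates one study-scale synthetic dataset (2000 genes, 3 replicates per
# condition per RNA level, log2 effect 2.0, replicate noise sd 0.3) with the
# EGF-like planted class mix, plus a toy DAG ontology with gene annotations
# and a slim mapping, and writes everything as plain-text files under
# results/data/ for the downstream steps.

suppressPackageStartupMessages(library(uncoupleR))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(n_genes = 2000L, n_replicates = 3L,
                        effect_size = 2.0, noise_sd = 0.3, seed = 8452L)
d <- generate_paired_dataset(cfg)
write_paired_expression_set(d$set, out)
write_truth(d$truth, file.path(out, "truth.tsv"))

onto <- generate_toy_ontology(n_terms = 60L, branching = 3L, seed = 8452L,
                              n_genes = 2000L)
# annotate terms over the simulated gene universe; one block of
# "translation-like" terms is biased towards planted translatome DEGs and a
# smaller block towards transcriptome DEGs, so enrichment has signal to find
ids <- onto$graph$terms$id
onto$annotations <- annotate_planted_terms(
  d$truth, ids,
  translatome_terms = ids[5:12], transcriptome_terms = ids[13:16],
  genes_per_term = 15L, bias = 0.7, seed = 8453L)
write_obo(onto$graph, file.path(out, "toy_ontology.obo"))
write.table(onto$annotations, file.path(out, "annotations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(onto$slim, file.path(out, "slim_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_deg <- sum(d$truth$class != "unchanged")
message(sprintf("simulated %d genes; %d planted DEGs (%.1f%%), class mix:",
                cfg$n_genes, n_deg, 100 * n_deg / cfg$n_genes))
print(table(d$truth$class))
message("wrote expression TSVs, truth, OBO ontology and slim map to ", out)
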