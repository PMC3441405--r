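#!/usr/bin/env Rscript
# Step 3 -- coupling classification and uncoupling degree.
#
# Classifies every gene into coupled / antidirectional / transcriptome-only /
# translatome-only / unchanged from the two DEG tables, summarizes the
# degree of uncoupling, sweeps the significance threshold from 0.01 to 0.5
# to show the classification is threshold-stable, and counts translationally
# enhanced vs buffered genes.

suppressPackageStartupMessages(library(uncoupleR))

trans <- read.delim("results/degs_transcriptome_rankprod.tsv")
transl <- read.delim("results/degs_translatome_rankprod.tsv")
fc <- read.delim("results/fold_changes.tsv")
truth <- read.delim("results/data/truth.tsv")

coupling <- classify_coupling(trans, transl, fold_changes = fc)
write.table(coupling, "results/coupling.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
s <- summarize_uncoupling(coupling)
message(sprintf("%d DEGs: %.1f%% uncoupled, %.1f%% coupled; translatome:transcriptome-only ratio %.1f",
                s$n_degs, s$uncoupled_pct, s$coupled_pct,
                s$translatome_to_transcriptome_ratio))

planted <- table(factor(truth$class, levels = COUPLING_CLASSES))
recovered <- table(coupling$class)
err <- 100 * (as.numeric(recovered) - as.numeric(planted)) / nrow(truth)
message(sprintf("planted-class recovery: max deviation %.2f percentage points",
                max(abs(err))))

sweep <- threshold_sweep(trans, transl,
                         thresholds = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5))
write.table(sweep, "results/threshold_sweep.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
u_by_th <- vapply(split(sweep, sweep$threshold), function(d) {
  deg <- d$count[d$class != "unchanged"]
  100 * sum(deg[d$class[d$class != "unchanged"] != "coupled"]) / sum(deg)
}, numeric(1))
message("uncoupled% across thresholds 0.01-0.5: ",
        paste(sprintf("%.0f", u_by_th), collapse = " / "))

deg_union <- union(trans$gene_id[trans$significant],
                   transl$gene_id[transl$significant])
b_deg <- buffering_counts(fc, genes = deg_union)
b_all <- buffering_counts(fc)
message(sprintf("buffering (DEG union): %.0f%% enhanced / %.0f%% buffered (%d tied); all genes: %.0f%% / %.0f%%",
                b_deg$enhanced_pct, b_deg$buffered_pct, b_deg$n_tied,
                b_all$enhanced_pct, b_all$buffered_pct))
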