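#!/usr/bin/env Rscript
# Transcriptional regulatory networks: assign gained enhancers to genes
# (single-nearest TSS and curated element-gene modes), keep targets with
# significantly increased expression (FDR < 0.05, log2FC > 0), intersect
# the per-TF networks, and test the recovered target set by ORA and
# preranked enrichment.

suppressMessages(library(regcircuit))

synth <- "results/synth"
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
genome <- read_genome(file.path(synth, "genome.txt"))
tss <- read_tss(file.path(synth, "tss.tsv"))
rd <- function(f, fmt) read_intervals(file.path(synth, f), fmt, genome)
truth <- jsonlite::read_json(file.path(synth, "truth.json"),
                             simplifyVector = TRUE)

gained <- differential_enhancers(rd("h3k27ac_restored.broadPeak", "broadPeak"),
                                 rd("h3k27ac_absent.broadPeak", "broadPeak"))
de <- read_de_table(file.path(synth, "de_table.tsv"))
inter <- read_interactions(file.path(synth, "interactions.tsv"))

trn_n <- build_trn(assign_nearest(gained, tss), de)
trn_c <- build_trn(assign_curated(gained, inter), de)
cat(sprintf("TRN (nearest-gene): %d upregulated targets; (curated): %d\n",
            length(trn_n$genes), length(trn_c$genes)))
cat(sprintf("planted targets recovered: nearest %d/%d, curated %d/%d\n",
            length(intersect(trn_n$genes, truth$upregulated_targets)),
            length(truth$upregulated_targets),
            length(intersect(trn_c$genes, truth$upregulated_targets)),
            length(truth$upregulated_targets)))
utils::write.table(trn_c$links, "results/tables/trn_links_curated.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# per-TF networks from TF-bound gained enhancers, and their overlap
tf_trns <- lapply(truth$tfs, function(tf) {
  tfpk <- rd(sprintf("tf_%s_restored.narrowPeak", tf), "narrowPeak")
  bound <- subtract_intervals(gained, tfpk, "whole_peak")
  bound <- subtract_intervals(gained, bound, "whole_peak")  # gained & TF-bound
  build_trn(assign_curated(bound, inter), de, tf = tf)
})
names(tf_trns) <- truth$tfs
ov <- trn_overlap(tf_trns)
utils::write.table(data.frame(region = names(ov), n_genes = as.integer(ov)),
                   "results/tables/trn_overlap.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("per-TF target overlap (Venn regions):",
    paste(sprintf("%s=%d", names(ov), ov), collapse = " "), "\n")

# enrichment of the recovered network against the gene-set collection
gmt <- read_gmt(file.path(synth, "gene_sets.gmt"))
ora <- ora_hypergeometric(trn_c$genes, gmt, de$gene)
utils::write.table(ora, "results/tables/ora.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("ORA top term: %s (p = %.2e)\n", ora$term[1], ora$p[1]))

scores <- stats::setNames(de$log2FoldChange, de$gene)
gsea <- do.call(rbind, lapply(names(gmt), function(term) {
  r <- preranked_enrichment(scores, gmt[[term]], n_perm = 1000, seed = 42)
  data.frame(term = term, es = r$es, p = r$p)
}))
utils::write.table(gsea, "results/tables/gsea.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("preranked enrichment (log2FC ranking):\n")
for (i in seq_len(nrow(gsea)))
  cat(sprintf("  %-22s ES %+.2f  p %.3g\n", gsea$term[i], gsea$es[i],
              gsea$p[i]))
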