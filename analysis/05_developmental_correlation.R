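#!/usr/bin/env Rscript
# Stage 5: sample-wise developmental correlation. Correlates each query
# expression sample with every pseudo-age of the developmental reference over
# the dependent-activated gene set; query samples generated from a given
# pseudo-age should correlate maximally with that age.

suppressMessages(library(specseqr))

seed <- 20260928
dir.create("results/targetome", showWarnings = FALSE, recursive = TRUE)

tt <- simulate_targetome_tables(n_genes = 600, seed = derive_seed(seed, "tables"))
write_expression_matrix(tt$dev_reference, "results/targetome/dev_reference.tsv")
write_expression_matrix(tt$dev_query, "results/targetome/dev_query.tsv")

gc_labels <- read_tsv_commented("results/targetome/gene_classes.tsv")
act <- gc_labels$gene_id[gc_labels$class == "dependent_activated"]

cc <- developmental_correlation(
  read_expression_matrix("results/targetome/dev_query.tsv"),
  read_expression_matrix("results/targetome/dev_reference.tsv"),
  act, transform = "log2cpm")
write_tsv_commented(data.frame(sample = rownames(cc), cc, check.names = FALSE),
                    "results/targetome/developmental_correlation.tsv",
                    meta = sprintf("transform: %s; n_genes: %d",
                                   attr(cc, "transform"),
                                   attr(cc, "n_genes")))

cat(sprintf("Correlation over %d dependent-activated genes (log2(cpm+1)):\n",
            attr(cc, "n_genes")))
print(round(cc, 3))
best <- colnames(cc)[apply(cc, 1, which.max)]
cat("Best-matching reference age per query sample:\n")
for (i in seq_len(nrow(cc))) {
  cat(sprintf("  %-10s -> %s\n", rownames(cc)[i], best[i]))
}
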