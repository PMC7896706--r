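#!/usr/bin/env Rscript
# PCA of the batch-corrected variance-stabilized matrix, factorial ANOVA
# with Tukey HSD on PC1 scores, top-loading genes and rule-based PC1
# outlier flagging.

library(frontloadr)

cm <- filter_low_counts(read_counts("results/data/counts.tsv",
                                    "results/data/metadata.csv"))
vb <- remove_batch_effect(vst(cm))
p <- pca(vb)

cat(sprintf("PC1 %.2f%%, PC2 %.2f%%, PC3 %.2f%% of variance\n",
            p$explained_variance_pct[1], p$explained_variance_pct[2],
            p$explained_variance_pct[3]))
utils::write.table(data.frame(sample_id = rownames(p$scores), p$scores),
                   "results/pca_scores.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

a <- anova_scores(p$scores[, 1], p$meta)
cat("Two-way ANOVA on PC1 scores:\n")
print(a$anova, row.names = FALSE)
cat("Tukey letter groups:",
    paste(names(a$letters), a$letters, sep = "=", collapse = "  "), "\n")
utils::write.table(a$anova, "results/pc1_anova.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

top <- top_loading_genes(p, component = 1, k = 100)
writeLines(top, "results/pc1_top100_genes.txt")
cat("Top PC1-loading genes written (first 5):",
    paste(head(top, 5), collapse = ", "), "\n")

fl <- flag_outliers(p, k_sd = 3)
if (nrow(fl) == 0) cat("No PC1 outlier samples flagged at 3 robust SDs.\n") else {
  cat("Flagged samples:\n"); print(fl, row.names = FALSE)
}
jsonlite::write_json(fl, "results/outlier_flags.json", auto_unbox = TRUE,
                     digits = NA)
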