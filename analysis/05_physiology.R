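#!/usr/bin/env Rscript
# Physiology: mass-covariate ANCOVAs on log MO2 and log lactate,
# mass-standardization of MO2 against the 10NO control regression, and the
# gene-expression vs standardized-MO2 Pearson screen (p < .01, unadjusted).

library(frontloadr)

ph <- utils::read.csv("results/data/physiology.csv")

for (resp in c("mo2", "lactate")) {
  a <- physio_ancova(ph, resp)
  cat("Two-way ANCOVA on log", resp, "(Type II, mass covariate):\n")
  print(a$anova, row.names = FALSE)
  cat("Tukey letters (covariate-adjusted means):",
      paste(names(a$letters), a$letters, sep = "=", collapse = "  "),
      "\n\n")
  utils::write.table(a$anova,
                     file.path("results", paste0("ancova_", resp, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

std <- standardize_mo2(ph)
cat(sprintf("Standardized MO2: control residual sum %.2e (least-squares check)\n",
            sum(std$std_mo2[std$treatment == "10NO"])))
utils::write.csv(std, "results/physiology_standardized.csv",
                 row.names = FALSE)

# correlate expression with standardized MO2 for the RNA-seq subset: the
# first 4-5 individuals per treatment stand in for the sequenced animals
cm <- filter_low_counts(read_counts("results/data/counts.tsv",
                                    "results/data/metadata.csv"))
vb <- remove_batch_effect(vst(cm))
samples <- colnames(vb$values)
per_tr <- split(std, std$treatment)
smo2 <- unlist(lapply(names(per_tr), function(tr) {
  ids <- samples[startsWith(samples, tr)]
  stats::setNames(per_tr[[tr]]$std_mo2[seq_along(ids)], ids)
}))
corr <- correlate_genes_mo2(vb, smo2, alpha = 0.01)
cat(sprintf("Gene-MO2 correlations: %d of %d genes flagged at p < .01\n",
            sum(corr$significant), nrow(corr)))
utils::write.table(corr, "results/gene_mo2_correlation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
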