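#!/usr/bin/env Rscript
# Filter, normalize and test the three pairwise contrasts: constitutive
# (20NO vs 10NO), cold hypoxia (10HY vs 10NO) and warm hypoxia
# (20HY vs 20NO). Writes one DE table per contrast.

library(frontloadr)

cm <- read_counts("results/data/counts.tsv", "results/data/metadata.csv")
cm <- filter_low_counts(cm, threshold = 5)
cat("Genes retained after the row-sum < 5 filter:",
    length(cm$gene_ids), "\n")

contrasts <- list(constitutive = c("20NO", "10NO"),
                  cold_hypoxia = c("10HY", "10NO"),
                  warm_hypoxia = c("20HY", "20NO"))
deg_totals <- numeric(0)
for (nm in names(contrasts)) {
  de <- nb_wald_test(cm, contrasts[[nm]])
  degs <- call_degs(de, alpha = 0.05)
  deg_totals[nm] <- length(degs$up) + length(degs$down)
  cat(sprintf("%-13s %4d up / %4d down DEGs (padj < .05)\n",
              nm, length(degs$up), length(degs$down)))
  utils::write.table(de, file.path("results", paste0("de_", nm, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
cat(sprintf("Hypoxia DEG reduction, warm vs cold: %.1f%%\n",
            100 * (1 - deg_totals["warm_hypoxia"] /
                     deg_totals["cold_hypoxia"])))
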