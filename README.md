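# frontloadr

Cross-tolerance between stressors — better performance under one stressor
after acclimation to a different one — can have a transcriptomic basis:
acclimation pre-shifts ("frontloads") the constitutive expression of
stress-response genes, so the inducible reaction when the second stressor
hits is smaller. `frontloadr` implements the full analysis for a 2x2
factorial RNA-seq + physiology design (acclimation temperature 10/20 degC
crossed with normoxia/hypoxia; treatments `10NO`, `10HY`, `20NO`, `20HY`),
for researchers studying multi-stressor plasticity in ectotherms.

## The classification at its core

For each gene significantly hypoxia-responsive in the cold-acclimated
group only (padj < .05 in `10HY` vs `10NO`, padj ≥ .05 in `20HY` vs
`20NO`), compute the raw fold changes

- fold upregulation = 2^log2FC, fold downregulation = 1/2^log2FC,

the reaction ratio r = FC_warm / FC_cold, and the constitutive expression
means c10, c20 (batch-corrected variance-stabilized counts over `10NO` and
`20NO` replicates). Then:

| condition | category |
|---|---|
| r > 1 | greater FC in warm-acclimated |
| r < 1 and constitutive shift in the direction of regulation (c20 > c10 for up-genes, c20 < c10 for down-genes) | **frontloaded** |
| r < 1, opposite constitutive shift | stress indicator |

Deviation of each direction's genes from a 50:50 split around the line of
equality is tested with a Pearson chi-squared (df = 1, no continuity
correction), X² = (a − b)²/(a + b).

Around this sit a median-of-ratios-normalized, shifted-log
variance-stabilized, batch-corrected NB Wald differential-expression stage
with BH adjustment; PCA with two-way ANOVA + Tukey HSD on scores and
rule-based outlier flagging; mass-covariate ANCOVAs on log MO2/lactate with
MO2 standardization and a gene–MO2 Pearson screen; and a synthetic-data
generator with planted ground truth for recovery testing. See the methods
vignette (`vignettes/frontloading-methods.Rmd`) for models, defaults and
assumptions.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data; each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # 2,000 genes x 20 samples + physiology
Rscript analysis/02_differential_expression.R
Rscript analysis/03_frontloading.R
Rscript analysis/04_ordination.R
Rscript analysis/05_physiology.R
Rscript analysis/06_report.R            # end-to-end pipeline + summary JSON
```

`analysis/03_frontloading.R` prints, for the default seed:

```
up   n=217: frontloaded 183 (84.3%), stress-indicator 34, greater-FC 0 | X2(1)=217.00 p=4.08e-49
down n=272: frontloaded 240 (88.2%), stress-indicator 30, greater-FC 2 | X2(1)=264.06 p=2.24e-59
Overlap (significant in both hypoxia contrasts): 68 genes
Recovery: 100.0% of planted frontloaded genes in the cold-only set classified frontloaded;
          0.9% of frontloaded calls are planted nulls.
```

Reading: 217 genes were upregulated by hypoxia in the cold-acclimated group
only; all sat on the reduced-reaction side of the line of equality (hence
X² equals n), and 84.3% of them were frontloaded — warm acclimation had
raised their baselines. Every planted frontloaded gene reaching the
cold-only set was recovered, with under 1% null contamination. The same
classification is available programmatically:

```r
library(frontloadr)
cm  <- filter_low_counts(read_counts("counts.tsv", "metadata.csv"))
vb  <- remove_batch_effect(vst(cm))
fr  <- classify_frontloading(nb_wald_test(cm, c("10HY", "10NO")),
                             nb_wald_test(cm, c("20HY", "20NO")), vb)
summarize_frontloading(fr)
```

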