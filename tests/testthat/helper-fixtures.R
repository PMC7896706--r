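# small in-code fixtures shared across test files

toy_meta <- function(sample_ids, treatment, batch = NULL) {
  data.frame(sample_id = sample_ids,
             treatment = treatment,
             temperature = as.integer(substr(treatment, 1, 2)),
             oxygen = substr(treatment, 3, 4),
             batch = if (is.null(batch)) "b1" else batch,
             stringsAsFactors = FALSE)
}

toy_cm <- function(counts, treatment, batch = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  count_matrix(counts, toy_meta(colnames(counts), treatment, batch))
}

toy_vst <- function(values, treatment, batch = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  structure(list(values = values,
                 meta = toy_meta(colnames(values), treatment, batch),
                 size_factors = rep(1, ncol(values)),
                 batch_corrected = TRUE),
            class = "vst_matrix")
}

# DE table stub with the columns the frontloading stage consumes
toy_de <- function(gene_id, log2fc, padj, contrast = "x_vs_y") {
  data.frame(gene_id = gene_id, base_mean = 100, log2fc = log2fc,
             se_log2fc = 0.1, p = padj, padj = padj, contrast = contrast,
             stringsAsFactors = FALSE)
}

# all-null simulator configuration (no planted effects)
null_sim_config <- function(n_genes, seed, dispersion = 0.1, ...) {
  sim_config(n_genes = n_genes,
             archetype_fractions = c(frontloaded_up = 0,
                                     frontloaded_down = 0,
                                     stress_indicator_up = 0,
                                     stress_indicator_down = 0,
                                     greater_fc = 0, null = 1),
             const_shift_log2 = 0, dispersion = dispersion,
             seed = seed, ...)
}
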