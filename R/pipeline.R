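#' Pipeline configuration
#'
#' @param counts_path,meta_path paths to the counts TSV and metadata CSV.
#' @param physio_path optional physiology CSV.
#' @param out_dir output directory for tables and the summary JSON.
#' @param alpha_de adjusted-p threshold for DEG calling (default 0.05).
#' @param alpha_corr p threshold for gene-MO2 correlations (default 0.01).
#' @param low_count_threshold row-sum filter threshold (default 5).
#' @param contrasts named list of treatment pairs; defaults to the
#'   constitutive (20NO vs 10NO), cold-hypoxia (10HY vs 10NO) and
#'   warm-hypoxia (20HY vs 20NO) comparisons.
#' @param outlier_k_sd robust-SD multiplier for PC1 outlier flagging.
#' @param drop_outliers drop flagged samples before the DE stage?
#' @param seed integer seed recorded in the report.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path, meta_path, physio_path = NULL,
                            out_dir = NULL,
                            alpha_de = 0.05, alpha_corr = 0.01,
                            low_count_threshold = 5,
                            contrasts = list(
                              constitutive = c("20NO", "10NO"),
                              cold_hypoxia = c("10HY", "10NO"),
                              warm_hypoxia = c("20HY", "20NO")),
                            outlier_k_sd = 3,
                            drop_outliers = FALSE,
                            seed = 1L) {
  stopifnot(alpha_de > 0, alpha_de < 1, alpha_corr > 0, alpha_corr < 1,
            low_count_threshold >= 0)
  for (ct in contrasts) {
    bad <- setdiff(ct, TREATMENTS)
    if (length(bad))
      stop("contrast references unknown treatment label(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(counts_path = counts_path, meta_path = meta_path,
                 physio_path = physio_path, out_dir = out_dir,
                 alpha_de = alpha_de, alpha_corr = alpha_corr,
                 low_count_threshold = low_count_threshold,
                 contrasts = contrasts, outlier_k_sd = outlier_k_sd,
                 drop_outliers = drop_outliers, seed = as.integer(seed)),
            class = "pipeline_config")
}

drop_samples <- function(cm, ids) {
  keep <- !(cm$sample_ids %in% ids)
  count_matrix(cm$counts[, keep, drop = FALSE],
               cm$meta[keep, , drop = FALSE])
}

#' Run the full cross-tolerance analysis pipeline
#'
#' Stage order: low-count filter, normalization, VST, batch correction, PCA
#' with advisory PC1 outlier flagging (optionally dropping flags and
#' refitting), NB Wald tests for the three treatment contrasts,
#' frontloading classification with the line-of-equality chi-squared, ANOVA
#' with Tukey HSD on PC1 scores and, when physiology data are supplied, the
#' log-scale mass-covariate ANCOVAs, MO2 standardization and gene-MO2
#' correlation screen. All applied thresholds are echoed into the report's
#' `settings` block. Deterministic end to end for fixed inputs and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return a report list; when `cfg$out_dir` is set, tables (TSV) and
#'   `summary.json` are also written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cm <- stage("read", read_counts(cfg$counts_path, cfg$meta_path))
  cm <- stage("filter", filter_low_counts(cm, cfg$low_count_threshold))
  v <- stage("vst", vst(cm))
  vb <- stage("batch_correct", remove_batch_effect(v))
  pc <- stage("pca", pca(vb))
  flags <- stage("flag_outliers", flag_outliers(pc, cfg$outlier_k_sd))
  if (cfg$drop_outliers && nrow(flags) > 0) {
    cm <- stage("drop_outliers", drop_samples(cm, flags$sample_id))
    v <- stage("vst", vst(cm))
    vb <- stage("batch_correct", remove_batch_effect(v))
    pc <- stage("pca", pca(vb))
  }
  de <- stage("de", lapply(cfg$contrasts, function(ct)
    nb_wald_test(cm, ct)))
  degs <- lapply(de, call_degs, alpha = cfg$alpha_de)

  front <- stage("frontload",
                 classify_frontloading(de$cold_hypoxia, de$warm_hypoxia,
                                       vb, alpha = cfg$alpha_de))
  n_cold <- length(degs$cold_hypoxia$up) + length(degs$cold_hypoxia$down)
  n_warm <- length(degs$warm_hypoxia$up) + length(degs$warm_hypoxia$down)
  front_summary <- summarize_frontloading(front, n_cold_degs = n_cold,
                                          n_warm_degs = n_warm)

  pc1_anova <- stage("anova_scores", anova_scores(pc$scores[, 1], pc$meta))

  physio_block <- NULL
  if (!is.null(cfg$physio_path)) {
    physio <- stage("physio_read",
                    utils::read.csv(cfg$physio_path,
                                    stringsAsFactors = FALSE))
    anc_mo2 <- stage("ancova_mo2", physio_ancova(physio, "mo2"))
    anc_lac <- stage("ancova_lactate", physio_ancova(physio, "lactate"))
    std <- stage("standardize_mo2", standardize_mo2(physio))
    corr <- NULL
    shared <- intersect(colnames(vb$values), std$individual_id)
    if (length(shared) >= 4) {
      smo2 <- stats::setNames(std$std_mo2, std$individual_id)
      corr <- stage("correlate",
                    correlate_genes_mo2(vb, smo2, cfg$alpha_corr))
    }
    physio_block <- list(
      ancova_mo2 = anc_mo2$anova, ancova_lactate = anc_lac$anova,
      tukey_mo2 = anc_mo2$tukey,
      std_mo2 = stats::setNames(std$std_mo2, std$individual_id),
      correlation = corr,
      n_corr_significant = if (!is.null(corr)) sum(corr$significant)
        else NA_integer_)
  }

  deg_counts <- lapply(degs, function(d)
    list(up = length(d$up), down = length(d$down),
         total = length(d$up) + length(d$down)))

  report <- list(
    settings = list(alpha_de = cfg$alpha_de, alpha_corr = cfg$alpha_corr,
                    low_count_threshold = cfg$low_count_threshold,
                    outlier_k_sd = cfg$outlier_k_sd,
                    drop_outliers = cfg$drop_outliers,
                    dispersion_floor = 1e-8,
                    dispersion_shrink_weight = 0.5,
                    padj_method = "BH",
                    independent_filtering = FALSE,
                    vst = "shifted-log log2(count/sf + 1)",
                    constitutive_statistic = "mean",
                    seed = cfg$seed,
                    contrasts = lapply(cfg$contrasts, paste,
                                       collapse = "_vs_")),
    n_genes_tested = length(cm$gene_ids),
    n_samples = length(cm$sample_ids),
    deg_counts = deg_counts,
    outlier_flags = flags$sample_id,
    pca = list(explained_variance_pct = pc$explained_variance_pct,
               pc1_anova = pc1_anova$anova,
               pc1_letters = as.list(pc1_anova$letters)),
    frontloading = front_summary,
    overlap = attr(front, "overlap")["total"],
    physiology = physio_block)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(de))
      utils::write.table(de[[nm]],
                         file.path(cfg$out_dir, paste0("de_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(front,
                       file.path(cfg$out_dir, "frontload_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = rownames(pc$scores),
                                  pc$scores, check.names = FALSE),
                       file.path(cfg$out_dir, "pca_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  report$tables <- list(de = de, frontload = front, pca = pc)
  invisible(report)
}

#' Write a self-contained synthetic fixture dataset
#'
#' `tiny` writes 500 genes over 18 samples (10NO and 10HY reduced to 4
#' replicates, mirroring a post-outlier-removal 4/4/5/5 design);
#' `paper_like` writes 20,000 genes over 20 samples.
#'
#' @param out_dir writable directory.
#' @param scale `"tiny"` or `"paper_like"`.
#' @param seed integer seed.
#' @return invisibly, named file paths (counts, meta, truth, physio).
#' @export
make_fixture <- function(out_dir, scale = c("tiny", "paper_like"),
                         seed = 1L) {
  scale <- match.arg(scale)
  n_genes <- if (scale == "tiny") 500 else 20000
  cfg <- sim_config(n_genes = n_genes, n_reps_per_treatment = 5,
                    seed = seed)
  sim <- simulate_counts(cfg)
  if (scale == "tiny") {
    drop <- c("10NO_r5", "10HY_r5")
    sim$counts <- drop_samples(sim$counts, drop)
  }
  physio <- simulate_physiology(physio_sim_config(seed = seed))
  write_sim_dataset(sim, physio, out_dir)
}
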