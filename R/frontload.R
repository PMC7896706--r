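#' Extract DEGs unique to the cold-acclimated hypoxia response
#'
#' Selects genes significantly affected by hypoxia in the cold-acclimated
#' contrast (`padj_cold < alpha`) but not in the warm-acclimated contrast
#' (`padj_warm >= alpha`, or missing — genes dropped from the warm test
#' count as not significantly affected). Genes significant in both contrasts
#' are excluded and reported as overlap.
#'
#' @param cold DE table for the 10HY vs 10NO contrast.
#' @param warm DE table for the 20HY vs 20NO contrast (same gene universe).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list: `up`, `down` (cold-only gene IDs split by the sign of the
#'   cold log2FC), `overlap` (list up/down/total of genes significant in
#'   both contrasts, split by cold-contrast direction).
#' @export
cold_only_degs <- function(cold, warm, alpha = 0.05) {
  stopifnot(is.data.frame(cold), is.data.frame(warm))
  if (!setequal(cold$gene_id, warm$gene_id))
    stop("cold and warm tables must cover the same gene universe")
  warm <- warm[match(cold$gene_id, warm$gene_id), ]
  sig_cold <- !is.na(cold$padj) & cold$padj < alpha
  sig_warm <- !is.na(warm$padj) & warm$padj < alpha
  only <- sig_cold & !sig_warm
  both <- sig_cold & sig_warm
  up <- cold$log2fc > 0
  list(up = cold$gene_id[only & up],
       down = cold$gene_id[only & !up],
       overlap = list(up = cold$gene_id[both & up],
                      down = cold$gene_id[both & !up],
                      total = sum(both)))
}

#' Raw fold change from a log2 fold change
#'
#' Fold upregulation is `2^log2fc`; fold downregulation is `1 / 2^log2fc`,
#' so a gene's raw fold change is > 1 in its own direction of regulation.
#'
#' @param log2fc finite log2 fold change(s).
#' @param direction `"up"` or `"down"` (recycled).
#' @return positive raw fold change(s).
#' @export
raw_fold_change <- function(log2fc, direction) {
  stopifnot(all(is.finite(log2fc)), all(direction %in% c("up", "down")))
  ifelse(direction == "up", 2^log2fc, 2^(-log2fc))
}

#' Classify cold-only hypoxia DEGs into frontloading categories
#'
#' For every gene unique to the cold-acclimated hypoxia response, computes
#' the reaction ratio (warm raw fold change over cold raw fold change, both
#' taken in the gene's cold direction of regulation) and the constitutive
#' expression means (batch-corrected VST values averaged over 20NO and 10NO
#' replicates), then applies the decision table:
#' \itemize{
#'   \item ratio > 1: `greater_fc` (greater reaction in the warm group);
#'   \item ratio < 1 and constitutive expression shifted in the direction of
#'     regulation (20NO mean > 10NO mean for up-genes, < for down-genes):
#'     `frontloaded`;
#'   \item ratio < 1 with the opposite constitutive inequality:
#'     `stress_indicator`;
#'   \item exact ties (ratio = 1 or equal means): `ambiguous`.
#' }
#'
#' @param cold,warm DE tables for 10HY vs 10NO and 20HY vs 20NO.
#' @param vst_bc batch-corrected `vst_matrix`.
#' @param alpha adjusted-p threshold for the cold-only selection.
#' @param const_stat `"mean"` (default) or `"median"` summary of the
#'   constitutive VST values.
#' @return data.frame of class `frontload_table`, one row per cold-only DEG:
#'   gene_id, direction, log2fc_cold, log2fc_warm, raw_fc_cold, raw_fc_warm,
#'   reaction_ratio, const_mean_10NO, const_mean_20NO, category; the
#'   cold-only overlap report is attached as attribute `"overlap"`.
#' @export
classify_frontloading <- function(cold, warm, vst_bc, alpha = 0.05,
                                  const_stat = c("mean", "median")) {
  const_stat <- match.arg(const_stat)
  stopifnot(inherits(vst_bc, "vst_matrix"))
  sel <- cold_only_degs(cold, warm, alpha)
  genes <- c(sel$up, sel$down)
  direction <- rep(c("up", "down"), c(length(sel$up), length(sel$down)))
  if (!all(genes %in% rownames(vst_bc$values)))
    stop("VST values missing for ",
         sum(!genes %in% rownames(vst_bc$values)), " classified gene(s)")

  warm <- warm[match(cold$gene_id, warm$gene_id), ]
  idx <- match(genes, cold$gene_id)
  l2_cold <- cold$log2fc[idx]
  l2_warm <- warm$log2fc[idx]

  summ <- if (const_stat == "mean") rowMeans else
    function(m) apply(m, 1, stats::median)
  cols_10 <- vst_bc$meta$treatment == "10NO"
  cols_20 <- vst_bc$meta$treatment == "20NO"
  if (!any(cols_10) || !any(cols_20))
    stop("VST matrix must contain 10NO and 20NO samples")
  vsub <- vst_bc$values[genes, , drop = FALSE]
  c10 <- summ(vsub[, cols_10, drop = FALSE])
  c20 <- summ(vsub[, cols_20, drop = FALSE])

  fc_cold <- raw_fold_change(l2_cold, direction)
  fc_warm <- raw_fold_change(l2_warm, direction)
  ratio <- fc_warm / fc_cold

  const_up <- c20 > c10
  const_dn <- c20 < c10
  category <- rep("ambiguous", length(genes))
  category[ratio > 1] <- "greater_fc"
  front <- ratio < 1 & ((direction == "up" & const_up) |
                          (direction == "down" & const_dn))
  stress <- ratio < 1 & ((direction == "up" & const_dn) |
                           (direction == "down" & const_up))
  category[front] <- "frontloaded"
  category[stress] <- "stress_indicator"

  out <- data.frame(gene_id = genes, direction = direction,
                    log2fc_cold = l2_cold, log2fc_warm = l2_warm,
                    raw_fc_cold = fc_cold, raw_fc_warm = fc_warm,
                    reaction_ratio = ratio,
                    const_mean_10NO = unname(c10),
                    const_mean_20NO = unname(c20),
                    category = category, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "overlap") <- sel$overlap
  class(out) <- c("frontload_table", "data.frame")
  out
}

#' Chi-squared test against a 50:50 split around the line of equality
#'
#' Pearson chi-squared (df = 1, no continuity correction) comparing the
#' observed reduced-reaction / greater-reaction split with equal expected
#' counts; algebraically `X2 = (a - b)^2 / (a + b)`.
#'
#' @param n_reduced number of reduced-reaction genes (ratio < 1).
#' @param n_greater number of greater-reaction genes (ratio > 1).
#' @return list with `statistic`, `df` (= 1) and `p` (upper tail).
#' @export
chisq_line_of_equality <- function(n_reduced, n_greater) {
  stopifnot(length(n_reduced) == 1, length(n_greater) == 1,
            n_reduced >= 0, n_greater >= 0)
  n <- n_reduced + n_greater
  if (n < 1) stop("at least one gene required")
  expected <- n / 2
  x2 <- (n_reduced - expected)^2 / expected +
    (n_greater - expected)^2 / expected
  list(statistic = x2, df = 1L,
       p = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Summarize a frontloading classification
#'
#' Category counts and percentages per direction (to 1 decimal place), the
#' line-of-equality chi-squared per direction, and the percent reduction in
#' DEG totals between acclimation groups when those totals are supplied.
#'
#' @param records a `frontload_table`.
#' @param n_cold_degs,n_warm_degs optional total DEG counts for the cold
#'   (10HY vs 10NO) and warm (20HY vs 20NO) contrasts, used for the
#'   reduction percentage `100 (1 - n_warm / n_cold)`.
#' @return nested list: per-direction counts, percentages and chi-squared;
#'   overall totals; `reduction_pct` when computable.
#' @export
summarize_frontloading <- function(records, n_cold_degs = NULL,
                                   n_warm_degs = NULL) {
  stopifnot(is.data.frame(records))
  cats <- c("frontloaded", "stress_indicator", "greater_fc", "ambiguous")
  per_dir <- lapply(c(up = "up", down = "down"), function(d) {
    sub <- records[records$direction == d, , drop = FALSE]
    n <- nrow(sub)
    counts <- vapply(cats, function(k) sum(sub$category == k), integer(1))
    pct <- if (n > 0) round(100 * counts / n, 1) else
      stats::setNames(rep(NA_real_, length(cats)), cats)
    n_red <- sum(sub$reaction_ratio < 1)
    n_gre <- sum(sub$reaction_ratio > 1)
    chisq <- if (n_red + n_gre >= 1)
      chisq_line_of_equality(n_red, n_gre) else NULL
    list(n = n, counts = as.list(counts), pct = as.list(pct),
         n_reduced = n_red, n_greater = n_gre, chisq = chisq)
  })
  out <- list(up = per_dir$up, down = per_dir$down,
              n_total = nrow(records))
  if (!is.null(n_cold_degs) && !is.null(n_warm_degs)) {
    if (n_cold_degs > 0)
      out$reduction_pct <- round(100 * (1 - n_warm_degs / n_cold_degs), 1)
    else out$reduction_pct <- NA_real_
    out$n_cold_degs <- n_cold_degs
    out$n_warm_degs <- n_warm_degs
  }
  out
}
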