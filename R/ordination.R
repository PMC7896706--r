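#' PCA of a (batch-corrected) VST matrix
#'
#' Covariance PCA of samples: genes are centred but not scaled, components
#' are ordered by explained variance, and each component's sign is fixed so
#' that the gene with the largest absolute loading has a positive loading.
#'
#' @param v a `vst_matrix`.
#' @param n_components number of components to keep (default
#'   `min(genes, samples - 1)`).
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `loadings` (genes x components), `explained_variance_pct`, `centering`
#'   (per-gene means), `meta`.
#' @export
pca <- function(v, n_components = NULL) {
  stopifnot(inherits(v, "vst_matrix"))
  x <- t(v$values)                       # samples x genes
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  max_comp <- min(ncol(x), nrow(x) - 1L)
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp)
    stop("n_components exceeds min(genes, samples - 1)")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  # total variance over all components, not just those kept
  ev_pct <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_pct = ev_pct[seq_len(k)],
                 all_variances = fit$sdev^2,
                 centering = fit$center, meta = v$meta),
            class = "pca_result")
}

#' Genes contributing most to a principal component
#'
#' @param p a `pca_result`.
#' @param component component index.
#' @param k number of genes to return (default 100); if `k` exceeds the
#'   gene count, all genes are returned with a warning.
#' @return character vector of gene IDs ranked by |loading| descending,
#'   ties broken lexicographically by gene ID.
#' @export
top_loading_genes <- function(p, component = 1, k = 100) {
  stopifnot(inherits(p, "pca_result"))
  if (component > ncol(p$loadings)) stop("component not available")
  ld <- p$loadings[, component]
  if (k > length(ld)) {
    warning("k exceeds gene count; returning all genes")
    k <- length(ld)
  }
  ord <- order(-abs(ld), names(ld))
  names(ld)[ord][seq_len(k)]
}

# compact-letter display by insert-absorb over a pairwise "different" matrix
letter_groups <- function(group_names, diff_pairs) {
  g <- length(group_names)
  same <- matrix(TRUE, g, g, dimnames = list(group_names, group_names))
  for (i in seq_len(nrow(diff_pairs))) {
    a <- diff_pairs$a[i]; b <- diff_pairs$b[i]
    if (diff_pairs$different[i]) same[a, b] <- same[b, a] <- FALSE
  }
  sets <- list()
  for (i in seq_len(g)) {
    members <- group_names[same[i, ]]
    # grow a maximal clique of mutually non-different groups containing i
    clique <- group_names[i]
    for (m in members) {
      if (m == group_names[i]) next
      if (all(same[m, clique])) clique <- c(clique, m)
    }
    clique <- sort(clique)
    if (!any(vapply(sets, function(s) setequal(s, clique) ||
                      all(clique %in% s), logical(1))))
      sets <- c(sets, list(clique))
  }
  sets <- sets[!duplicated(lapply(sets, paste, collapse = "|"))]
  letters_out <- stats::setNames(rep("", g), group_names)
  for (j in seq_along(sets))
    for (m in sets[[j]])
      letters_out[m] <- paste0(letters_out[m], letters[j])
  letters_out
}

#' Two-way ANOVA with Tukey HSD on principal-component scores
#'
#' Full-factorial ANOVA of one component's scores on acclimation temperature
#' and oxygen, plus Tukey HSD over the four treatment cells with a
#' compact-letter grouping at family-wise alpha = 0.05.
#'
#' @param scores numeric vector of scores for one component.
#' @param meta sample metadata aligned with `scores` (temperature, oxygen,
#'   treatment).
#' @return list: `anova` (data.frame term/df/F/p), `tukey` (pairwise
#'   data.frame), `letters` (named letter grouping per treatment).
#' @export
anova_scores <- function(scores, meta) {
  stopifnot(length(scores) == nrow(meta))
  d <- data.frame(score = scores,
                  temperature = factor(meta$temperature),
                  oxygen = factor(meta$oxygen),
                  treatment = factor(meta$treatment))
  cell_n <- table(d$temperature, d$oxygen)
  if (any(cell_n < 2)) stop("each factorial cell needs >= 2 replicates")
  fit <- stats::aov(score ~ temperature * oxygen, data = d)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  keep <- terms != "Residuals"
  anova_tab <- data.frame(term = terms[keep], df = s$Df[keep],
                          F = s$`F value`[keep], p = s$`Pr(>F)`[keep],
                          stringsAsFactors = FALSE)
  tuk_fit <- stats::aov(score ~ treatment, data = d)
  tk <- stats::TukeyHSD(tuk_fit, conf.level = 0.95)$treatment
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  tukey <- data.frame(a = pairs[, 1], b = pairs[, 2],
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  tukey$different <- tukey$p_adj < 0.05
  list(anova = anova_tab, tukey = tukey,
       letters = letter_groups(levels(d$treatment), tukey))
}

#' Flag outlier samples along PC1
#'
#' Rule-based surrogate for visual outlier screening: a sample is flagged
#' when its PC1 score deviates from its treatment-group median by strictly
#' more than `k_sd` robust SDs (MAD with the normal consistency constant).
#' Flags are advisory; removal is the caller's choice.
#'
#' @param p a `pca_result`.
#' @param k_sd robust-SD multiplier (default 3).
#' @return data.frame of flagged samples (sample_id, treatment, pc1,
#'   group_median, deviation_mads); zero rows when no sample is flagged.
#' @export
flag_outliers <- function(p, k_sd = 3) {
  stopifnot(inherits(p, "pca_result"))
  meta <- p$meta
  tab <- table(meta$treatment)
  if (any(tab < 3)) stop("each treatment needs >= 3 samples for flagging")
  pc1 <- p$scores[, 1]
  out <- lapply(names(tab), function(tr) {
    idx <- which(meta$treatment == tr)
    med <- stats::median(pc1[idx])
    s <- stats::mad(pc1[idx])
    dev <- abs(pc1[idx] - med)
    dm <- if (s > 0) dev / s else ifelse(dev > 0, Inf, 0)
    flagged <- dm > k_sd
    data.frame(sample_id = meta$sample_id[idx][flagged],
               treatment = rep(tr, sum(flagged)),
               pc1 = pc1[idx][flagged],
               group_median = rep(med, sum(flagged)),
               deviation_mads = dm[flagged],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
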