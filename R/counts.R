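#' Construct a validated count matrix with aligned sample metadata
#'
#' @param counts non-negative integer matrix, genes x samples; dimnames
#'   supply gene and sample IDs.
#' @param meta data.frame with one row per sample column: `sample_id`,
#'   `treatment` (one of 10NO/10HY/20NO/20HY), `temperature`, `oxygen`,
#'   `batch`. Missing temperature/oxygen columns are derived from the
#'   treatment code.
#' @return list of class `count_matrix`: gene_ids, sample_ids, counts, meta.
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene (row) and sample (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample IDs")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("metadata needs a sample_id column")
  missing_meta <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing_meta))
    stop("metadata missing sample(s): ", paste(missing_meta, collapse = ", "))
  extra <- setdiff(meta$sample_id, colnames(counts))
  if (length(extra))
    stop("metadata has sample(s) absent from counts: ",
         paste(extra, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  if (!"treatment" %in% names(meta)) stop("metadata needs a treatment column")
  bad <- setdiff(unique(meta$treatment), TREATMENTS)
  if (length(bad))
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "))
  if (!"temperature" %in% names(meta))
    meta$temperature <- as.integer(substr(meta$treatment, 1, 2))
  if (!"oxygen" %in% names(meta))
    meta$oxygen <- substr(meta$treatment, 3, 4)
  if (!"batch" %in% names(meta)) meta$batch <- "b1"
  meta$batch <- as.character(meta$batch)
  rownames(meta) <- NULL
  structure(list(gene_ids = rownames(counts),
                 sample_ids = colnames(counts),
                 counts = counts, meta = meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  cat("treatments:", paste(table(x$meta$treatment), collapse = "/"),
      " batches:", length(unique(x$meta$batch)), "\n")
  invisible(x)
}

#' Read a count matrix and sample metadata from disk
#'
#' @param counts_path TSV with gene IDs in the first column and one column
#'   per sample.
#' @param meta_path CSV with sample_id, treatment, and optionally
#'   temperature, oxygen, batch.
#' @return a `count_matrix`.
#' @export
read_counts <- function(counts_path, meta_path) {
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  if (!is.numeric(counts)) stop("counts file contains non-numeric entries")
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

#' Remove genes with low total counts
#'
#' Drops genes whose total count summed across all samples falls below
#' `threshold`; survivor order is preserved.
#'
#' @param cm a `count_matrix`.
#' @param threshold minimum row sum to retain (default 5).
#' @return filtered `count_matrix`.
#' @export
filter_low_counts <- function(cm, threshold = 5) {
  stopifnot(inherits(cm, "count_matrix"), threshold >= 0)
  keep <- rowSums(cm$counts) >= threshold
  count_matrix(cm$counts[keep, , drop = FALSE], cm$meta)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: each sample's median ratio of counts to the
#' per-gene geometric mean, computed over genes expressed in every sample.
#'
#' @param cm a `count_matrix`.
#' @return named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) stop("no gene has nonzero counts in all samples")
  logc <- log(counts[all_pos, , drop = FALSE])
  geo <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(stats::median(col - geo)))
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  sf
}

#' Shifted-log variance-stabilizing transform
#'
#' `value = log2(count / size_factor + 1)`: a monotone, depth-normalized
#' transform that tempers the count-level mean-variance relationship for the
#' downstream rank and mean comparisons.
#'
#' @param cm a `count_matrix`.
#' @return list of class `vst_matrix`: values (genes x samples), meta,
#'   size_factors, batch_corrected flag.
#' @export
vst <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  sf <- size_factors(cm)
  values <- log2(sweep(cm$counts, 2, sf, "/") + 1)
  structure(list(values = values, meta = cm$meta, size_factors = sf,
                 batch_corrected = FALSE),
            class = "vst_matrix")
}

#' Remove an additive batch effect from a VST matrix
#'
#' Fits, per gene, least squares `value ~ treatment + batch` and subtracts
#' the fitted batch component while retaining treatment effects
#' (via [limma::removeBatchEffect]); rows are then re-centred to their
#' original means so the per-gene grand mean is preserved exactly.
#' A single batch is an identity operation.
#'
#' @param v a `vst_matrix`.
#' @return a `vst_matrix` with `batch_corrected = TRUE`.
#' @export
remove_batch_effect <- function(v) {
  stopifnot(inherits(v, "vst_matrix"))
  batch <- factor(v$meta$batch)
  out <- v
  if (nlevels(batch) < 2) {
    out$batch_corrected <- TRUE
    return(out)
  }
  treatment <- factor(v$meta$treatment)
  if (nlevels(treatment) > 1) {
    tab <- table(treatment, batch)
    if (all(rowSums(tab > 0) == 1))
      stop("batch is confounded with treatment; cannot correct")
    design <- stats::model.matrix(~treatment)
  } else design <- matrix(1, ncol(v$values), 1)
  corrected <- limma::removeBatchEffect(v$values, batch = batch,
                                        design = design)
  corrected <- corrected - rowMeans(corrected) + rowMeans(v$values)
  out$values <- corrected
  out$batch_corrected <- TRUE
  out
}

# method-of-moments NB dispersion per gene, pooled within treatment groups,
# shrunk half-way toward a 1/mu + const mean-dispersion trend
estimate_dispersions <- function(norm_counts, group, floor = 1e-8,
                                 shrink_weight = 0.5) {
  group <- factor(group)
  n <- ncol(norm_counts)
  k <- nlevels(group)
  mu <- rowMeans(norm_counts)
  ss <- 0
  for (g in levels(group)) {
    cols <- which(group == g)
    if (length(cols) < 2) next
    gm <- rowMeans(norm_counts[, cols, drop = FALSE])
    ss <- ss + rowSums((norm_counts[, cols, drop = FALSE] - gm)^2)
  }
  v <- ss / max(n - k, 1)
  alpha_mom <- pmax((v - mu) / mu^2, floor)
  alpha_mom[!is.finite(alpha_mom)] <- floor
  # parametric trend alpha(mu) = a0 + a1/mu on informative genes
  ok <- is.finite(mu) & mu > 0 & alpha_mom > floor
  if (sum(ok) >= 10) {
    fit <- stats::lm(alpha_mom[ok] ~ I(1 / mu[ok]))
    a0 <- max(stats::coef(fit)[1], floor)
    a1 <- max(stats::coef(fit)[2], 0)
  } else {
    a0 <- max(stats::median(alpha_mom), floor)
    a1 <- 0
  }
  trend <- a0 + a1 / pmax(mu, 1e-8)
  pmax((1 - shrink_weight) * alpha_mom + shrink_weight * trend, floor)
}

#' Negative-binomial Wald test for a pairwise treatment contrast
#'
#' Documented stand-in for the conventional NB differential-expression
#' workflow: a per-gene NB log-link GLM with batch and treatment covariates
#' fitted on all samples, method-of-moments dispersion (floored at 1e-8)
#' shrunk half-way toward a fitted `a0 + a1/mu` mean-dispersion trend, and a
#' Wald z test on the contrast coefficient. Reported log2 fold changes are
#' unshrunk maximum-likelihood estimates with the sign convention
#' first-named over second (positive = higher in `contrast[1]`).
#'
#' @param cm a `count_matrix` (usually after [filter_low_counts()]).
#' @param contrast character pair `(treatmentA, treatmentB)`.
#' @param alpha_bh unused here; see [call_degs()].
#' @return data.frame of class `de_result`: gene_id, base_mean, log2fc,
#'   se_log2fc, p, padj, contrast. `padj` is BH across all tested genes.
#' @export
nb_wald_test <- function(cm, contrast) {
  stopifnot(inherits(cm, "count_matrix"), length(contrast) == 2)
  bad <- setdiff(contrast, unique(cm$meta$treatment))
  if (length(bad))
    stop("contrast names unknown treatment(s): ", paste(bad, collapse = ", "))
  if (contrast[1] == contrast[2]) stop("degenerate contrast")
  for (tr in contrast)
    if (sum(cm$meta$treatment == tr) < 2)
      stop("treatment ", tr, " has fewer than 2 replicates")

  sf <- size_factors(cm)
  norm <- sweep(cm$counts, 2, sf, "/")
  base_mean <- rowMeans(norm)

  treatment <- stats::relevel(factor(cm$meta$treatment), ref = contrast[2])
  batch <- factor(cm$meta$batch)
  if (nlevels(batch) > 1) {
    design <- stats::model.matrix(~batch + treatment)
  } else {
    design <- stats::model.matrix(~treatment)
  }
  coef_name <- paste0("treatment", contrast[1])
  ci <- match(coef_name, colnames(design))
  if (is.na(ci)) stop("contrast coefficient not found in design")

  alpha <- estimate_dispersions(norm, cm$meta$treatment)
  off <- log(sf)
  p_idx <- seq_len(ncol(design))

  n_genes <- nrow(cm$counts)
  log2fc <- se <- pval <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    y <- cm$counts[g, ]
    if (all(y == 0)) {
      log2fc[g] <- 0; se[g] <- NA_real_; pval[g] <- 1
      next
    }
    fam <- MASS::negative.binomial(theta = 1 / alpha[g])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(design, y, family = fam,
                                      offset = off)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$rank < ncol(design)) {
      log2fc[g] <- 0; se[g] <- NA_real_; pval[g] <- 1
      next
    }
    beta <- fit$coefficients[ci]
    rmat <- fit$qr$qr[p_idx, p_idx, drop = FALSE]
    rmat[lower.tri(rmat)] <- 0
    cov <- tryCatch(chol2inv(rmat), error = function(e) NULL)
    if (is.null(cov) || !is.finite(cov[ci, ci]) || cov[ci, ci] <= 0) {
      log2fc[g] <- beta / log(2); se[g] <- NA_real_; pval[g] <- 1
      next
    }
    sei <- sqrt(cov[ci, ci])
    z <- beta / sei
    log2fc[g] <- beta / log(2)
    se[g] <- sei / log(2)
    pval[g] <- 2 * stats::pnorm(-abs(z))
  }
  res <- data.frame(gene_id = cm$gene_ids, base_mean = base_mean,
                    log2fc = log2fc, se_log2fc = se, p = pval,
                    padj = bh_adjust(pval),
                    contrast = paste(contrast, collapse = "_vs_"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes from a DE result table
#'
#' Genes with `padj < alpha` (strict), partitioned by the sign of log2fc.
#'
#' @param de a `de_result` data.frame.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list with character vectors `up`, `down`.
#' @export
call_degs <- function(de, alpha = 0.05) {
  stopifnot(is.data.frame(de), all(c("gene_id", "log2fc", "padj") %in%
                                     names(de)))
  sig <- !is.na(de$padj) & de$padj < alpha
  list(up = de$gene_id[sig & de$log2fc > 0],
       down = de$gene_id[sig & de$log2fc < 0])
}
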