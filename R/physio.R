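#' Oxygen uptake rate from a closed-chamber respirometry trace
#'
#' Standard closed-respirometry slope formulation: after discarding an
#' initial handling-stress window, MO2 is minus the least-squares slope of
#' PO2 (percent air saturation) against time, scaled by the oxygen
#' solubility coefficient and the chamber volume. Negative computed rates
#' are floored at zero with a warning.
#'
#' @param times increasing times in minutes.
#' @param po2 percent air saturation at each time.
#' @param chamber_volume_ml chamber volume (ml).
#' @param solubility_coefficient O2 amount per ml per percent a.s.
#' @param discard_initial_min initial window to drop (default 30 min).
#' @return MO2 (amount O2 per minute).
#' @export
mo2_from_trace <- function(times, po2, chamber_volume_ml,
                           solubility_coefficient,
                           discard_initial_min = 30) {
  stopifnot(length(times) == length(po2), chamber_volume_ml > 0,
            solubility_coefficient > 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  keep <- times >= discard_initial_min
  if (sum(keep) < 2)
    stop("fewer than 2 points remain after the discard window")
  slope <- stats::coef(stats::lm(po2[keep] ~ times[keep]))[2]
  mo2 <- -slope * solubility_coefficient * chamber_volume_ml
  if (mo2 < 0) {
    warning("negative computed MO2 floored at 0")
    mo2 <- 0
  }
  unname(mo2)
}

#' Two-way ANCOVA on log-transformed physiology responses
#'
#' Fits `log(response) ~ temperature * oxygen + mass` on natural-log
#' responses, reports Type-II F tests for the main effects and the mass
#' covariate with the interaction tested in the full model, and Tukey
#' pairwise comparisons of the four treatment cells at covariate-adjusted
#' means (evaluated at the grand-mean mass). Non-positive responses are
#' excluded with a warning.
#'
#' @param physio data.frame with columns treatment, temperature, oxygen,
#'   wet_mass and the response.
#' @param response `"mo2"` or `"lactate"`.
#' @return list: `anova` (term/df/F/p), `tukey` (adjusted-mean pairwise
#'   comparisons), `letters`, `model` (the underlying lm).
#' @export
physio_ancova <- function(physio, response = c("mo2", "lactate")) {
  response <- match.arg(response)
  y <- physio[[response]]
  bad <- !is.finite(y) | y <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive/missing ", response,
            " value(s) excluded")
    physio <- physio[!bad, , drop = FALSE]
    y <- y[!bad]
  }
  d <- data.frame(logy = log(y),
                  temperature = factor(physio$temperature),
                  oxygen = factor(physio$oxygen),
                  mass = physio$wet_mass,
                  treatment = factor(physio$treatment))
  if (any(table(d$temperature, d$oxygen) < 2))
    stop("each factorial cell needs >= 2 replicates")
  fit <- stats::lm(logy ~ temperature * oxygen + mass, data = d)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)
  keep <- terms != "Residuals"
  anova_tab <- data.frame(term = terms[keep], df = a2$Df[keep],
                          F = a2$`F value`[keep], p = a2$`Pr(>F)`[keep],
                          stringsAsFactors = FALSE)
  emm <- emmeans::emmeans(fit, ~ temperature * oxygen)
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  lab <- as.data.frame(emm)
  cell <- paste0(lab$temperature, lab$oxygen)
  # map "temperature10 oxygen..." contrast labels onto treatment codes
  split_lab <- function(s) {
    parts <- strsplit(s, " - ", fixed = TRUE)[[1]]
    gsub("[^0-9A-Z]", "", parts)
  }
  pl <- t(vapply(as.character(prs$contrast), split_lab, character(2)))
  tukey <- data.frame(a = pl[, 1], b = pl[, 2],
                      estimate = prs$estimate, se = prs$SE,
                      p_adj = prs$p.value, stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  tukey$different <- tukey$p_adj < 0.05
  list(anova = anova_tab, tukey = tukey,
       letters = letter_groups(sort(unique(cell)), tukey),
       model = fit)
}

#' Mass-standardized metabolic rate
#'
#' Fits the least-squares regression of MO2 on wet mass within the
#' normoxic cold-acclimated control group (10NO) and returns, for every
#' individual in all treatments, the residual of its observed MO2 from that
#' control line.
#'
#' @param physio data.frame with treatment, wet_mass, mo2.
#' @return input data.frame with an added `std_mo2` column.
#' @export
standardize_mo2 <- function(physio) {
  ctrl <- physio$treatment == "10NO"
  if (sum(ctrl) < 3) stop("need >= 3 control (10NO) individuals")
  if (stats::var(physio$wet_mass[ctrl]) == 0)
    stop("zero mass variance among controls")
  fit <- stats::lm(mo2 ~ wet_mass, data = physio[ctrl, , drop = FALSE])
  physio$std_mo2 <- physio$mo2 -
    stats::predict(fit, newdata = physio)
  physio
}

#' Correlate gene expression with standardized metabolic rate
#'
#' Per-gene Pearson correlation between (batch-corrected) VST expression
#' and per-sample standardized MO2, with a two-sided p-value and a
#' significance flag at `p < alpha`; no multiple-testing adjustment is
#' applied. Genes with constant expression get an undefined correlation and
#' are never flagged.
#'
#' @param v a `vst_matrix`.
#' @param std_mo2 named numeric vector of standardized MO2, names matching
#'   the VST sample IDs.
#' @param alpha significance threshold (default 0.01).
#' @return data.frame: gene_id, r, p, significant.
#' @export
correlate_genes_mo2 <- function(v, std_mo2, alpha = 0.01) {
  stopifnot(inherits(v, "vst_matrix"))
  if (is.null(names(std_mo2)))
    stop("std_mo2 must be named by sample ID")
  common <- intersect(colnames(v$values), names(std_mo2))
  missing <- setdiff(colnames(v$values), names(std_mo2))
  if (length(missing) == ncol(v$values))
    stop("no sample IDs shared between expression and MO2")
  if (length(common) < 4)
    stop("need >= 4 samples with both expression and standardized MO2")
  x <- v$values[, common, drop = FALSE]
  y <- std_mo2[common]
  n <- length(y)
  sx <- apply(x, 1, stats::sd)
  r <- rep(NA_real_, nrow(x))
  ok <- sx > 0 & stats::sd(y) > 0
  if (any(ok))
    r[ok] <- as.vector(stats::cor(t(x[ok, , drop = FALSE]), y))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  data.frame(gene_id = rownames(x), r = r, p = p,
             significant = !is.na(p) & p < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
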