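#' Configuration for the synthetic count-matrix generator
#'
#' Builds a validated configuration describing a 2x2 factorial RNA-seq
#' experiment (acclimation temperature 10/20 degC crossed with oxygen NO/HY),
#' with genes planted according to the cross-tolerance archetypes the
#' frontloading classifier is meant to recover.
#'
#' Archetypes and their planted effects (all on the log2 scale):
#' \describe{
#'   \item{frontloaded_up}{constitutive shift `+const_shift_log2` at 20 degC,
#'     cold hypoxia reaction `+cold_reaction_log2`, warm reaction attenuated
#'     by `warm_attenuation`.}
#'   \item{frontloaded_down}{mirror image with negative signs.}
#'   \item{stress_indicator_up}{cold up-reaction, attenuated warm reaction,
#'     but constitutive expression *lowered* at 20 degC.}
#'   \item{stress_indicator_down}{mirror image.}
#'   \item{greater_fc}{warm reaction amplified by `greater_fc_amplification`
#'     (> 1) instead of attenuated; the warm-group counts are drawn with
#'     dispersion inflated by `greater_fc_dispersion_mult` so warm
#'     significance is not guaranteed.}
#'   \item{null}{no planted effect of any kind.}
#' }
#'
#' @param n_genes number of genes to simulate.
#' @param n_reps_per_treatment replicates in each of the four treatments.
#' @param n_batches number of batches; replicates are split across batches
#'   as evenly as possible within every treatment.
#' @param archetype_fractions named proportions over the six archetypes;
#'   must sum to 1.
#' @param baseline_mean_log_range range (natural-log scale) from which
#'   per-gene baseline means are drawn log-uniformly.
#' @param dispersion negative-binomial dispersion alpha (Var = mu + alpha
#'   mu^2), constant across genes; 0 gives Poisson counts.
#' @param const_shift_log2 magnitude of the 20NO-vs-10NO constitutive shift.
#' @param cold_reaction_log2 magnitude of the hypoxia |log2FC| at 10 degC.
#' @param warm_attenuation fraction (in [0, 1)) of the cold reaction retained
#'   at 20 degC for the reduced-reaction archetypes.
#' @param greater_fc_amplification factor (> 1) applied to the cold reaction
#'   for the greater_fc archetype.
#' @param greater_fc_dispersion_mult dispersion multiplier for greater_fc
#'   genes in the two warm treatments.
#' @param batch_shift_log2 additive log2 shift applied to batch 2 samples.
#' @param seed integer seed; one seed drives the whole generator stream.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_reps_per_treatment = 5,
                       n_batches = 2,
                       archetype_fractions = c(frontloaded_up = 0.09,
                                               frontloaded_down = 0.12,
                                               stress_indicator_up = 0.015,
                                               stress_indicator_down = 0.015,
                                               greater_fc = 0.06,
                                               null = 0.70),
                       baseline_mean_log_range = c(log(10), log(1000)),
                       dispersion = 0.1,
                       const_shift_log2 = 1,
                       cold_reaction_log2 = 2,
                       warm_attenuation = 0.2,
                       greater_fc_amplification = 1.5,
                       greater_fc_dispersion_mult = 15,
                       batch_shift_log2 = 0.3,
                       seed = 1L) {
  stopifnot(n_genes >= 1, n_reps_per_treatment >= 1, n_batches >= 1)
  wanted <- c("frontloaded_up", "frontloaded_down", "stress_indicator_up",
              "stress_indicator_down", "greater_fc", "null")
  if (!setequal(names(archetype_fractions), wanted))
    stop("archetype_fractions must be named over: ",
         paste(wanted, collapse = ", "))
  archetype_fractions <- archetype_fractions[wanted]
  if (abs(sum(archetype_fractions) - 1) > 1e-9)
    stop("archetype_fractions must sum to 1")
  if (any(archetype_fractions < 0)) stop("archetype fractions must be >= 0")
  stopifnot(length(baseline_mean_log_range) == 2,
            diff(baseline_mean_log_range) >= 0)
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (const_shift_log2 < 0 || cold_reaction_log2 < 0)
    stop("effect magnitudes must be >= 0")
  if (warm_attenuation < 0 || warm_attenuation >= 1)
    stop("warm_attenuation must lie in [0, 1)")
  if (greater_fc_amplification <= 1)
    stop("greater_fc_amplification must exceed 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_reps_per_treatment = as.integer(n_reps_per_treatment),
                 n_batches = as.integer(n_batches),
                 archetype_fractions = archetype_fractions,
                 baseline_mean_log_range = baseline_mean_log_range,
                 dispersion = dispersion,
                 const_shift_log2 = const_shift_log2,
                 cold_reaction_log2 = cold_reaction_log2,
                 warm_attenuation = warm_attenuation,
                 greater_fc_amplification = greater_fc_amplification,
                 greater_fc_dispersion_mult = greater_fc_dispersion_mult,
                 batch_shift_log2 = batch_shift_log2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

TREATMENTS <- c("10NO", "10HY", "20NO", "20HY")

# Balanced sample sheet: reps split across batches within each treatment.
sim_sample_meta <- function(n_reps, n_batches) {
  meta <- do.call(rbind, lapply(TREATMENTS, function(tr) {
    data.frame(sample_id = sprintf("%s_r%d", tr, seq_len(n_reps)),
               treatment = tr,
               temperature = as.integer(substr(tr, 1, 2)),
               oxygen = substr(tr, 3, 4),
               batch = sprintf("b%d", ((seq_len(n_reps) - 1L) %% n_batches) + 1L),
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  meta
}

# Per-gene planted truth for a vector of archetype labels.
sim_truth_for <- function(archetype, cfg) {
  n <- length(archetype)
  const_log2 <- cold_log2fc <- warm_log2fc <- numeric(n)
  # greater_fc genes get a random reaction sign; drawn here so the truth
  # table is part of the seeded stream
  gf_sign <- sample(c(-1, 1), n, replace = TRUE)
  for (i in seq_len(n)) {
    a <- archetype[i]
    if (a == "frontloaded_up") {
      const_log2[i] <- cfg$const_shift_log2
      cold_log2fc[i] <- cfg$cold_reaction_log2
      warm_log2fc[i] <- cfg$warm_attenuation * cold_log2fc[i]
    } else if (a == "frontloaded_down") {
      const_log2[i] <- -cfg$const_shift_log2
      cold_log2fc[i] <- -cfg$cold_reaction_log2
      warm_log2fc[i] <- cfg$warm_attenuation * cold_log2fc[i]
    } else if (a == "stress_indicator_up") {
      const_log2[i] <- -cfg$const_shift_log2
      cold_log2fc[i] <- cfg$cold_reaction_log2
      warm_log2fc[i] <- cfg$warm_attenuation * cold_log2fc[i]
    } else if (a == "stress_indicator_down") {
      const_log2[i] <- cfg$const_shift_log2
      cold_log2fc[i] <- -cfg$cold_reaction_log2
      warm_log2fc[i] <- cfg$warm_attenuation * cold_log2fc[i]
    } else if (a == "greater_fc") {
      const_log2[i] <- 0
      cold_log2fc[i] <- gf_sign[i] * cfg$cold_reaction_log2
      warm_log2fc[i] <- cfg$greater_fc_amplification * cold_log2fc[i]
    } # null: all zero
  }
  data.frame(archetype = archetype, const_log2 = const_log2,
             cold_log2fc = cold_log2fc, warm_log2fc = warm_log2fc,
             stringsAsFactors = FALSE)
}

#' Simulate a factorial RNA-seq count matrix with planted frontloading
#'
#' Counts are drawn from a negative binomial with mean
#' `mu_base * 2^(const_log2 [Ta=20]) * 2^(cold_log2fc [HY, Ta=10]) *
#' 2^(warm_log2fc [HY, Ta=20]) * 2^(batch_shift_log2 [batch 2])` and
#' `Var = mu + alpha mu^2`. Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a list with elements `counts` (a `count_matrix`, see
#'   [count_matrix()]) and `truth` (data.frame: gene_id, archetype, mu_base,
#'   const_log2, cold_log2fc, warm_log2fc).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  meta <- sim_sample_meta(cfg$n_reps_per_treatment, cfg$n_batches)
  n <- cfg$n_genes

  counts_per <- floor(cfg$archetype_fractions * n)
  # distribute the rounding remainder to the largest fractions
  rem <- n - sum(counts_per)
  if (rem > 0) {
    ord <- order(cfg$archetype_fractions, decreasing = TRUE)
    counts_per[ord[seq_len(rem)]] <- counts_per[ord[seq_len(rem)]] + 1L
  }
  archetype <- sample(rep(names(counts_per), counts_per))

  truth <- sim_truth_for(archetype, cfg)
  truth$mu_base <- exp(stats::runif(n, cfg$baseline_mean_log_range[1],
                                    cfg$baseline_mean_log_range[2]))
  truth$gene_id <- sprintf("g%05d", seq_len(n))
  truth <- truth[, c("gene_id", "archetype", "mu_base", "const_log2",
                     "cold_log2fc", "warm_log2fc")]

  warm <- meta$temperature == 20
  hy <- meta$oxygen == "HY"
  b2 <- meta$batch != "b1"
  log2mu <- outer(log2(truth$mu_base), rep(1, nrow(meta))) +
    outer(truth$const_log2, as.numeric(warm)) +
    outer(truth$cold_log2fc, as.numeric(hy & !warm)) +
    outer(truth$warm_log2fc, as.numeric(hy & warm)) +
    cfg$batch_shift_log2 * matrix(as.numeric(b2), n, nrow(meta), byrow = TRUE)
  mu <- 2^log2mu

  alpha <- matrix(cfg$dispersion, n, nrow(meta))
  alpha[truth$archetype == "greater_fc", warm] <-
    cfg$dispersion * cfg$greater_fc_dispersion_mult

  counts <- matrix(0L, n, nrow(meta),
                   dimnames = list(truth$gene_id, meta$sample_id))
  pois <- alpha < 1e-12
  if (any(pois)) counts[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) counts[!pois] <- stats::rnbinom(sum(!pois),
                                                  mu = mu[!pois],
                                                  size = 1 / alpha[!pois])
  list(counts = count_matrix(counts, meta), truth = truth)
}

#' Configuration for the synthetic physiology generator
#'
#' Emulates per-individual wet mass, oxygen uptake (MO2) and whole-body
#' lactate in the 2x2 factorial design, with allometric mass scaling and a
#' hypometabolic suppression applied only to the warm-acclimated hypoxic
#' treatment (20HY).
#'
#' @param n_per_treatment individuals per treatment.
#' @param mass_mean_mg mean wet mass in mg (default 87.3).
#' @param mass_cv coefficient of variation of mass.
#' @param allometric_exponent mass-scaling exponent b in MO2 ~ mass^b.
#' @param mo2_baseline MO2 normalizing constant (units O2 per time at 1 mg).
#' @param hypometabolism_factor_20HY multiplicative MO2 suppression, applied
#'   to 20HY individuals only; must lie in (0, 1).
#' @param noise_cv lognormal CV of the multiplicative MO2/lactate noise.
#' @param lactate_mass_slope slope of lactate on mass (per mg).
#' @param lactate_baseline lactate intercept at zero mass.
#' @param n_runs number of experimental runs (batches).
#' @param seed integer seed.
#' @return a list of class `physio_sim_config`.
#' @export
physio_sim_config <- function(n_per_treatment = 10,
                              mass_mean_mg = 87.3,
                              mass_cv = 0.21,
                              allometric_exponent = 0.75,
                              mo2_baseline = 0.05,
                              hypometabolism_factor_20HY = 0.6,
                              noise_cv = 0.15,
                              lactate_mass_slope = 0.01,
                              lactate_baseline = 0.5,
                              n_runs = 2,
                              seed = 1L) {
  stopifnot(n_per_treatment >= 1, mass_mean_mg > 0, mass_cv >= 0,
            mo2_baseline > 0, noise_cv >= 0, n_runs >= 1)
  if (hypometabolism_factor_20HY <= 0 || hypometabolism_factor_20HY >= 1)
    stop("hypometabolism_factor_20HY must lie in (0, 1)")
  structure(list(n_per_treatment = as.integer(n_per_treatment),
                 mass_mean_mg = mass_mean_mg, mass_cv = mass_cv,
                 allometric_exponent = allometric_exponent,
                 mo2_baseline = mo2_baseline,
                 hypometabolism_factor_20HY = hypometabolism_factor_20HY,
                 noise_cv = noise_cv,
                 lactate_mass_slope = lactate_mass_slope,
                 lactate_baseline = lactate_baseline,
                 n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "physio_sim_config")
}

#' Simulate per-individual physiology records
#'
#' Masses are lognormal around `mass_mean_mg`;
#' `MO2 = mo2_baseline * mass^allometric_exponent * treatment_factor * noise`
#' where the treatment factor is `hypometabolism_factor_20HY` for 20HY and 1
#' otherwise, and noise is lognormal with CV `noise_cv`. Lactate increases
#' linearly with mass (same multiplicative noise model).
#'
#' @param cfg a [physio_sim_config()].
#' @return data.frame with columns individual_id, treatment, temperature,
#'   oxygen, run, wet_mass, mo2, lactate, end_po2_pct_as.
#' @export
simulate_physiology <- function(cfg) {
  stopifnot(inherits(cfg, "physio_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_per_treatment
  rec <- do.call(rbind, lapply(TREATMENTS, function(tr) {
    data.frame(individual_id = sprintf("%s_i%d", tr, seq_len(n)),
               treatment = tr,
               temperature = as.integer(substr(tr, 1, 2)),
               oxygen = substr(tr, 3, 4),
               run = sprintf("run%d", ((seq_len(n) - 1L) %% cfg$n_runs) + 1L),
               stringsAsFactors = FALSE)
  }))
  m <- nrow(rec)
  sdlog_mass <- sqrt(log(1 + cfg$mass_cv^2))
  rec$wet_mass <- cfg$mass_mean_mg *
    exp(stats::rnorm(m, -sdlog_mass^2 / 2, sdlog_mass))
  if (any(rec$wet_mass <= 0)) stop("generated non-positive mass")
  tf <- ifelse(rec$treatment == "20HY", cfg$hypometabolism_factor_20HY, 1)
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  noise <- function() exp(stats::rnorm(m, -sdlog^2 / 2, sdlog))
  rec$mo2 <- cfg$mo2_baseline * rec$wet_mass^cfg$allometric_exponent *
    tf * noise()
  rec$lactate <- (cfg$lactate_baseline +
                    cfg$lactate_mass_slope * rec$wet_mass) * noise()
  rec$end_po2_pct_as <- ifelse(rec$oxygen == "HY", 30, 80)
  rownames(rec) <- NULL
  rec
}

#' Write a simulated dataset to plain-text files
#'
#' Counts go to TSV (genes as rows, header = sample IDs), metadata and
#' physiology to CSV, truth to TSV; the files round-trip through
#' [read_counts()].
#'
#' @param sim result of [simulate_counts()].
#' @param physio result of [simulate_physiology()] or NULL.
#' @param dir output directory (created if missing).
#' @return invisibly, the named file paths.
#' @export
write_sim_dataset <- function(sim, physio = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             meta = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.tsv"))
  cm <- sim$counts
  df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE)
  utils::write.table(df, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(cm$meta, paths["meta"], row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(physio)) {
    paths["physio"] <- file.path(dir, "physiology.csv")
    utils::write.csv(physio, paths["physio"], row.names = FALSE,
                     quote = FALSE)
  }
  invisible(paths)
}
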