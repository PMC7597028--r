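#' Simulation parameters for the synthetic two-origin cohort
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults describe the
#' study design the pipeline assumes: a small two-origin normal panel (12 FI,
#' 8 OSE), 24 tumors inheriting one origin's methylation state at a planted set
#' of origin-differential CpGs, a tumor-common aberration field that dominates
#' global variance, negative-binomial expression with planted origin-specific
#' DE genes, and exponential survival with an OSE-dependent hazard ratio.
#'
#' @param n_fi,n_ose,n_tumor Numbers of fimbrial (FI) normals, ovarian surface
#'   epithelium (OSE) normals, and tumors in the methylation cohort.
#' @param n_cpg Number of CpG features.
#' @param n_origin_dms Number of planted origin-differential CpGs.
#' @param origin_delta_m Planted FI-vs-OSE shift at those CpGs (M-value units).
#' @param tumor_fraction_aberrant Fraction of CpGs receiving the tumor-common
#'   shift field shared by all tumors.
#' @param tumor_shift_sd Standard deviation of the tumor-common shift
#'   (M-value units).
#' @param origin_fidelity Probability that a tumor retains its own origin's
#'   mean at each planted CpG (otherwise it takes the other origin's mean).
#' @param noise_sd Per-entry i.i.d. Gaussian noise, M-value units.
#' @param n_genes Number of genes in the expression cohort.
#' @param n_signature_genes Number of planted origin-DE genes.
#' @param expr_log2fc Planted log2 fold change between origins.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param n_expr Size of the retrospective expression/survival cohort.
#' @param hazard_ratio_ose Hazard ratio of OSE-like vs FI-like tumors.
#' @param median_survival_fi_days Median survival of the FI-like arm, days.
#' @param censor_rate Probability a sample receives an independent uniform
#'   censoring time before the follow-up horizon.
#' @param horizon_days Follow-up horizon of the simulated study; event times
#'   beyond it are administratively censored.
#' @param seed Integer seed; every generator consumes an independent stream
#'   derived from it.
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(seed = 7)
#' p$n_tumor
#' @export
sim_params <- function(n_fi = 12L, n_ose = 8L, n_tumor = 24L,
                       n_cpg = 20000L, n_origin_dms = 1000L,
                       origin_delta_m = 2.5,
                       tumor_fraction_aberrant = 0.2,
                       tumor_shift_sd = 2,
                       origin_fidelity = 0.9,
                       noise_sd = 0.5,
                       n_genes = 2000L, n_signature_genes = 100L,
                       expr_log2fc = 2, nb_dispersion = 0.1,
                       n_expr = 150L,
                       hazard_ratio_ose = 2,
                       median_survival_fi_days = 1500,
                       censor_rate = 0.15,
                       horizon_days = 3650,
                       seed = 1L) {
  p <- list(n_fi = as.integer(n_fi), n_ose = as.integer(n_ose),
            n_tumor = as.integer(n_tumor), n_cpg = as.integer(n_cpg),
            n_origin_dms = as.integer(n_origin_dms),
            origin_delta_m = origin_delta_m,
            tumor_fraction_aberrant = tumor_fraction_aberrant,
            tumor_shift_sd = tumor_shift_sd,
            origin_fidelity = origin_fidelity, noise_sd = noise_sd,
            n_genes = as.integer(n_genes),
            n_signature_genes = as.integer(n_signature_genes),
            expr_log2fc = expr_log2fc, nb_dispersion = nb_dispersion,
            n_expr = as.integer(n_expr),
            hazard_ratio_ose = hazard_ratio_ose,
            median_survival_fi_days = median_survival_fi_days,
            censor_rate = censor_rate, horizon_days = horizon_days,
            seed = as.integer(seed))
  counts <- c("n_fi", "n_ose", "n_tumor", "n_cpg", "n_origin_dms",
              "n_genes", "n_signature_genes", "n_expr")
  for (nm in counts) {
    if (is.na(p[[nm]]) || p[[nm]] < 0L)
      stop("sim_params: '", nm, "' must be a non-negative count")
  }
  if (p$n_origin_dms > p$n_cpg)
    stop("sim_params: n_origin_dms (", p$n_origin_dms,
         ") exceeds n_cpg (", p$n_cpg, ")")
  if (p$origin_fidelity < 0 || p$origin_fidelity > 1)
    stop("sim_params: origin_fidelity must lie in [0, 1]")
  if (p$censor_rate < 0 || p$censor_rate > 1)
    stop("sim_params: censor_rate must lie in [0, 1]")
  if (p$origin_delta_m <= 0) stop("sim_params: origin_delta_m must be > 0")
  if (p$tumor_fraction_aberrant < 0 || p$tumor_fraction_aberrant > 1)
    stop("sim_params: tumor_fraction_aberrant must lie in [0, 1]")
  if (p$hazard_ratio_ose <= 0) stop("sim_params: hazard_ratio_ose must be > 0")
  structure(p, class = "sim_params")
}

#' Pipeline configuration
#'
#' Analysis-stage thresholds and sizes used across the pipeline. Defaults are
#' the published operating points: adjusted p < 0.05 with |delta M| > 1 for the
#' methylation signature, Louvain on the first 50 principal components with a
#' 20-neighbor graph, the best of 2000 random GMM restarts, a Louvain
#' resolution scan over [0.1, 1.5], a 75% consistency threshold with 70/30
#' train/test splits, FDR < 0.05 with |logFC| > 0.8 for differential
#' expression, and a 5-year (1826-day) survival horizon.
#'
#' @param dms_alpha BH-adjusted p-value cutoff for differential methylation.
#' @param dms_min_abs_dm Minimum |delta M| (M units) for a signature CpG.
#' @param n_pcs_louvain Number of principal components fed to Louvain.
#' @param knn_k Neighborhood size for kNN graphs and diffusion maps.
#' @param gmm_restarts Number of random EM restarts for the Gaussian mixture.
#' @param gmm_components Number of mixture components.
#' @param resolution_range Louvain resolution scan range (length-2 numeric).
#' @param consistency_threshold Minimum classification consistency below which
#'   a sample is called "uncertain".
#' @param train_fraction Training fraction of each stratified split.
#' @param n_gene_permutations Trees (gene patches) per bagged ensemble.
#' @param n_split_shuffles Number of stratified train/test splits.
#' @param survival_horizon_days Survival analysis horizon (default 5 years).
#' @param de_fdr,de_min_lfc Differential-expression thresholds.
#' @param n_diffusion_comps Diffusion components used for pseudotime.
#' @param seed Integer seed for the seeded stages.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(dms_alpha = 0.05, dms_min_abs_dm = 1,
                            n_pcs_louvain = 50L, knn_k = 20L,
                            gmm_restarts = 2000L, gmm_components = 2L,
                            resolution_range = c(0.1, 1.5),
                            consistency_threshold = 0.75,
                            train_fraction = 0.7,
                            n_gene_permutations = 100L,
                            n_split_shuffles = 100L,
                            survival_horizon_days = 1826,
                            de_fdr = 0.05, de_min_lfc = 0.8,
                            n_diffusion_comps = 15L,
                            seed = 1L) {
  cfg <- list(dms_alpha = dms_alpha, dms_min_abs_dm = dms_min_abs_dm,
              n_pcs_louvain = as.integer(n_pcs_louvain),
              knn_k = as.integer(knn_k),
              gmm_restarts = as.integer(gmm_restarts),
              gmm_components = as.integer(gmm_components),
              resolution_range = resolution_range,
              consistency_threshold = consistency_threshold,
              train_fraction = train_fraction,
              n_gene_permutations = as.integer(n_gene_permutations),
              n_split_shuffles = as.integer(n_split_shuffles),
              survival_horizon_days = survival_horizon_days,
              de_fdr = de_fdr, de_min_lfc = de_min_lfc,
              n_diffusion_comps = as.integer(n_diffusion_comps),
              seed = as.integer(seed))
  stopifnot(cfg$dms_alpha > 0, cfg$dms_alpha < 1,
            cfg$dms_min_abs_dm >= 0,
            cfg$n_pcs_louvain >= 1L, cfg$knn_k >= 1L,
            cfg$gmm_restarts >= 1L, cfg$gmm_components >= 1L,
            length(cfg$resolution_range) == 2L,
            cfg$resolution_range[1] > 0,
            cfg$resolution_range[2] >= cfg$resolution_range[1],
            cfg$consistency_threshold > 0, cfg$consistency_threshold <= 1,
            cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$n_gene_permutations >= 1L, cfg$n_split_shuffles >= 1L,
            cfg$survival_horizon_days > 0,
            cfg$de_fdr > 0, cfg$de_fdr < 1, cfg$de_min_lfc >= 0,
            cfg$n_diffusion_comps >= 2L)
  structure(cfg, class = "pipeline_config")
}

# Derive an independent, reproducible sub-stream seed for a named stage so
# that changing one stage's internals never perturbs another stage's draws.
# Kept below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}
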