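#' Simulate a two-origin methylation cohort with tumors
#'
#' Generates a CpG-by-sample methylation cohort with the variance structure
#' the cell-of-origin analysis assumes:
#' \itemize{
#' \item baseline per-CpG M values drawn from a two-component
#'   (methylated/unmethylated) mixture, so marginal beta values are bimodal;
#' \item a planted set of origin-differential CpGs where the FI and OSE means
#'   straddle the beta = 0.5 midpoint and differ by `origin_delta_m` M units,
#'   with random direction (hyper- or hypomethylated in OSE);
#' \item tumors that copy their origin's mean at each planted CpG with
#'   probability `origin_fidelity` (else the other origin's mean);
#' \item one tumor-common random shift field (sd `tumor_shift_sd`) over a
#'   fraction `tumor_fraction_aberrant` of all CpGs, shared by every tumor, so
#'   the normal-vs-tumor axis dominates global variance while the origin
#'   signal survives inside the planted subspace;
#' \item i.i.d. Gaussian noise (sd `noise_sd`) everywhere.
#' }
#' Betas are derived from M values and clipped to the open interval (0, 1).
#'
#' @param params A [sim_params()] object.
#' @return List with `cohort` (a [methyl_cohort()]) and `truth` (list with
#'   `origin_of_tumor`, named character; `planted_dms`, data frame of CpG id
#'   and direction where `+1` means hypermethylated in OSE; `tumor_cpgs`, the
#'   indices carrying the tumor-common shift).
#' @examples
#' sim <- simulate_methylation(sim_params(n_cpg = 500, n_origin_dms = 50))
#' sim$cohort
#' @export
simulate_methylation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(stage_seed(p$seed, "methylation"))
  n_norm <- p$n_fi + p$n_ose
  n <- n_norm + p$n_tumor
  cpg_ids <- sprintf("cg%07d", seq_len(p$n_cpg))
  sample_ids <- c(sprintf("FI_%02d", seq_len(p$n_fi)),
                  sprintf("OSE_%02d", seq_len(p$n_ose)),
                  sprintf("T_%02d", seq_len(p$n_tumor)))
  tissue <- c(rep("FI", p$n_fi), rep("OSE", p$n_ose), rep("TUMOR", p$n_tumor))

  # baseline: bimodal mixture of unmethylated (M ~ -3) and methylated (M ~ 3)
  comp <- stats::rbinom(p$n_cpg, 1L, 0.5)
  base <- stats::rnorm(p$n_cpg, mean = ifelse(comp == 1L, 3, -3), sd = 1)

  dms_idx <- if (p$n_origin_dms > 0L) sort(sample.int(p$n_cpg, p$n_origin_dms))
             else integer(0)
  direction <- integer(0)
  mu_fi <- base
  mu_ose <- base
  if (length(dms_idx)) {
    direction <- sample(c(-1L, 1L), length(dms_idx), replace = TRUE)
    center <- stats::rnorm(length(dms_idx), 0, 0.5)
    mu_fi[dms_idx] <- center - direction * p$origin_delta_m / 2
    mu_ose[dms_idx] <- center + direction * p$origin_delta_m / 2
  }

  origin_of_tumor <- sample(c("FI", "OSE"), p$n_tumor, replace = TRUE)
  names(origin_of_tumor) <- sample_ids[tissue == "TUMOR"]

  n_aber <- round(p$tumor_fraction_aberrant * p$n_cpg)
  tumor_cpgs <- if (n_aber > 0) sort(sample.int(p$n_cpg, n_aber)) else integer(0)
  tumor_shift <- numeric(p$n_cpg)
  if (length(tumor_cpgs))
    tumor_shift[tumor_cpgs] <- stats::rnorm(length(tumor_cpgs), 0,
                                            p$tumor_shift_sd)

  m <- matrix(0, nrow = p$n_cpg, ncol = n,
              dimnames = list(cpg_ids, sample_ids))
  for (j in seq_len(n)) {
    mu <- switch(tissue[j], FI = mu_fi, OSE = mu_ose, TUMOR = {
      o <- origin_of_tumor[sample_ids[j]]
      own <- if (o == "FI") mu_fi else mu_ose
      other <- if (o == "FI") mu_ose else mu_fi
      v <- own
      if (length(dms_idx)) {
        flip <- stats::runif(length(dms_idx)) > p$origin_fidelity
        v[dms_idx[flip]] <- other[dms_idx[flip]]
      }
      v + tumor_shift
    })
    m[, j] <- mu + stats::rnorm(p$n_cpg, 0, p$noise_sd)
  }

  beta <- m_to_beta(m)
  eps <- 1e-6
  beta <- pmin(pmax(beta, eps), 1 - eps)
  samples <- data.frame(sample_id = sample_ids, tissue_class = tissue,
                        batch = "cohort1",
                        true_origin = ifelse(tissue == "TUMOR",
                                             origin_of_tumor[sample_ids],
                                             tissue),
                        stringsAsFactors = FALSE)
  cohort <- methyl_cohort(beta, samples, m = beta_to_m(beta))
  truth <- list(origin_of_tumor = origin_of_tumor,
                planted_dms = data.frame(cpg_id = cpg_ids[dms_idx],
                                         direction = direction,
                                         stringsAsFactors = FALSE),
                tumor_cpgs = cpg_ids[tumor_cpgs])
  list(cohort = cohort, truth = truth)
}

#' Simulate an expression cohort with planted origin-DE genes
#'
#' Negative-binomial gene-by-sample counts. Library sizes are log-uniform over
#' a 4-fold range; a planted gene set is shifted by `expr_log2fc` between the
#' two origins (random direction, applied symmetrically around the baseline
#' mean).
#'
#' @param origins Character vector of per-sample origin labels (`"FI"` /
#'   `"OSE"`), named by sample id (names are generated if absent).
#' @param params A [sim_params()] object; uses `n_genes`,
#'   `n_signature_genes`, `expr_log2fc`, `nb_dispersion`, `seed`.
#' @return List with `counts` (gene x sample integer matrix), `samples`
#'   (sheet with sample_id, origin), and `truth` (`planted_de_genes`: data
#'   frame of gene id and direction, `+1` = up in OSE).
#' @export
simulate_expression <- function(origins, params) {
  stopifnot(inherits(params, "sim_params"))
  sample_ids <- names(origins)
  origins <- as.character(origins)
  if (!all(origins %in% c("FI", "OSE")))
    stop("simulate_expression: origins must be 'FI' or 'OSE'")
  if (length(unique(origins)) < 2L || any(table(origins) < 2L))
    stop("simulate_expression: need at least 2 samples per origin ",
         "(differential expression is undefined otherwise)")
  p <- params
  set.seed(stage_seed(p$seed, "expression"))
  n <- length(origins)
  if (is.null(sample_ids)) sample_ids <- sprintf("E_%03d", seq_len(n))
  gene_ids <- sprintf("gene%05d", seq_len(p$n_genes))

  base_mu <- 2^stats::runif(p$n_genes, 3, 10)          # 8..1024 expected counts
  lib_factor <- exp(stats::runif(n, log(0.5), log(2))) # 4-fold log-uniform

  n_de <- if (p$expr_log2fc == 0) 0L else min(p$n_signature_genes, p$n_genes)
  de_idx <- if (n_de > 0L) sort(sample.int(p$n_genes, n_de)) else integer(0)
  de_dir <- if (n_de > 0L) sample(c(-1L, 1L), n_de, replace = TRUE) else integer(0)

  lfc_fi <- lfc_ose <- numeric(p$n_genes)
  if (n_de > 0L) {
    lfc_fi[de_idx] <- -de_dir * p$expr_log2fc / 2
    lfc_ose[de_idx] <- de_dir * p$expr_log2fc / 2
  }
  size <- 1 / p$nb_dispersion
  counts <- matrix(0L, nrow = p$n_genes, ncol = n,
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n)) {
    lfc <- if (origins[j] == "OSE") lfc_ose else lfc_fi
    mu <- base_mu * 2^lfc * lib_factor[j]
    counts[, j] <- stats::rnbinom(p$n_genes, size = size, mu = mu)
  }
  samples <- data.frame(sample_id = sample_ids, origin = unname(origins),
                        stringsAsFactors = FALSE)
  truth <- list(planted_de_genes = data.frame(gene_id = gene_ids[de_idx],
                                              direction = de_dir,
                                              stringsAsFactors = FALSE))
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate survival records with an origin-dependent hazard
#'
#' Event times are exponential; the OSE-like rate is the FI-like rate times
#' `hazard_ratio_ose` (FI rate set by `median_survival_fi_days = log(2)/rate`).
#' With probability `censor_rate` a sample receives an independent censoring
#' time uniform on (0, `horizon_days`); times beyond the follow-up horizon are
#' administratively censored at the horizon.
#'
#' @param origins Character vector (`"FI"`/`"OSE"`), optionally named by
#'   sample id.
#' @param params A [sim_params()] object.
#' @return Data frame with `sample_id`, `group` (`FI-like`/`OSE-like`),
#'   `time_days`, `event` (1 = death, 0 = censored).
#' @export
simulate_survival <- function(origins, params) {
  stopifnot(inherits(params, "sim_params"))
  sample_ids <- names(origins)
  origins <- as.character(origins)
  stopifnot(all(origins %in% c("FI", "OSE")))
  p <- params
  set.seed(stage_seed(p$seed, "survival"))
  n <- length(origins)
  if (is.null(sample_ids)) sample_ids <- sprintf("S_%03d", seq_len(n))
  rate_fi <- log(2) / p$median_survival_fi_days
  rate <- ifelse(origins == "OSE", rate_fi * p$hazard_ratio_ose, rate_fi)
  t_event <- stats::rexp(n, rate)
  censored_draw <- stats::runif(n) < p$censor_rate
  # censoring window: the follow-up horizon, or (for open-ended follow-up)
  # the 99.9th percentile of the slower arm's event distribution
  cens_window <- if (is.finite(p$horizon_days)) p$horizon_days
                 else stats::qexp(0.999, rate_fi)
  t_cens <- ifelse(censored_draw, stats::runif(n, 0, cens_window), Inf)
  time <- pmin(t_event, t_cens, p$horizon_days)
  event <- as.integer(t_event <= pmin(t_cens, p$horizon_days))
  data.frame(sample_id = sample_ids,
             group = ifelse(origins == "OSE", "OSE-like", "FI-like"),
             time_days = time, event = event, stringsAsFactors = FALSE)
}
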