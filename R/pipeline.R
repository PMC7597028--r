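#' Mean silhouette of a labeling in a feature space
#'
#' Mean silhouette width of the given labels over the Euclidean distances of
#' `x` (samples in rows); used to contrast how well different label sets
#' (origin vs normal/tumor) separate in the full-CpG versus signature space.
#'
#' @param x Sample x feature matrix.
#' @param labels Vector of labels, one per row.
#' @return Mean silhouette width.
#' @export
space_silhouette <- function(x, labels) {
  f <- as.integer(factor(labels))
  stopifnot(length(f) == nrow(x), length(unique(f)) >= 2L)
  sil <- cluster::silhouette(f, stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Run the full cell-of-origin pipeline on a synthetic cohort
#'
#' Executes every stage end to end on simulated data: methylation cohort
#' generation, feature filtering, OriPrint signature calling, tumor
#' classification by the three clustering routes plus the GMM check and
#' their consensus, dual-rooted diffusion pseudotime with the intersection
#' test, translation to a transcriptomic classifier on a retrospective
#' expression cohort (differential expression, coherent signature, external
#' classification, bagging consistency), and survival comparison of the
#' resulting subtypes. Writes all stage outputs plus `report.json` and a run
#' manifest under `out_dir` when given.
#'
#' @param params A [sim_params()] object.
#' @param config A [pipeline_config()] object.
#' @param out_dir Optional output directory; created if missing.
#' @return List with `report` (named list of headline quantities), `calls`,
#'   `signature`, `expr_calls`, `manifest`.
#' @export
run_pipeline <- function(params = sim_params(), config = pipeline_config(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  # ---- methylation cohort ---------------------------------------------------
  sim <- simulate_methylation(params)
  cohort <- filter_features(sim$cohort)
  if (length(unique(cohort$samples$batch)) > 1L)
    cohort <- methyl_cohort(m_to_beta(
      batch_adjust(cohort$m, cohort$samples$batch,
                   cohort$samples$tissue_class)),
      cohort$samples)

  # ---- OriPrint signature ---------------------------------------------------
  signature <- call_oriprint(cohort, config)
  n_sig <- length(signature_cpgs(signature))
  if (n_sig == 0L) stop("run_pipeline failed at stage 'oriprint': empty signature")

  # ---- classification -------------------------------------------------------
  xsig <- signature_space(cohort, signature)
  n_pcs <- min(config$n_pcs_louvain, nrow(xsig) - 1L, ncol(xsig))
  pcs <- stats::prcomp(xsig, center = TRUE, rank. = n_pcs)$x
  dm_sig <- diffusion_map(xsig, knn_k = min(config$knn_k, nrow(xsig) - 1L),
                          n_comps = config$n_diffusion_comps)
  votes <- list(
    pearson = classify_pearson_hclust(cohort, signature),
    louvain = classify_louvain(pcs, cohort$samples,
                               knn_k = min(config$knn_k, nrow(pcs) - 1L),
                               seed = stage_seed(config$seed, "louvain")),
    density = classify_density(dm_sig$components, cohort$samples))
  cons <- consensus_call(votes, threshold = config$consistency_threshold)
  nspace <- fit_normal_space(cohort, signature, n_components = 2L)
  gmm <- classify_gmm(project_space(nspace, xsig), cohort$samples,
                      n_restarts = config$gmm_restarts,
                      seed = stage_seed(config$seed, "gmm"))

  # ---- trajectory -----------------------------------------------------------
  root_fi <- select_root(dm_sig, cohort$samples, "FI")
  root_ose <- select_root(dm_sig, cohort$samples, "OSE")
  dpt_fi <- diffusion_pseudotime(dm_sig, root_fi)
  dpt_ose <- diffusion_pseudotime(dm_sig, root_ose)
  inter <- intersection_analysis(dpt_fi, dpt_ose, cohort$samples)

  # ---- transcriptomic translation ------------------------------------------
  set.seed(stage_seed(params$seed, "expr-origins"))
  expr_origins <- sample(c("FI", "OSE"), params$n_expr, replace = TRUE)
  names(expr_origins) <- sprintf("P_%03d", seq_len(params$n_expr))
  expr <- simulate_expression(expr_origins, params)
  norm <- tmm_normalize(expr$counts)
  # two independent halves stand in for the cells / FFPE evidence cohorts
  half <- seq_len(floor(params$n_expr / 2))
  de_a <- differential_expression(norm$logcpm[, half, drop = FALSE],
                                  expr_origins[half],
                                  config$de_fdr, config$de_min_lfc)
  de_b <- differential_expression(norm$logcpm[, -half, drop = FALSE],
                                  expr_origins[-half],
                                  config$de_fdr, config$de_min_lfc)
  tsig <- build_signature(de_a, de_b)
  expr_calls <- classify_external_cohort(norm$logcpm, tsig,
                                         resolution_range =
                                           config$resolution_range,
                                         seed = stage_seed(config$seed,
                                                           "external"))
  init <- expr_calls$consensus
  names(init) <- expr_calls$sample_id
  init <- init[init != "uncertain"]
  bag <- bagging_consistency(
    norm$logcpm[tsig$gene_id, , drop = FALSE][, names(init), drop = FALSE],
    init, config)
  uncertain_fraction <- mean(bag$consensus == "uncertain")

  # ---- survival -------------------------------------------------------------
  surv <- simulate_survival(expr_origins, params)
  final <- bag$consensus
  names(final) <- bag$sample_id
  surv$call <- final[surv$sample_id]
  surv5 <- restrict_followup(surv, config$survival_horizon_days)
  a <- surv5[!is.na(surv5$call) & surv5$call == "FI-like", ]
  b <- surv5[!is.na(surv5$call) & surv5$call == "OSE-like", ]
  lr <- logrank_test(a, b)
  km_a <- kaplan_meier(a); km_b <- kaplan_meier(b)
  med <- median_difference(km_a, km_b)
  cox_in <- surv5[!is.na(surv5$call) & surv5$call != "uncertain", ]
  cox_in$call <- factor(cox_in$call, levels = c("FI-like", "OSE-like"))
  cox <- cox_ph(cox_in, "call")

  report <- list(
    signature_size = n_sig,
    signature_hyper = length(signature$hyper_in_ose),
    signature_hypo = length(signature$hypo_in_ose),
    concordance = cons$overall_concordance,
    gmm_best_loglik = gmm$best_loglik,
    intersection_sample = inter$intersection_sample,
    intersection_is_tumor = inter$intersection_is_tumor,
    tumor_intermediacy = inter$tumor_intermediacy,
    transcriptomic_signature_size = nrow(tsig),
    uncertain_fraction = uncertain_fraction,
    logrank_chi2 = lr$chi2,
    logrank_p = lr$p,
    median_difference_days = med$days,
    cox_hr_ose = cox$hr[1],
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  manifest <- list(params = unclass(params), config = unclass(config),
                   seed = params$seed,
                   versions = list(oriprint =
                                     as.character(utils::packageVersion("oriprint")),
                                   R = R.version.string))
  out <- list(report = report, calls = cons$calls, votes = votes,
              signature = signature, transcriptomic_signature = tsig,
              expr_calls = expr_calls, bagging = bag,
              survival = surv5, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_matrix_tsv(cohort$beta, file.path(out_dir, "beta.tsv"),
                     id_col = "cpg_id")
    utils::write.table(cohort$samples, file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cons$calls, file.path(out_dir, "origin_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bag, file.path(out_dir, "expr_consistency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(surv5, file.path(out_dir, "survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$output_hashes <- as.list(tools::md5sum(
      list.files(out_dir, full.names = TRUE, pattern = "\\.(tsv|json)$")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest
  }
  out
}
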