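sig_from_ids <- function(ids) {
  structure(list(hyper_in_ose = ids, hypo_in_ose = character(0),
                 thresholds = list(), dms_table = NULL),
            class = "oriprint_signature")
}

test_that("normal-space PCA centers on normals and improves with rank", {
  set.seed(14)
  sim <- small_sim(seed = 14)
  co <- sim$cohort
  sig <- call_oriprint(co)
  sp <- fit_normal_space(co, sig, n_components = 3L)
  expect_equal(crossprod(sp$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(sp$explained_variance) <= 1e-12))
  # the normals' mean profile projects to the origin
  x <- t(co$beta[signature_cpgs(sig), co$samples$tissue_class != "TUMOR"])
  expect_equal(as.vector(project_space(sp, rbind(colMeans(x)))),
               rep(0, 3), tolerance = 1e-8)
  # reconstruction error decreases monotonically with the number of components
  xn <- scale(x, center = TRUE, scale = FALSE)
  errs <- vapply(1:8, function(k) {
    spk <- fit_normal_space(co, sig, n_components = k)
    proj <- project_space(spk, x)
    sum((xn - proj %*% t(spk$loadings))^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-6))
  expect_error(fit_normal_space(co, sig, n_components = 100), "rank")
})

test_that("a tumor copied from an FI normal is called FI-like", {
  sim <- small_sim(seed = 2)
  co <- sim$cohort
  beta <- co$beta
  dup <- beta[, "FI_01"] + 1e-4 * (runif(nrow(beta)) - 0.5)
  beta <- cbind(beta, T_dup = pmin(pmax(dup, 1e-6), 1 - 1e-6))
  samples <- rbind(co$samples,
                   data.frame(sample_id = "T_dup", tissue_class = "TUMOR",
                              batch = "cohort1", true_origin = "FI"))
  co2 <- methyl_cohort(beta, samples)
  sig <- call_oriprint(co2)
  lab <- classify_pearson_hclust(co2, sig)
  expect_equal(unname(lab["T_dup"]), "FI-like")
})

test_that("hierarchical classification is invariant to column permutation", {
  sim <- small_sim(seed = 5)
  co <- sim$cohort
  sig <- call_oriprint(co)
  lab <- classify_pearson_hclust(co, sig)
  set.seed(1)
  perm <- sample(ncol(co$beta))
  co2 <- methyl_cohort(co$beta[, perm], co$samples[perm, , drop = FALSE])
  lab2 <- classify_pearson_hclust(co2, sig)
  expect_equal(lab2[names(lab)], lab)
})

test_that("a constant-profile sample is refused by name", {
  blob <- make_blob_cohort(n_per = 10, d = 5, seed = 3)
  x <- t(blob$x)
  rownames(x) <- sprintf("cg%03d", seq_len(nrow(x)))
  beta <- m_to_beta(x)
  beta[, 3] <- 0.5
  co <- methyl_cohort(beta, blob$samples)
  sig <- sig_from_ids(rownames(beta))
  expect_error(classify_pearson_hclust(co, sig), blob$samples$sample_id[3])
})

test_that("Louvain recovers separated blobs and is seed-reproducible", {
  blob <- make_blob_cohort(n_per = 25, d = 4, sep = 10, seed = 8)
  lab <- classify_louvain(blob$x, blob$samples, knn_k = 10, seed = 5)
  expect_equal(lab, blob$truth[names(lab)])
  lab2 <- classify_louvain(blob$x, blob$samples, knn_k = 10, seed = 5)
  expect_identical(lab, lab2)
  expect_error(classify_louvain(blob$x[1:5, ], blob$samples[1:5, ],
                                knn_k = 10), "knn_k")
})

test_that("density clustering recovers blobs and absorbs outliers", {
  blob <- make_blob_cohort(n_per = 20, d = 3, sep = 12, seed = 6)
  lab <- classify_density(blob$x, blob$samples)
  expect_equal(lab, blob$truth[names(lab)])
  # one far outlier tumor joins its nearest cluster, others unchanged
  x2 <- rbind(blob$x, OUT = c(60, rep(0, 2)))
  s2 <- rbind(blob$samples,
              data.frame(sample_id = "OUT", tissue_class = "TUMOR",
                         batch = "b1"))
  lab2 <- classify_density(x2, s2)
  expect_equal(lab2[names(lab)], lab)
  expect_equal(unname(lab2["OUT"]), "OSE-like")  # nearest = blob at +sep
})

test_that("GMM recovers blobs; best log-likelihood is monotone in restarts", {
  blob <- make_blob_cohort(n_per = 20, d = 2, sep = 8, seed = 9)
  g10 <- classify_gmm(blob$x, blob$samples, n_restarts = 10, seed = 4)
  g50 <- classify_gmm(blob$x, blob$samples, n_restarts = 50, seed = 4)
  expect_equal(g10$labels, blob$truth[names(g10$labels)])
  expect_gte(g50$best_loglik, g10$best_loglik)
  expect_identical(classify_gmm(blob$x, blob$samples, 10, 4)$cluster,
                   g10$cluster)
})

test_that("consensus fuses votes and measures concordance correctly", {
  ids <- sprintf("t%02d", 1:10)
  v1 <- setNames(rep(c("FI-like", "OSE-like"), each = 5), ids)
  cc <- consensus_call(list(a = v1, b = v1, c = v1))
  expect_equal(cc$overall_concordance, 1)
  expect_true(all(cc$calls$consensus != "uncertain"))
  expect_true(all(cc$calls$consistency == 1))

  v2 <- v1; v2["t03"] <- "OSE-like"   # one dissenting vote
  cc2 <- consensus_call(list(a = v1, b = v1, c = v2))
  expect_equal(cc2$overall_concordance, 0.9)
  expect_equal(cc2$calls$consensus[cc2$calls$sample_id == "t03"], "uncertain")
  # a 2-of-3 majority survives at the strict-majority threshold
  cc3 <- consensus_call(list(a = v1, b = v1, c = v2), threshold = 0.66)
  expect_equal(cc3$calls$consensus[cc3$calls$sample_id == "t03"], "FI-like")

  expect_error(consensus_call(list(a = v1, b = v1[1:5])), "different samples")
})

test_that("default-cohort classifiers agree with the planted origins", {
  sim <- default_sim(seed = 1)
  co <- sim$cohort
  sig <- call_oriprint(co)
  truth <- setNames(paste0(sim$truth$origin_of_tumor, "-like"),
                    names(sim$truth$origin_of_tumor))
  x <- t(co$beta[signature_cpgs(sig), ])
  pcs <- stats::prcomp(x, center = TRUE, rank. = min(50, nrow(x) - 1))$x
  dm <- diffusion_map(x, knn_k = 20, n_comps = 15)
  votes <- list(
    pearson = classify_pearson_hclust(co, sig),
    louvain = classify_louvain(pcs, co$samples, knn_k = 20, seed = 11),
    density = classify_density(dm$components, co$samples))
  for (v in votes)
    expect_gte(mean(v[names(truth)] == truth), 0.9)
  expect_gte(mean(votes$pearson[names(truth)] == truth), 0.95)

  # GMM in OriPrint space beats GMM in whole-CpG space against truth
  nspace <- fit_normal_space(co, sig, 2L)
  g_sig <- classify_gmm(project_space(nspace, x), co$samples,
                        n_restarts = 100, seed = 3)
  xfull <- t(co$beta)
  pcs_full <- stats::prcomp(xfull, center = TRUE, rank. = 2)$x
  g_full <- classify_gmm(pcs_full, co$samples, n_restarts = 100, seed = 3)
  acc <- function(g) mean(g$labels[names(truth)] == truth)
  expect_gte(acc(g_sig), acc(g_full))
})
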