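test_that("TMM factors are 1 for identical libraries and geometric-mean 1", {
  set.seed(41)
  one <- rpois(50, 100)
  counts <- matrix(rep(one, 4), ncol = 4,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  nm <- tmm_normalize(counts)
  expect_equal(unname(nm$size_factors), rep(1, 4))
  set.seed(42)
  counts2 <- matrix(rnbinom(50 * 4, mu = 200, size = 5), 50, 4,
                    dimnames = dimnames(counts))
  nm2 <- tmm_normalize(counts2)
  expect_equal(exp(mean(log(nm2$size_factors))), 1, tolerance = 1e-9)
  expect_error(tmm_normalize(cbind(counts, z = 0L)), "all-zero")
})

test_that("an exactly doubled library gets identical logCPM", {
  set.seed(43)
  a <- rpois(200, 150) + 1L
  counts <- cbind(s1 = a, s2 = 2L * a, s3 = rpois(200, 140) + 1L)
  rownames(counts) <- paste0("g", 1:200)
  lc <- tmm_normalize(counts)$logcpm
  expect_equal(lc[, "s1"], lc[, "s2"], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("TMM factors match the brute-force trim/weight oracle", {
  set.seed(44)
  counts <- matrix(rpois(18, lambda = rep(c(50, 200, 1000, 30, 500, 80), 3)),
                   nrow = 6, dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  counts[2, 2] <- 600L
  expect_equal(unname(tmm_normalize(counts)$size_factors),
               tmm_oracle(counts), tolerance = 1e-9)
  set.seed(45)
  big <- matrix(rnbinom(400 * 5, mu = exp(runif(400, 2, 7)), size = 3) + 1L,
                400, 5, dimnames = list(paste0("g", 1:400), paste0("s", 1:5)))
  expect_equal(unname(tmm_normalize(big)$size_factors), tmm_oracle(big),
               tolerance = 1e-9)
})

test_that("differential expression recovers planted genes and nothing else", {
  origins <- setNames(rep(c("FI", "OSE"), each = 8), sprintf("s%02d", 1:16))
  ex <- simulate_expression(origins, sim_params(seed = 3))
  lcpm <- tmm_normalize(ex$counts)$logcpm
  de <- differential_expression(lcpm, origins)
  called <- de$gene_id[de$significant]
  planted <- ex$truth$planted_de_genes$gene_id
  expect_gte(mean(planted %in% called), 0.9)
  expect_gte(mean(called %in% planted), 0.9)
  # identical groups: nothing significant
  half <- lcpm[, 1:8]
  de0 <- differential_expression(cbind(half, half),
                                 rep(c("A", "B"), each = 8))
  expect_equal(sum(de0$significant), 0)
  expect_error(differential_expression(lcpm, rep("A", 16)), "two groups")
})

test_that("coherent signature keeps same-signed shared genes only", {
  mk <- function(ids, lfc, sig) data.frame(gene_id = ids, logFC = lfc,
                                           t_stat = 1, p = 0.01, p_adj = 0.01,
                                           significant = sig)
  a <- mk(paste0("g", 1:10), c(rep(2, 5), rep(-2, 2), rep(2, 3)),
          c(rep(TRUE, 7), rep(FALSE, 3)))
  b <- mk(paste0("g", 1:10), rep(2, 10), c(rep(TRUE, 7), rep(FALSE, 3)))
  sig <- build_signature(a, b)   # 5 same-signed + 2 opposite-signed
  expect_equal(nrow(sig), 5)
  expect_setequal(sig$gene_id, paste0("g", 1:5))
  # symmetric in its arguments
  expect_equal(build_signature(b, a), sig)
  # disjoint significant sets: empty, with a warning
  a2 <- mk(paste0("g", 1:4), 2, c(TRUE, TRUE, FALSE, FALSE))
  b2 <- mk(paste0("g", 1:4), 2, c(FALSE, FALSE, TRUE, TRUE))
  expect_warning(s0 <- build_signature(a2, b2), "no coherent")
  expect_equal(nrow(s0), 0)
})

three_blob_cohort <- function(seed = 4, n_side = 25, n_mid = 10, ng = 30) {
  set.seed(seed)
  sig <- structure(data.frame(gene_id = sprintf("g%02d", 1:ng),
                              direction = rep(c(1L, -1L), ng / 2)),
                   class = c("transcriptomic_signature", "data.frame"))
  mk <- function(shift, n)
    vapply(seq_len(n), function(i) rnorm(ng, shift * sig$direction * 2),
           numeric(ng))
  lc <- cbind(mk(-1, n_side), mk(0, n_mid), mk(1, n_side))
  rownames(lc) <- sig$gene_id
  colnames(lc) <- sprintf("s%02d", seq_len(ncol(lc)))
  list(logcpm = lc, signature = sig,
       zone = rep(c("L", "M", "R"), c(n_side, n_mid, n_side)))
}

test_that("external classification keeps extremes and rejects the middle", {
  tb <- three_blob_cohort()
  calls <- classify_external_cohort(tb$logcpm, tb$signature, knn_k = 10,
                                    seed = 3)
  expect_true(all(calls$consensus[tb$zone == "L"] == "FI-like"))
  expect_true(all(calls$consensus[tb$zone == "M"] == "uncertain"))
  expect_true(all(calls$consensus[tb$zone == "R"] == "OSE-like"))
  # deterministic under a fixed seed
  calls2 <- classify_external_cohort(tb$logcpm, tb$signature, knn_k = 10,
                                     seed = 3)
  expect_identical(calls, calls2)
  # flipping the direction convention flips every label
  sig_f <- tb$signature; sig_f$direction <- -sig_f$direction
  calls3 <- classify_external_cohort(tb$logcpm, sig_f, knn_k = 10, seed = 3)
  flip <- c("FI-like" = "OSE-like", "OSE-like" = "FI-like",
            uncertain = "uncertain")
  expect_equal(unname(flip[calls$consensus]), calls3$consensus)
})

test_that("bagging consistency separates clean labels from shuffled ones", {
  ec <- make_expr_classes(n_per = 25, n_genes = 40, sep = 4, seed = 7)
  cfg <- pipeline_config(n_split_shuffles = 30L, n_gene_permutations = 15L,
                         seed = 5)
  bag <- bagging_consistency(ec$x, ec$labels, cfg)
  expect_equal(sum(bag$consensus == "uncertain"), 0)
  expect_true(all(bag$consensus == ec$labels[bag$sample_id]))
  expect_true(all(bag$consistency >= 0.75))

  set.seed(8)
  shuffled <- setNames(sample(ec$labels), names(ec$labels))
  bag_sh <- bagging_consistency(ec$x, shuffled, cfg)
  expect_gt(mean(bag_sh$consensus == "uncertain"), 0.5)
  # clean consistencies stochastically dominate shuffled ones
  wt <- wilcox.test(bag$consistency, bag_sh$consistency,
                    alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 0.01)
  expect_error(bagging_consistency(ec$x, ec$labels[c(1:15, 26:30)], cfg),
               "10 samples")
})
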