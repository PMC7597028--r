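test_that("methylation generator is seeded-deterministic and internally consistent", {
  a <- small_sim(seed = 42)
  b <- small_sim(seed = 42)
  expect_identical(a$cohort$beta, b$cohort$beta)
  expect_identical(a$truth, b$truth)
  # betas strictly inside (0,1); conversion identity
  expect_true(all(a$cohort$beta > 0 & a$cohort$beta < 1))
  expect_equal(a$cohort$m, beta_to_m(a$cohort$beta), tolerance = 1e-12)
  # truth channel well-formed
  expect_true(all(a$truth$planted_dms$cpg_id %in% a$cohort$cpg_ids))
  expect_true(all(a$truth$origin_of_tumor %in% c("FI", "OSE")))
  expect_equal(length(a$truth$origin_of_tumor),
               sum(a$cohort$samples$tissue_class == "TUMOR"))
})

test_that("parameter validation catches impossible designs", {
  expect_error(sim_params(n_origin_dms = 100, n_cpg = 50), "exceeds")
  expect_error(sim_params(origin_fidelity = 1.2), "fidelity")
  expect_error(sim_params(origin_delta_m = -1), "origin_delta_m")
})

test_that("planted origin shift is recovered from the generated matrix", {
  sim <- default_sim(seed = 1)
  co <- sim$cohort
  planted <- sim$truth$planted_dms$cpg_id
  cls <- co$samples$tissue_class
  dm <- rowMeans(co$m[planted, cls == "OSE", drop = FALSE]) -
    rowMeans(co$m[planted, cls == "FI", drop = FALSE])
  expect_lt(abs(mean(abs(dm)) - 2.5) / 2.5, 0.1)
  # direction matches the recorded truth
  expect_gt(mean(sign(dm) == sim$truth$planted_dms$direction), 0.99)
})

test_that("no planted signal means identical FI/OSE marginals", {
  sim <- simulate_methylation(sim_params(n_cpg = 3000, n_origin_dms = 0,
                                         seed = 9))
  expect_equal(nrow(sim$truth$planted_dms), 0)
  co <- sim$cohort
  cls <- co$samples$tissue_class
  dm <- rowMeans(co$m[, cls == "OSE"]) - rowMeans(co$m[, cls == "FI"])
  # group difference is pure noise around zero
  expect_lt(abs(mean(dm)), 0.05)
  suppressWarnings(sig <- call_oriprint(co))
  expect_lte(length(signature_cpgs(sig)), 3000 * 0.01)
})

test_that("perfect fidelity and vanishing noise pin tumors to their origin pattern", {
  sim <- simulate_methylation(sim_params(
    n_cpg = 1000, n_origin_dms = 100, origin_fidelity = 1,
    noise_sd = 1e-9, tumor_fraction_aberrant = 0, seed = 4))
  co <- sim$cohort
  planted <- sim$truth$planted_dms$cpg_id
  cls <- co$samples$tissue_class
  fi_mean <- rowMeans(co$m[planted, cls == "FI", drop = FALSE])
  ose_mean <- rowMeans(co$m[planted, cls == "OSE", drop = FALSE])
  for (tid in names(sim$truth$origin_of_tumor)) {
    target <- if (sim$truth$origin_of_tumor[tid] == "FI") fi_mean else ose_mean
    expect_equal(unname(co$m[planted, tid]), unname(target), tolerance = 1e-4)
  }
})

test_that("expression generator plants the requested fold change", {
  p <- sim_params(seed = 3)
  origins <- setNames(rep(c("FI", "OSE"), each = 8), sprintf("s%02d", 1:16))
  a <- simulate_expression(origins, p)
  b <- simulate_expression(origins, p)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts >= 0))

  lcpm <- tmm_normalize(a$counts)$logcpm
  tr <- a$truth$planted_de_genes
  d <- rowMeans(lcpm[tr$gene_id, origins == "OSE"]) -
    rowMeans(lcpm[tr$gene_id, origins == "FI"])
  expect_lt(abs(mean(d * tr$direction) - p$expr_log2fc) / p$expr_log2fc, 0.15)

  # no effect size -> no planted genes
  z <- simulate_expression(origins, sim_params(expr_log2fc = 0, seed = 3))
  expect_equal(nrow(z$truth$planted_de_genes), 0)
  # single-origin input refused
  expect_error(simulate_expression(rep("FI", 6), p), "per origin")
})

test_that("survival generator obeys the exponential model", {
  origins <- rep(c("FI", "OSE"), each = 50)
  # no censoring, unbounded follow-up: everyone has an event
  sv <- simulate_survival(origins, sim_params(censor_rate = 0,
                                              horizon_days = Inf, seed = 2))
  expect_true(all(sv$event == 1))
  expect_true(all(sv$time_days >= 0))

  # equal hazards: the two groups are exchangeable in law (KS on large n)
  sv2 <- simulate_survival(rep(c("FI", "OSE"), each = 2000),
                           sim_params(hazard_ratio_ose = 1, censor_rate = 0,
                                      horizon_days = Inf, seed = 5))
  ks <- suppressWarnings(ks.test(sv2$time_days[sv2$group == "FI-like"],
                                 sv2$time_days[sv2$group == "OSE-like"]))
  expect_gt(ks$p.value, 0.01)

  # hazard ratio 2: empirical median ratio ~ 2 (exponential medians ~ 1/rate)
  meds <- vapply(1:500, function(r) {
    s <- simulate_survival(rep(c("FI", "OSE"), each = 200),
                           sim_params(hazard_ratio_ose = 2, censor_rate = 0,
                                      horizon_days = Inf, seed = 1000 + r))
    c(median(s$time_days[s$group == "FI-like"]),
      median(s$time_days[s$group == "OSE-like"]))
  }, numeric(2))
  ratio <- mean(meds[1, ] / meds[2, ])
  expect_lt(abs(ratio - 2), 0.1)
})
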