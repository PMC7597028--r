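# Small programmatic fixtures shared across tests.

# Two Gaussian blobs in `d` dimensions, separated along the first axis, with
# the first `n_anchor` points of each blob marked as FI / OSE normals and the
# rest as tumors.
make_blob_cohort <- function(n_per = 20L, d = 2L, sep = 8, n_anchor = 5L,
                             seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * d, 0), ncol = d),
             matrix(stats::rnorm(n_per * d, sep), ncol = d))
  rownames(x) <- sprintf("b%03d", seq_len(2L * n_per))
  cls <- c(rep(c("FI", "TUMOR"), c(n_anchor, n_per - n_anchor)),
           rep(c("OSE", "TUMOR"), c(n_anchor, n_per - n_anchor)))
  samples <- data.frame(sample_id = rownames(x), tissue_class = cls,
                        batch = "b1", stringsAsFactors = FALSE)
  truth <- rep(c("FI-like", "OSE-like"), each = n_per)
  names(truth) <- rownames(x)
  list(x = x, samples = samples, truth = truth[cls == "TUMOR"])
}

# A tiny but realistic methylation cohort for fast unit tests.
small_sim <- function(seed = 1L, ...) {
  simulate_methylation(sim_params(n_cpg = 2000L, n_origin_dms = 150L,
                                  seed = seed, ...))
}

# Default-condition cohort cached per session (used by several test files).
default_sim_cache <- new.env()
default_sim <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(default_sim_cache[[key]]))
    default_sim_cache[[key]] <- simulate_methylation(sim_params(seed = seed))
  default_sim_cache[[key]]
}

# A clean two-class expression matrix (genes x samples) with mean shift
# `sep` on every gene, plus labels.
make_expr_classes <- function(n_per = 30L, n_genes = 40L, sep = 2,
                              seed = 1L) {
  set.seed(seed)
  dir <- rep(c(1, -1), length.out = n_genes)
  x <- cbind(
    vapply(seq_len(n_per), function(i) stats::rnorm(n_genes, -sep / 2 * dir),
           numeric(n_genes)),
    vapply(seq_len(n_per), function(i) stats::rnorm(n_genes, sep / 2 * dir),
           numeric(n_genes)))
  rownames(x) <- sprintf("g%04d", seq_len(n_genes))
  colnames(x) <- sprintf("s%03d", seq_len(2L * n_per))
  labels <- setNames(rep(c("FI-like", "OSE-like"), each = n_per), colnames(x))
  list(x = x, labels = labels, direction = dir)
}
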