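#' Convert methylation beta values to M values
#'
#' The M value is the log2-odds (logit base 2) of the methylation fraction,
#' `m = log2(beta / (1 - beta))`. M values are approximately homoscedastic and
#' are the scale on which differential methylation is tested.
#'
#' @param beta Numeric matrix (or vector) of beta values.
#' @param clip_eps If not `NULL`, beta values are clipped to
#'   `[clip_eps, 1 - clip_eps]` before the transform; if `NULL` (default),
#'   values outside the open interval (0, 1) raise an error.
#' @return Matrix of M values, same shape and dimnames as `beta`.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))
#' @export
beta_to_m <- function(beta, clip_eps = NULL) {
  if (!is.null(clip_eps)) {
    stopifnot(clip_eps > 0, clip_eps < 0.5)
    beta <- pmin(pmax(beta, clip_eps), 1 - clip_eps)
  }
  if (any(!is.na(beta) & (beta <= 0 | beta >= 1)))
    stop("beta_to_m: beta values must lie strictly inside (0, 1); ",
         "pass clip_eps to clip boundary values")
  log2(beta / (1 - beta))
}

#' Convert M values back to beta values
#'
#' Inverse of [beta_to_m()]: `beta = 2^m / (2^m + 1)`.
#'
#' @param m Numeric matrix (or vector) of M values; must be finite.
#' @return Matrix of beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m) & !is.na(m)))
    stop("m_to_beta: M values must be finite")
  # 1 / (1 + 2^-m) is stable for large |m|
  1 / (1 + 2^(-m))
}

#' Assemble a methylation cohort
#'
#' Bundles the CpG-by-sample beta matrix, its M-value counterpart, and the
#' sample sheet, after consistency checks. Either matrix may be supplied; the
#' other is derived through the conversion identity.
#'
#' @param beta CpG x sample beta matrix (rows = CpGs, columns = samples).
#' @param samples Data frame with columns `sample_id`, `tissue_class`
#'   (one of `"FI"`, `"OSE"`, `"TUMOR"`), `batch`, and optionally
#'   `true_origin`.
#' @param m Optional precomputed M matrix; derived from `beta` if missing.
#' @param clip_eps Clipping bound used when deriving M from beta.
#' @return An object of class `methyl_cohort`: list with `beta`, `m`,
#'   `samples`, `cpg_ids`.
#' @export
methyl_cohort <- function(beta, samples, m = NULL, clip_eps = 1e-6) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  if (!all(c("sample_id", "tissue_class", "batch") %in% names(samples)))
    stop("methyl_cohort: sample sheet needs sample_id, tissue_class, batch")
  if (anyDuplicated(samples$sample_id))
    stop("methyl_cohort: sample ids must be unique")
  if (!setequal(colnames(beta), samples$sample_id))
    stop("methyl_cohort: matrix columns and sample sheet disagree")
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  bad <- setdiff(unique(samples$tissue_class), c("FI", "OSE", "TUMOR"))
  if (length(bad))
    stop("methyl_cohort: unknown tissue_class: ", paste(bad, collapse = ", "))
  if (is.null(m)) m <- beta_to_m(beta, clip_eps = clip_eps)
  stopifnot(identical(dim(m), dim(beta)))
  structure(list(beta = beta, m = m, samples = samples,
                 cpg_ids = rownames(beta)),
            class = "methyl_cohort")
}

#' @export
print.methyl_cohort <- function(x, ...) {
  tab <- table(x$samples$tissue_class)
  cat("methyl_cohort: ", nrow(x$beta), " CpGs x ", ncol(x$beta), " samples (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Filter CpG features by missingness and variability
#'
#' Removes CpGs whose fraction of missing values exceeds
#' `max_missing_fraction` or whose standard deviation (computed on beta,
#' missing values removed) falls below `min_sd`. Remaining missing values are
#' rejected: downstream stages assume a complete matrix and no imputation is
#' performed.
#'
#' @param cohort A [methyl_cohort()].
#' @param max_missing_fraction Maximum tolerated per-CpG missing fraction.
#' @param min_sd Minimum per-CpG standard deviation of beta values.
#' @return Filtered `methyl_cohort`.
#' @export
filter_features <- function(cohort, max_missing_fraction = 0, min_sd = 0) {
  stopifnot(inherits(cohort, "methyl_cohort"),
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_sd >= 0)
  beta <- cohort$beta
  miss <- rowMeans(is.na(beta))
  sds <- apply(beta, 1L, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  keep <- miss <= max_missing_fraction & sds >= min_sd
  if (!any(keep))
    stop("filter_features: no CpGs retained (", sum(miss > max_missing_fraction),
         " failed missingness, ", sum(sds < min_sd), " failed min_sd of ",
         length(keep), " total)")
  beta <- beta[keep, , drop = FALSE]
  if (anyNA(beta))
    stop("filter_features: ", sum(is.na(beta)), " missing values remain after ",
         "filtering; tighten max_missing_fraction (no imputation is done)")
  methyl_cohort(beta, cohort$samples, m = cohort$m[keep, , drop = FALSE])
}

#' Two-moment batch adjustment with a protected biological covariate
#'
#' Deterministic location/scale batch correction. Per feature, each
#' (group, batch) cell mean is replaced by the size-weighted group mean
#' pooled over batches (removing the batch location effect while protecting
#' the biological group structure), and the within-cell residuals of each
#' batch are rescaled so that every batch has the pooled residual standard
#' deviation. Group differences are preserved exactly; the operation is
#' exactly idempotent.
#'
#' @param m Feature x sample numeric matrix (typically M values).
#' @param batch Character/factor vector of batch labels, one per column.
#' @param group Character/factor vector of biological group labels to protect.
#' @return Adjusted matrix, same shape and dimnames.
#' @export
batch_adjust <- function(m, batch, group) {
  stopifnot(is.matrix(m), length(batch) == ncol(m), length(group) == ncol(m))
  batch <- as.factor(droplevels(as.factor(batch)))
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(batch) == 1L) return(m)
  if (any(table(batch) < 2L))
    stop("batch_adjust: every batch needs at least 2 samples")
  # Confounding check: each batch holding exactly one group (and vice versa)
  # leaves the batch effect indistinguishable from the biological signal.
  ct <- table(batch, group)
  if (all(rowSums(ct > 0) == 1L) && all(colSums(ct > 0) == 1L))
    stop("batch_adjust: batch and group are confounded; adjustment would ",
         "remove the biological signal")
  cell <- interaction(group, batch, drop = TRUE)
  cell_mat <- stats::model.matrix(~ 0 + cell)
  cell_n <- colSums(cell_mat)
  cell_means <- (m %*% cell_mat) %*% diag(1 / cell_n, nrow = ncol(cell_mat))
  resid <- m - cell_means %*% t(cell_mat)
  # pooled group means (size-weighted over batches) as the protected fit
  grp_mat <- stats::model.matrix(~ 0 + group)
  grp_means <- (m %*% grp_mat) %*% diag(1 / colSums(grp_mat),
                                        nrow = ncol(grp_mat))
  fitted <- grp_means %*% t(grp_mat)
  # residual scale per batch (within-cell df); rescale to the pooled scale
  var_b <- matrix(0, nrow(m), nlevels(batch))
  df_b <- numeric(nlevels(batch))
  for (bi in seq_len(nlevels(batch))) {
    idx <- batch == levels(batch)[bi]
    df_b[bi] <- sum(idx) - length(unique(cell[idx]))
    if (df_b[bi] > 0)
      var_b[, bi] <- rowSums(resid[, idx, drop = FALSE]^2) / df_b[bi]
  }
  pooled_var <- as.vector(var_b %*% df_b) / max(sum(df_b), 1)
  adj <- resid
  for (bi in seq_len(nlevels(batch))) {
    idx <- batch == levels(batch)[bi]
    if (df_b[bi] > 0) {
      scale <- ifelse(var_b[, bi] > 1e-24 & pooled_var > 1e-24,
                      sqrt(pooled_var / var_b[, bi]), 1)
      adj[, idx] <- resid[, idx, drop = FALSE] * scale
    }
  }
  out <- fitted + adj
  dimnames(out) <- dimnames(m)
  out
}

#' Read / write feature-by-sample matrices and sample sheets
#'
#' Tab-separated layout: header row of sample ids, first column the feature
#' id. `read_sample_sheet()` expects at least `sample_id`, `tissue_class`,
#' `batch` columns.
#'
#' @param path File path.
#' @param x Matrix (for writers) with dimnames set.
#' @param id_col Name written for the feature-id column.
#' @return `read_matrix_tsv` returns a numeric matrix; `read_sample_sheet`
#'   a data frame; writers return `path` invisibly.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path, id_col = "feature_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_matrix_tsv
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue_class", "batch") %in% names(df)))
    stop("read_sample_sheet: need sample_id, tissue_class, batch columns")
  df
}
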