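#' TMM normalization and logCPM
#'
#' Trimmed-mean-of-M-values library-size normalization (reference library =
#' the one whose 75th-percentile count fraction is closest to the mean;
#' per-library weighted trimmed mean of gene-wise log ratios, 30% trim on M,
#' 5% on A, inverse-asymptotic-variance weights; factors rescaled to
#' geometric mean 1), delegated to edgeR. logCPM uses a prior count of 0.5
#' scaled proportionally to each effective library size so that exactly
#' proportional libraries receive identical logCPM.
#'
#' @param counts Gene x sample nonnegative count matrix.
#' @return List with `size_factors` (geometric mean 1) and `logcpm`.
#' @export
tmm_normalize <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (ncol(counts) < 2L) stop("tmm_normalize: need at least 2 libraries")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("tmm_normalize: all-zero library: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  sf <- dge$samples$norm.factors
  names(sf) <- colnames(counts)
  logcpm <- edgeR::cpm(dge, log = TRUE, prior.count = 0.5)
  list(size_factors = sf, logcpm = logcpm)
}

#' Two-group differential expression on logCPM
#'
#' Moderated two-group test (shared machinery with the methylation stage; see
#' [moderated_t_test()]) applied to logCPM values, with Benjamini-Hochberg
#' adjustment. A gene is significant when `p_adj < de_fdr` and
#' `|logFC| > de_min_lfc`. The log fold change is the mean of the second
#' factor level minus the first (so `OSE-like` minus `FI-like` for the
#' standard labels).
#'
#' @param logcpm Gene x sample matrix of logCPM values.
#' @param labels Two-level group labels, one per column.
#' @param de_fdr,de_min_lfc Significance thresholds.
#' @return Data frame: `gene_id`, `logFC`, `t_stat`, `p`, `p_adj`,
#'   `significant`.
#' @export
differential_expression <- function(logcpm, labels, de_fdr = 0.05,
                                    de_min_lfc = 0.8) {
  tab <- moderated_t_test(logcpm, labels)
  data.frame(gene_id = tab$feature_id, logFC = tab$delta_m,
             t_stat = tab$t_stat, p = tab$p, p_adj = tab$p_adj,
             significant = tab$p_adj < de_fdr & abs(tab$delta_m) > de_min_lfc,
             stringsAsFactors = FALSE)
}

#' Build the coherent transcriptomic signature
#'
#' Intersects two differential-expression tables (e.g. the cultured-cells and
#' FFPE cohorts) and keeps the genes significant in both with the same fold
#' change sign. Symmetric in its two arguments.
#'
#' @param de_a,de_b Data frames from [differential_expression()].
#' @return Object of class `transcriptomic_signature`: data frame with
#'   `gene_id` and `direction` (`+1` = up in OSE-like).
#' @export
build_signature <- function(de_a, de_b) {
  sa <- de_a[de_a$significant, c("gene_id", "logFC")]
  sb <- de_b[de_b$significant, c("gene_id", "logFC")]
  common <- merge(sa, sb, by = "gene_id", suffixes = c("_a", "_b"))
  coherent <- common[sign(common$logFC_a) == sign(common$logFC_b), ,
                     drop = FALSE]
  if (nrow(coherent) == 0L)
    warning("build_signature: no coherent genes between the two tables")
  out <- data.frame(gene_id = coherent$gene_id,
                    direction = as.integer(sign(coherent$logFC_a)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("transcriptomic_signature", "data.frame"))
}

#' Classify an external expression cohort with the transcriptomic signature
#'
#' Restricts the cohort to signature genes and z-scores each gene, then scans
#' Louvain community detection on a kNN graph over a resolution grid and
#' keeps the most stable resolution (the grid point with maximal mean
#' adjusted Rand agreement with its neighbors). A diffusion map over the same
#' space then locates the two communities at the extremes of the dominant
#' diffusion axis (maximal centroid separation along the first component);
#' those are kept as the robustly stratified samples and every other sample
#' is called `"uncertain"`. The kept clusters are named by signature-direction
#' concordance: the cluster whose mean z-profile agrees more with the up-in-
#' OSE directions is `OSE-like`.
#'
#' @param logcpm Gene x sample logCPM matrix.
#' @param signature A [build_signature()] result.
#' @param resolution_range Length-2 numeric, scanned in steps of 0.1.
#' @param knn_k Neighborhood size (capped below the sample count).
#' @param seed Seed for Louvain.
#' @return Data frame: `sample_id`, `consensus`
#'   (`FI-like`/`OSE-like`/`uncertain`), `cluster`, `score`.
#' @export
classify_external_cohort <- function(logcpm, signature,
                                     resolution_range = c(0.1, 1.5),
                                     knn_k = 15L, seed = 1L) {
  genes <- intersect(signature$gene_id, rownames(logcpm))
  if (length(genes) < 2L)
    stop("classify_external_cohort: cohort shares too few signature genes")
  n <- ncol(logcpm)
  if (n < 10L) stop("classify_external_cohort: need at least 10 samples")
  x <- logcpm[genes, , drop = FALSE]
  z <- (x - rowMeans(x)) / pmax(apply(x, 1L, stats::sd), 1e-12)
  zs <- t(z)                                 # samples x genes
  k <- min(knn_k, n - 1L)
  adj <- knn_adjacency(zs, k)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  grid <- seq(resolution_range[1], resolution_range[2], by = 0.1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  parts <- lapply(grid, function(res) {
    set.seed(seed)
    as.integer(igraph::membership(
      igraph::cluster_louvain(g, resolution = res)))
  })
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  n_comm <- vapply(parts, function(p) length(unique(p)), integer(1))
  if (all(n_comm < 2L))
    stop("classify_external_cohort: fewer than 2 communities at every ",
         "resolution in the scan")
  stability <- vapply(seq_along(grid), function(i) {
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= length(grid)]
    mean(vapply(nb, function(j)
      mclust::adjustedRandIndex(parts[[i]], parts[[j]]), numeric(1)))
  }, numeric(1))
  stability[n_comm < 2L] <- -Inf
  chosen <- which.max(stability)             # ties: lowest resolution
  part <- parts[[chosen]]

  dm <- diffusion_map(zs, knn_k = min(k, n - 1L),
                      n_comps = min(5L, n - 2L))
  cl_ids <- sort(unique(part))
  cent1 <- vapply(cl_ids, function(cl)
    mean(dm$components[part == cl, 1L]), numeric(1))
  keep <- cl_ids[c(which.min(cent1), which.max(cent1))]

  dir_vec <- signature$direction[match(genes, signature$gene_id)]
  score <- vapply(keep, function(cl)
    mean(sign(rowMeans(z[, part == cl, drop = FALSE])) * dir_vec), numeric(1))
  side <- c("FI-like", "FI-like")
  side[which.max(score)] <- "OSE-like"
  if (score[1] == score[2]) side <- c("FI-like", "OSE-like")

  consensus <- rep("uncertain", n)
  consensus[part == keep[1L]] <- side[1L]
  consensus[part == keep[2L]] <- side[2L]
  sample_score <- colMeans(z * dir_vec)
  data.frame(sample_id = colnames(logcpm), consensus = consensus,
             cluster = part, score = sample_score, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bagging-consistency robustness of a two-class stratification
#'
#' Repeatedly draws stratified train/test splits at `train_fraction`; within
#' each split a bagged collection of decision trees is grown on random
#' patches of the training set (each tree sees a random subset of training
#' samples and a random subset of genes) and every tree predicts the test
#' samples. A sample's consistency is the cumulative share of its modal label
#' over all predictions it receives across all iterations (splits x gene
#' patches); samples below `consistency_threshold` are called `"uncertain"`.
#'
#' @param logcpm Gene x sample matrix, typically restricted to the genes that
#'   generated the stratification (e.g. the DE genes).
#' @param initial_labels Named two-class label vector used to train.
#' @param config A [pipeline_config()]; uses `train_fraction`,
#'   `n_split_shuffles`, `n_gene_permutations` (trees per ensemble),
#'   `consistency_threshold`, `seed`.
#' @param patch_samples,patch_features Fractions of training samples / genes
#'   seen by each tree.
#' @return Data frame: `sample_id`, `initial`, `modal`, `consistency`,
#'   `n_test_appearances`, `consensus` (modal label or `"uncertain"`).
#' @export
bagging_consistency <- function(logcpm, initial_labels,
                                config = pipeline_config(),
                                patch_samples = 0.8, patch_features = 0.5) {
  ids <- names(initial_labels)
  stopifnot(!is.null(ids), all(ids %in% colnames(logcpm)))
  lab <- factor(initial_labels)
  if (nlevels(lab) != 2L)
    stop("bagging_consistency: need exactly two initial classes")
  if (any(table(lab) < 10L))
    stop("bagging_consistency: need at least 10 samples per class")
  x <- t(logcpm[, ids, drop = FALSE])        # samples x genes
  n <- nrow(x); p <- ncol(x)
  set.seed(stage_seed(config$seed, "bagging"))
  n_votes <- matrix(0L, n, 2L, dimnames = list(ids, levels(lab)))
  n_seen <- integer(n)
  n_genes_patch <- max(2L, floor(patch_features * p))
  for (s in seq_len(config$n_split_shuffles)) {
    train <- unlist(lapply(levels(lab), function(lv) {
      idx <- which(lab == lv)
      sample(idx, max(2L, round(config$train_fraction * length(idx))))
    }), use.names = FALSE)
    test <- setdiff(seq_len(n), train)
    if (!length(test)) next
    for (b in seq_len(config$n_gene_permutations)) {
      rows <- sample(train, max(4L, round(patch_samples * length(train))))
      if (length(unique(lab[rows])) < 2L) next   # useless patch, skip
      cols <- sample.int(p, n_genes_patch)
      df <- data.frame(y = lab[rows], x[rows, cols, drop = FALSE])
      fit <- rpart::rpart(y ~ ., data = df,
                          method = "class",
                          control = rpart::rpart.control(xval = 0L,
                                                         cp = 0.01,
                                                         maxdepth = 3L,
                                                         minsplit = 5L))
      pred <- predict(fit,
                      newdata = data.frame(x[test, cols, drop = FALSE]),
                      type = "class")
      idx <- cbind(test, as.integer(pred))
      n_votes[idx] <- n_votes[idx] + 1L
      n_seen[test] <- n_seen[test] + 1L
    }
  }
  if (any(n_seen == 0L))
    warning("bagging_consistency: ", sum(n_seen == 0L),
            " samples never appeared in a test split")
  modal_idx <- max.col(n_votes, ties.method = "first")
  consistency <- ifelse(n_seen > 0L,
                        n_votes[cbind(seq_len(n), modal_idx)] / n_seen, NA_real_)
  modal <- levels(lab)[modal_idx]
  consensus <- ifelse(!is.na(consistency) &
                        consistency >= config$consistency_threshold,
                      modal, "uncertain")
  data.frame(sample_id = ids, initial = as.character(lab), modal = modal,
             consistency = consistency, n_test_appearances = n_seen,
             consensus = consensus, row.names = NULL, stringsAsFactors = FALSE)
}
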