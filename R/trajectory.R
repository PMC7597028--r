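#' Diffusion map of a sample-by-feature matrix
#'
#' Builds a symmetrized kNN graph (Euclidean), applies a Gaussian kernel with
#' per-point adaptive bandwidth (the distance to the `knn_k`-th neighbor),
#' removes the sampling-density bias by the anisotropic normalization
#' `K = W / (q q^T)` with `q` the kernel row sums (alpha = 1), and
#' eigendecomposes the row-stochastic transition operator `P = D^-1 K`
#' through its symmetric conjugate. The trivial constant eigenvector
#' (eigenvalue 1) is dropped.
#'
#' @param x Sample x feature numeric matrix with rownames.
#' @param knn_k Neighborhood size; must be smaller than the sample count.
#' @param n_comps Number of nontrivial components to return.
#' @return Object of class `diffusion_result`: `eigenvalues` (descending),
#'   `components` (sample x n_comps, eigenvectors scaled by eigenvalues),
#'   `eigenvectors` (unscaled, for pseudotime), `transition_row_sums`,
#'   `knn_k`, `stationary` (stationary distribution weights).
#' @export
diffusion_map <- function(x, knn_k = 20L, n_comps = 15L) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (knn_k >= n) stop("diffusion_map: knn_k must be below the sample count")
  n_comps <- min(n_comps, n - 1L)
  d <- as.matrix(stats::dist(x))
  sigma <- apply(d, 1L, function(r) sort(r)[knn_k + 1L])
  sigma <- pmax(sigma, 1e-12)
  mask <- matrix(0, n, n)
  for (i in seq_len(n)) mask[i, order(d[i, ])[2:(knn_k + 1L)]] <- 1
  mask <- pmax(mask, t(mask))
  diag(mask) <- 1
  w <- exp(-d^2 / outer(sigma, sigma)) * mask
  # the transition operator needs a connected graph: join any disconnected
  # components through their nearest inter-component pair, with the same
  # adaptive kernel weight
  repeat {
    comp <- graph_components(w > 0)
    if (max(comp) == 1L) break
    best <- NULL; best_d <- Inf
    for (i in seq_len(n)) {
      far <- comp != comp[i]
      if (any(far)) {
        j <- which(far)[which.min(d[i, far])]
        if (d[i, j] < best_d) { best_d <- d[i, j]; best <- c(i, j) }
      }
    }
    w[best[1], best[2]] <- w[best[2], best[1]] <-
      exp(-best_d^2 / (sigma[best[1]] * sigma[best[2]]))
  }
  q <- rowSums(w)
  k_mat <- w / outer(q, q)          # anisotropic, alpha = 1
  deg <- rowSums(k_mat)
  p_mat <- k_mat / deg              # row-stochastic transition matrix
  s <- k_mat / sqrt(outer(deg, deg))
  es <- eigen(s, symmetric = TRUE)
  lam <- es$values
  psi <- es$vectors / sqrt(deg)     # right eigenvectors of P
  # normalize under the degree inner product: psi^T diag(deg) psi = I
  # (eigen returns orthonormal phi, so this already holds)
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; psi <- psi[, ord, drop = FALSE]
  keep <- 2:(n_comps + 1L)
  lam_k <- lam[keep]
  psi_k <- psi[, keep, drop = FALSE]
  rownames(psi_k) <- rownames(x)
  comps <- sweep(psi_k, 2L, lam_k, `*`)
  structure(list(eigenvalues = lam_k, components = comps,
                 eigenvectors = psi_k,
                 transition_row_sums = rowSums(p_mat),
                 knn_k = knn_k, stationary = deg / sum(deg)),
            class = "diffusion_result")
}

# Connected-component labels of a logical adjacency matrix (BFS).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' Diffusion pseudotime from a root sample
#'
#' The diffusion-pseudotime distance between the root and every sample is the
#' Euclidean distance between their accumulated-transition representations,
#' the eigenvectors scaled by `lambda / (1 - lambda)` (the closed form of the
#' summed powers of the transition operator over all timescales).
#'
#' @param result A [diffusion_map()] result.
#' @param root Sample id of the pseudotime origin.
#' @return Object of class `pseudotime_result`: `root_sample_id`, `dpt`
#'   (named, nonnegative, 0 at the root), `scaled_dpt` in \[0, 1\].
#' @export
diffusion_pseudotime <- function(result, root) {
  stopifnot(inherits(result, "diffusion_result"))
  ids <- rownames(result$eigenvectors)
  if (!root %in% ids)
    stop("diffusion_pseudotime: unknown root sample '", root, "'")
  lam <- pmin(result$eigenvalues, 1 - 1e-10)
  scale <- lam / (1 - lam)
  rep_mat <- sweep(result$eigenvectors, 2L, scale, `*`)
  delta <- sweep(rep_mat, 2L, rep_mat[match(root, ids), ])
  dpt <- sqrt(rowSums(delta^2))
  names(dpt) <- ids
  rng <- range(dpt)
  scaled <- if (diff(rng) > 0) (dpt - rng[1]) / diff(rng) else dpt * 0
  structure(list(root_sample_id = root, dpt = dpt, scaled_dpt = scaled),
            class = "pseudotime_result")
}

#' Select a pseudotime root by peripheral position
#'
#' Returns the sample of the requested tissue class with the most extreme
#' (largest absolute) coordinate on the first diffusion component,
#' deterministically tie-broken by sample id order.
#'
#' @param result A [diffusion_map()] result.
#' @param samples Sample sheet with `sample_id` and `tissue_class`.
#' @param tissue_class Class to pick the root from (e.g. `"FI"`).
#' @return Sample id of the selected root.
#' @export
select_root <- function(result, samples, tissue_class) {
  ids <- rownames(result$components)
  cls <- samples$tissue_class[match(ids, samples$sample_id)]
  cand <- which(cls == tissue_class)
  if (!length(cand))
    stop("select_root: no samples of class '", tissue_class, "'")
  v <- abs(result$components[cand, 1L])
  ord <- order(-v, ids[cand])
  ids[cand[ord[1L]]]
}

#' Dual-root pseudotime intersection analysis
#'
#' Given pseudotimes rooted at an FI and an OSE sample, finds the sample
#' where the two scaled pseudotime paths intersect (the argmin of
#' `|scaled_dpt_fi - scaled_dpt_ose|`) and quantifies tumor intermediacy: the
#' fraction of tumors whose rank along the FI-rooted pseudotime lies strictly
#' between the median ranks of the FI and OSE normals.
#'
#' @param dpt_fi,dpt_ose [diffusion_pseudotime()] results over the same
#'   samples, rooted in FI and OSE respectively.
#' @param samples Sample sheet with `sample_id` and `tissue_class`.
#' @return List with `intersection_sample`, `intersection_is_tumor`,
#'   `tumor_intermediacy`, `degenerate` (TRUE when the minimum is tied).
#' @export
intersection_analysis <- function(dpt_fi, dpt_ose, samples) {
  ids <- names(dpt_fi$dpt)
  if (!setequal(ids, names(dpt_ose$dpt)))
    stop("intersection_analysis: pseudotimes cover different samples")
  ids <- sort(ids)
  gap <- abs(dpt_fi$scaled_dpt[ids] - dpt_ose$scaled_dpt[ids])
  best <- which(gap <= min(gap) + 1e-12)
  inter_id <- ids[best[1L]]
  cls <- samples$tissue_class[match(ids, samples$sample_id)]
  rk <- rank(dpt_fi$scaled_dpt[ids], ties.method = "average")
  med_fi <- stats::median(rk[cls == "FI"])
  med_ose <- stats::median(rk[cls == "OSE"])
  lo <- min(med_fi, med_ose); hi <- max(med_fi, med_ose)
  tum <- cls == "TUMOR"
  intermediacy <- if (any(tum)) mean(rk[tum] > lo & rk[tum] < hi) else NA_real_
  list(intersection_sample = inter_id,
       intersection_is_tumor = cls[match(inter_id, ids)] == "TUMOR",
       tumor_intermediacy = intermediacy,
       degenerate = length(best) > 1L)
}
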