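# ---- shared helpers ---------------------------------------------------------

# Symmetrized (union) kNN adjacency over rows of x, Euclidean, edge weight 1.
knn_adjacency <- function(x, k) {
  n <- nrow(x)
  if (k >= n) stop("knn_adjacency: k must be smaller than the sample count")
  d <- as.matrix(stats::dist(x))
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    adj[i, nb] <- 1
  }
  adj <- pmax(adj, t(adj))
  dimnames(adj) <- list(rownames(x), rownames(x))
  adj
}

# Given a 2-cluster partition over all samples, name each cluster's side
# (FI vs OSE) by the normals it contains; a cluster without normals (or an
# ambiguous majority) falls back to the higher mean Pearson correlation of its
# member profiles to the FI vs OSE normal centroid. `x` is sample x feature.
anchor_cluster_sides <- function(cluster, tissue_class, x) {
  stopifnot(length(cluster) == length(tissue_class), nrow(x) == length(cluster))
  cl_ids <- sort(unique(cluster))
  stopifnot(length(cl_ids) == 2L)
  cent_fi <- colMeans(x[tissue_class == "FI", , drop = FALSE])
  cent_ose <- colMeans(x[tissue_class == "OSE", , drop = FALSE])
  # share of each normal class captured by the cluster
  score <- vapply(cl_ids, function(cl) {
    in_cl <- cluster == cl
    fi_share <- if (sum(tissue_class == "FI")) {
      sum(in_cl & tissue_class == "FI") / sum(tissue_class == "FI")
    } else 0
    ose_share <- if (sum(tissue_class == "OSE")) {
      sum(in_cl & tissue_class == "OSE") / sum(tissue_class == "OSE")
    } else 0
    fi_share - ose_share
  }, numeric(1))
  side <- character(2)
  if (score[1] == score[2]) {
    # no informative normals: similarity of cluster centroids to the class
    # centroids (Pearson when the space is rich enough, else distance)
    side <- vapply(cl_ids, function(cl) {
      cent <- colMeans(x[cluster == cl, , drop = FALSE])
      if (ncol(x) >= 3L) {
        if (stats::cor(cent, cent_fi) >= stats::cor(cent, cent_ose)) "FI" else "OSE"
      } else {
        if (sum((cent - cent_fi)^2) <= sum((cent - cent_ose)^2)) "FI" else "OSE"
      }
    }, character(1))
    if (side[1] == side[2])
      warning("anchor_cluster_sides: both clusters resemble the same origin; ",
              "labels are degenerate")
  } else {
    side[which.max(score)] <- "FI"
    side[which.min(score)] <- "OSE"
  }
  names(side) <- as.character(cl_ids)
  side
}

# Turn a 2-cluster partition into per-tumor FI-like / OSE-like labels.
tumor_labels_from_clusters <- function(cluster, samples, x) {
  side <- anchor_cluster_sides(cluster, samples$tissue_class, x)
  lab <- paste0(side[as.character(cluster)], "-like")
  names(lab) <- samples$sample_id
  lab[samples$tissue_class == "TUMOR"]
}

# Beta matrix restricted to signature CpGs, samples in rows.
signature_space <- function(cohort, signature, use = c("beta", "m")) {
  use <- match.arg(use)
  cpgs <- signature_cpgs(signature)
  missing <- setdiff(cpgs, cohort$cpg_ids)
  if (length(missing))
    stop("signature_space: ", length(missing), " signature CpGs absent from cohort")
  t(cohort[[use]][cpgs, , drop = FALSE])
}

# ---- embedding --------------------------------------------------------------

#' Fit the normal-defined OriPrint principal-component space
#'
#' PCA fit on the beta values of the FI and OSE normal samples only,
#' restricted to signature CpGs. Tumors are later projected into this space
#' with [project_space()] but never influence the fit.
#'
#' @param cohort A [methyl_cohort()].
#' @param signature An `oriprint_signature`.
#' @param n_components Number of components to retain.
#' @return Object of class `embedding_space`: `loadings` (feature x
#'   component, orthonormal), `center`, `explained_variance`.
#' @export
fit_normal_space <- function(cohort, signature, n_components = 2L) {
  x <- signature_space(cohort, signature)
  normals <- cohort$samples$tissue_class %in% c("FI", "OSE")
  if (sum(normals) < 3L) stop("fit_normal_space: need at least 3 normal samples")
  xn <- x[normals, , drop = FALSE]
  max_comp <- min(sum(normals) - 1L, ncol(xn))
  if (n_components > max_comp)
    stop("fit_normal_space: n_components (", n_components,
         ") exceeds available rank (", max_comp, ")")
  pc <- stats::prcomp(xn, center = TRUE, scale. = FALSE, rank. = n_components)
  structure(list(loadings = pc$rotation, center = pc$center,
                 explained_variance = pc$sdev[seq_len(n_components)]^2),
            class = "embedding_space")
}

#' @rdname fit_normal_space
#' @param space An `embedding_space`.
#' @param x Sample x feature matrix over the same features.
#' @export
project_space <- function(space, x) {
  stopifnot(inherits(space, "embedding_space"))
  sweep(x, 2L, space$center) %*% space$loadings
}

# ---- classifiers ------------------------------------------------------------

#' Classify tumors by Pearson-correlation hierarchical clustering
#'
#' Computes the 1 - Pearson correlation distance between all samples (normals
#' and tumors) over signature CpGs, clusters with Ward's method ("ward.D2"),
#' cuts the tree into two clusters, and names each cluster's side by the
#' normals it contains (see Details of [consensus_call()] for the anchoring
#' rule).
#'
#' @param cohort A [methyl_cohort()] with normals and tumors.
#' @param signature An `oriprint_signature`.
#' @return Named character vector of per-tumor labels
#'   (`"FI-like"` / `"OSE-like"`).
#' @export
classify_pearson_hclust <- function(cohort, signature) {
  x <- signature_space(cohort, signature)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("classify_pearson_hclust: constant profile (undefined correlation) ",
         "for sample(s): ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  dmat <- stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(dmat, method = "ward.D2")
  cl <- stats::cutree(hc, k = 2L)
  tumor_labels_from_clusters(cl, cohort$samples, x)
}

#' Classify tumors by Louvain community detection on principal components
#'
#' Builds a symmetrized unweighted kNN graph over the supplied principal
#' component coordinates, runs Louvain modularity optimization (seeded), and
#' agglomerates the resulting communities by repeatedly merging the pair with
#' the closest centroids until exactly two remain; tumors are then labeled by
#' normal anchoring.
#'
#' @param coords Sample x component matrix (typically the first
#'   `n_pcs_louvain` principal components of all samples in signature space).
#' @param samples Sample sheet aligned with the rows of `coords`.
#' @param knn_k Neighborhood size.
#' @param seed Seed controlling Louvain's randomized vertex order.
#' @return Named character vector of per-tumor labels.
#' @export
classify_louvain <- function(coords, samples, knn_k = 20L, seed = 1L) {
  stopifnot(nrow(coords) == nrow(samples))
  if (nrow(coords) < knn_k + 1L)
    stop("classify_louvain: need more than knn_k samples")
  adj <- knn_adjacency(coords, knn_k)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = NULL)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    cls_per_comp <- tapply(samples$tissue_class, comp$membership,
                           function(z) length(unique(z[z != "TUMOR"])))
    if (any(comp$csize == 1L) || any(cls_per_comp == 0L))
      stop("classify_louvain: kNN graph disconnected with an unanchored ",
           "component; increase knn_k")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  cl <- igraph::membership(igraph::cluster_louvain(g))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  cl <- merge_to_k_clusters(as.integer(cl), coords, k = 2L)
  tumor_labels_from_clusters(cl, samples, coords)
}

# Merge clusters by nearest centroids until k remain.
merge_to_k_clusters <- function(cluster, coords, k = 2L) {
  cluster <- as.integer(factor(cluster))
  while (length(unique(cluster)) > k) {
    ids <- sort(unique(cluster))
    cent <- t(vapply(ids, function(cl)
      colMeans(coords[cluster == cl, , drop = FALSE]), numeric(ncol(coords))))
    d <- as.matrix(stats::dist(cent))
    diag(d) <- Inf
    pair <- which(d == min(d), arr.ind = TRUE)[1L, ]
    cluster[cluster == ids[pair[2L]]] <- ids[pair[1L]]
  }
  if (length(unique(cluster)) < k)
    stop("merge_to_k_clusters: fewer than ", k, " clusters available")
  as.integer(factor(cluster))
}

#' Classify tumors by density-based hierarchical clustering
#'
#' HDBSCAN-style procedure on diffusion-map coordinates: the mutual
#' reachability distance (pairwise distance floored by each point's core
#' distance, the distance to its `min_pts`-th neighbor) is clustered by
#' single linkage; the hierarchy is cut at increasing depth until at least two
#' clusters of size >= `min_cluster_size` survive. Points in smaller
#' (noise) clusters are reassigned to the nearest surviving centroid, and the
#' two largest survivors form the final bipartition, labeled by normal
#' anchoring.
#'
#' @param coords Sample x coordinate matrix (diffusion-map coordinates).
#' @param samples Sample sheet aligned with `coords`.
#' @param min_pts Core-distance neighborhood size.
#' @param min_cluster_size Minimum size for a cluster to escape noise status.
#' @return Named character vector of per-tumor labels.
#' @export
classify_density <- function(coords, samples, min_pts = 5L,
                             min_cluster_size = 4L) {
  stopifnot(nrow(coords) == nrow(samples))
  n <- nrow(coords)
  if (n <= min_pts) stop("classify_density: too few samples for min_pts")
  d <- as.matrix(stats::dist(coords))
  core <- apply(d, 1L, function(r) sort(r)[min_pts + 1L])
  mreach <- pmax(d, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(mreach) <- 0
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")
  cl <- NULL
  for (k in 2:(n - 1L)) {
    cand <- stats::cutree(hc, k = k)
    sizes <- table(cand)
    if (sum(sizes >= min_cluster_size) >= 2L) { cl <- cand; break }
  }
  if (is.null(cl))
    stop("classify_density: no hierarchy level with 2 density clusters of ",
         "size >= ", min_cluster_size)
  sizes <- sort(table(cl), decreasing = TRUE)
  keep <- as.integer(names(sizes)[1:2])
  cent <- t(vapply(keep, function(k2)
    colMeans(coords[cl == k2, , drop = FALSE]), numeric(ncol(coords))))
  out <- integer(n)
  for (i in seq_len(n)) {
    if (cl[i] %in% keep) {
      out[i] <- match(cl[i], keep)
    } else {  # noise point: nearest surviving centroid
      out[i] <- which.min(colSums((t(cent) - coords[i, ])^2))
    }
  }
  tumor_labels_from_clusters(out, samples, coords)
}

#' Classify tumors by a two-component Gaussian mixture
#'
#' Full-covariance Gaussian mixture fit by EM from `n_restarts` random
#' initializations (two random observations as starting means, the pooled
#' covariance as starting covariance); the restart with the highest
#' log-likelihood wins. Restarts whose EM collapses to a degenerate
#' covariance are discarded. Labels are posterior argmax, named by normal
#' anchoring.
#'
#' @param coords Sample x coordinate matrix (typically the first two
#'   principal components of the normal-defined signature space).
#' @param samples Sample sheet aligned with `coords`.
#' @param n_restarts Number of random EM restarts.
#' @param seed Seed for the restart stream (a prefix of the stream is shared
#'   between runs with different `n_restarts`).
#' @return List with `labels` (per-tumor), `best_loglik`, `cluster`
#'   (per-sample component index).
#' @export
classify_gmm <- function(coords, samples, n_restarts = 2000L, seed = 1L) {
  stopifnot(nrow(coords) == nrow(samples))
  n <- nrow(coords)
  if (n < 4L) stop("classify_gmm: need at least 4 samples")
  x <- as.matrix(coords)
  p <- ncol(x)
  set.seed(seed)
  best <- NULL
  n_ok <- 0L
  for (r in seq_len(n_restarts)) {
    init <- sample.int(n, 2L)
    fit <- tryCatch(gmm_em(x, x[init, , drop = FALSE]), error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("classify_gmm: every EM restart degenerated")
  cl <- max.col(best$resp)
  lab <- tumor_labels_from_clusters(cl, samples, x)
  list(labels = lab, best_loglik = best$loglik, cluster = cl,
       n_effective_restarts = n_ok)
}

# EM for a 2-component full-covariance Gaussian mixture. Errors on
# degenerate covariance so the caller can discard the restart.
gmm_em <- function(x, mu0, max_iter = 200L, tol = 1e-8) {
  n <- nrow(x); p <- ncol(x)
  mu <- mu0
  sig <- stats::cov(x)
  sigma <- list(sig, sig)
  w <- c(0.5, 0.5)
  loglik <- -Inf
  dens <- function(mu_k, sig_k) {
    ch <- tryCatch(chol(sig_k), error = function(e) NULL)
    if (is.null(ch) || any(diag(ch) < 1e-10)) stop("degenerate covariance")
    z <- forwardsolve(t(ch), t(x) - mu_k)
    exp(-0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi))
  }
  for (it in seq_len(max_iter)) {
    f1 <- w[1] * dens(mu[1, ], sigma[[1]])
    f2 <- w[2] * dens(mu[2, ], sigma[[2]])
    tot <- f1 + f2
    if (any(tot <= 0) || any(!is.finite(tot))) stop("degenerate likelihood")
    ll <- sum(log(tot))
    resp <- cbind(f1 / tot, f2 / tot)
    for (k in 1:2) {
      rk <- resp[, k]
      nk <- sum(rk)
      if (nk < 1e-8) stop("empty component")
      mu[k, ] <- colSums(x * rk) / nk
      xc <- sweep(x, 2L, mu[k, ])
      sigma[[k]] <- crossprod(xc * sqrt(rk)) / nk
      w[k] <- nk / n
    }
    if (is.finite(loglik) && abs(ll - loglik) < tol) { loglik <- ll; break }
    loglik <- ll
  }
  list(loglik = loglik, resp = resp, mu = mu, sigma = sigma, weights = w)
}

#' Fuse per-method origin votes into consensus calls
#'
#' Per sample, the consistency is the largest label share among the method
#' votes; the consensus is the majority label when consistency reaches
#' `threshold` and `"uncertain"` otherwise. The overall concordance is the
#' fraction of samples on which *all* methods agree.
#'
#' @param votes Named list of per-sample label vectors (one element per
#'   method); all must cover the same samples.
#' @param threshold Consistency threshold (default 0.75; with three methods a
#'   2-of-3 majority falls below it and becomes uncertain; 0.66 reproduces
#'   strict-majority behavior).
#' @return List with `calls` (data frame: sample_id, one vote column per
#'   method, consistency, consensus) and `overall_concordance`.
#' @export
consensus_call <- function(votes, threshold = 0.75) {
  stopifnot(is.list(votes), length(votes) >= 2L)
  ids <- names(votes[[1]])
  if (is.null(ids)) stop("consensus_call: votes must be named by sample id")
  for (v in votes) {
    if (!setequal(names(v), ids))
      stop("consensus_call: vote sets cover different samples")
  }
  vm <- vapply(votes, function(v) v[ids], character(length(ids)))
  consistency <- apply(vm, 1L, function(r) max(table(r)) / length(r))
  majority <- apply(vm, 1L, function(r) names(which.max(table(r))))
  consensus <- ifelse(consistency >= threshold, majority, "uncertain")
  all_agree <- apply(vm, 1L, function(r) length(unique(r)) == 1L)
  calls <- data.frame(sample_id = ids, vm, consistency = consistency,
                      consensus = consensus, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(calls = calls, overall_concordance = mean(all_agree))
}
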