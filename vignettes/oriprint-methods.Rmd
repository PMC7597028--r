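---
title: "Tracing the cell of origin of high-grade serous ovarian cancer from DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the cell of origin of high-grade serous ovarian cancer from DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriprint)
```

## The scientific problem

High-grade serous ovarian cancer (HGSOC) has two candidate tissues of
origin: the fimbrial epithelium of the distal fallopian tube (FI) and the
ovarian surface epithelium (OSE). DNA methylation is an attractive lineage
tracer because tissue-specific CpG methylation is largely retained through
transformation. The difficulty is that, genome-wide, most methylation
variance in a mixed cohort separates *normal from tumor*, not FI from OSE;
a cell-of-origin signal is invisible in global embeddings. The package
implements the strategy of first learning the set of CpGs that
differentiate the two *normal* epithelia — the **OriPrint** signature — and
then reading tumors only through that subspace, where the retained origin
signal dominates.

The pipeline has five analytical stages:

1. **Signature calling.** A moderated two-group t-test on M values
   (`moderated_t_test()`, `call_oriprint()`) contrasts FI and OSE normals;
   CpGs with Benjamini–Hochberg adjusted p below `dms_alpha = 0.05` and
   |ΔM| above `dms_min_abs_dm = 1` form the signature, split into
   hyper- and hypomethylated-in-OSE sets.
2. **Tumor classification.** Tumors and normals are co-embedded in the
   signature space (beta values) and bipartitioned by three independent
   clustering routes — Ward ("ward.D2") hierarchical clustering on
   1 − Pearson distances, Louvain community detection on a 20-nearest-
   neighbor graph over the leading principal components, and a
   density-based hierarchy on diffusion-map coordinates — plus a
   2-component Gaussian-mixture check on the first two components of the
   normal-defined principal space. Per-method votes are fused by
   `consensus_call()`: a sample whose agreeing-vote share falls below
   `consistency_threshold = 0.75` is *uncertain*.
3. **Trajectory.** `diffusion_map()` and `diffusion_pseudotime()` order
   all samples along diffusion pseudotime twice, rooted once in an FI and
   once in an OSE sample; `intersection_analysis()` asks whether the two
   paths cross inside the tumor cloud and what fraction of tumors rank
   between the two normal groups.
4. **Transcriptomic translation.** Because retrospective FFPE cohorts do
   not support array methylation, the stratification is transferred to
   expression: TMM-normalized logCPM, moderated differential expression
   (FDR < 0.05, |logFC| > 0.8), a coherent signature
   (`build_signature()`: significant and same-signed in both evidence
   cohorts), external-cohort classification with an *uncertain* band
   (`classify_external_cohort()`), and a bagging-consistency robustness
   filter (`bagging_consistency()`, the 75% rule).
5. **Survival.** Kaplan–Meier curves, log-rank tests, median differences
   and Cox proportional hazards (`survival_analysis` functions) compare
   FI-like and OSE-like patients over a 5-year (1826-day) horizon;
   uncertain samples are excluded from contrasts.

## The synthetic cohort: what it emulates

`simulate_methylation()` generates the study conditions all tests run
under. Its default parameters are the design of the two-origin experiment:
12 FI and 8 OSE normals, 24 tumors, 20,000 CpGs, 1,000 planted
origin-differential CpGs with ΔM = 2.5, origin fidelity 0.9.

The generator reproduces four structural features of real cohorts:

* **Bimodal betas.** Baseline per-CpG M values are a two-component mixture
  (means ±3, sd 1), so marginal beta values pile up near 0.1 and 0.9 as on
  arrays.
* **Origin-differential CpGs.** At planted CpGs the FI and OSE means
  straddle the beta = 0.5 midpoint at ±ΔM/2 around a near-zero M center,
  with random direction — the state-switch picture typical of
  tissue-differential methylation. The planted |ΔM| equals
  `origin_delta_m` in expectation, so the detection threshold |ΔM| > 1
  sits well below the planted effect.
* **Tumor variance hierarchy.** All tumors share one random shift field
  (sd `tumor_shift_sd = 2` over a fraction
  `tumor_fraction_aberrant = 0.2` of CpGs) plus i.i.d. noise
  (`noise_sd = 0.5`). The shared field gives the normal-vs-tumor axis a
  squared-M footprint of about 0.2·20000·4 = 16,000 globally — dominating
  the 1000·2.5² = 6,250 origin separation — while its footprint inside the
  signature subspace (≈0.2·1000·4 = 800) stays well below the origin
  separation. This single mechanism reproduces the observed variance
  hierarchy: global embeddings separate normals from tumors, the signature
  subspace separates origins. A shared field (rather than independent
  per-tumor fields) also keeps tumor–tumor similarity above tumor–normal
  similarity.
* **Origin inheritance with drift.** Each tumor copies its origin's mean
  at each planted CpG with probability `origin_fidelity` and the other
  origin's mean otherwise. At fidelity 0.9 tumors sit at roughly the
  0.1/0.9 points of the FI–OSE axis — retaining a classifiable origin
  signal while being measurably intermediate, which is what the dual-root
  pseudotime stage detects. At fidelity 0.5 the origin signal is erased by
  construction and classification accuracy collapses to chance, the
  behavior the fidelity-scan test checks.

Expression (`simulate_expression()`) uses negative-binomial counts
(dispersion 0.1, per-gene mean 2^U(3,10)), library sizes log-uniform over a
4-fold range, and 100 planted DE genes at log2FC = 2 applied symmetrically
around the baseline. Survival (`simulate_survival()`) is exponential with
the OSE-like rate equal to the FI-like rate times `hazard_ratio_ose = 2`
(FI median 1500 days, a realistic HGSOC overall-survival scale), uniform
censoring with probability `censor_rate = 0.15` inside the follow-up
window, and administrative censoring at `horizon_days = 3650`; with an
unbounded horizon the censoring window falls back to the 99.9th percentile
of the slower arm.

What the generator does **not** emulate: array probe chemistry and probe-
level artifacts, copy-number-driven methylation change, correlated CpG
blocks (planted CpGs are independent), cohort-specific batch structure
(batches must be injected explicitly to exercise `batch_adjust()`), and
non-proportional hazards. Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes, not that real cohorts satisfy
those assumptions.

## Numerical and design choices

* **Beta vs M.** Differential methylation is tested on M values (the
  approximately homoscedastic scale); clustering, embeddings and
  pseudotime run on beta values. Betas are clipped to
  [1e-6, 1 − 1e-6] before the logit so M stays finite.
* **Moderated t.** The prior degrees of freedom and prior variance are
  estimated by moment matching of the log residual variances: the excess
  of `var(log s²)` over `trigamma(d/2)` identifies `trigamma(d0/2)`
  (inverted by Newton iteration); a non-positive excess yields `d0 = ∞`
  (full pooling). `d0 = 0` reproduces the ordinary pooled t exactly, which
  is how the implementation is cross-checked against a brute-force oracle;
  it is also compared against limma on random matrices in the test suite.
  Trend and robust variants are deliberately off.
* **Batch adjustment** is a deterministic two-moment stand-in for
  empirical-Bayes batch correction: per feature, each (group, batch) cell
  mean is replaced by the pooled group mean and within-cell residuals are
  rescaled to the pooled per-batch scale. The construction is exactly
  idempotent and preserves group differences exactly; confounded designs
  (batch ≡ group) are refused. Pre-corrected matrices can be supplied
  instead, so a full empirical-Bayes implementation is pluggable.
* **Diffusion maps.** Symmetrized kNN graph (k = 20, the neighborhood
  size used throughout), Gaussian kernel with per-point adaptive bandwidth
  (distance to the k-th neighbor), anisotropic density normalization
  (α = 1), eigendecomposition through the symmetric conjugate of the
  transition operator. A disconnected graph makes cross-component
  pseudotime meaningless, so components are joined through their nearest
  inter-component pair before normalization (with the same kernel); this
  happens on small cohorts whenever the two origin lobes are farther apart
  than any within-lobe neighborhood. Pseudotime uses 15 components with
  the accumulated-transition scaling λ/(1 − λ), eigenvalues capped at
  1 − 1e-10.
* **Roots and intersection.** The paper chose pseudotime roots visually by
  peripheral position; here the root of each class is the sample with the
  most extreme first-component coordinate, tie-broken by sample id. The
  "paths intersect centrally in the tumors" claim is operationalized as:
  the sample minimizing |scaled FI-rooted pseudotime − scaled OSE-rooted
  pseudotime| (ties flagged degenerate, first id wins), plus a tumor
  intermediacy score — the fraction of tumors whose FI-rooted rank lies
  strictly between the median ranks of the FI and OSE normals.
* **Cluster anchoring.** Clusters are named by the normals they capture
  (share of FI normals minus share of OSE normals); a tie (e.g. a cluster
  with no normals) falls back to similarity of the cluster centroid to the
  FI vs OSE centroids — Pearson correlation in ≥3 dimensions, Euclidean
  distance below that. If both clusters resolve to the same side the
  labels are degenerate and a warning is raised rather than an error: this
  happens by construction when clustering a space (such as the whole-CpG
  space) whose dominant axis is not the origin axis.
* **Louvain and GMM.** Louvain runs under a fixed seed on an unweighted
  union-kNN graph; its communities are agglomerated by nearest-centroid
  merging until exactly two remain. The Gaussian mixture is fit by EM with
  full covariances from 2000 random restarts (two random observations as
  means, pooled covariance); restarts that collapse (non-positive-definite
  covariance, empty component) are discarded and the best log-likelihood
  wins. The restart stream is a seeded prefix, so the best log-likelihood
  is non-decreasing in the number of restarts.
* **Density clustering** is an HDBSCAN-style construction: single linkage
  on mutual-reachability distances (core distance = distance to the 5th
  neighbor), the hierarchy cut at increasing depth until at least two
  clusters of size ≥ 4 survive, smaller clusters treated as noise and
  reassigned to the nearest surviving centroid, and the two largest
  survivors forming the bipartition.
* **logCPM.** TMM size factors come from the trimmed-mean definition
  (30% trim on M, 5% on A, inverse-variance weights, geometric mean 1).
  The prior count (0.5) is scaled proportionally to each effective library
  size, so exactly proportional libraries receive identical logCPM — the
  property a fixed offset would break.
* **Resolution scan.** "Most stable clusters" is operationalized as the
  resolution grid point (0.1 to 1.5, step 0.1) whose partition has the
  highest mean adjusted Rand index with its grid neighbors; ties resolve
  to the lower resolution. The two retained communities are those at the
  extremes of the first diffusion component. The full diffusion metric is
  unsuitable for this selection: a small, weakly connected intermediate
  cluster legitimately has large diffusion distances to everything and
  would masquerade as "most distant", while the intent is the two ends of
  the main axis.
* **Bagging consistency.** The published procedure permutes the model
  genes 1000 times and the train/test split 1000 times. Running a full
  convergent ensemble per (split × gene set) combination is computationally
  prohibitive at any scale, so the two loops are composed differently with
  the same ingredients: each of `n_split_shuffles` stratified 70/30 splits
  grows `n_gene_permutations` depth-3 trees, each on a random patch (80%
  of training samples × 50% of genes), and every tree predicts the test
  samples. Consistency is the cumulative modal-label share over all
  predictions a sample receives; the 75% rule then defines *uncertain*.
  Pooling tree-level votes (rather than per-split ensemble majorities) is
  what makes the statistic sensitive: ensemble majorities smooth away
  exactly the instability the rule is meant to expose. Defaults are the
  scaled-down 100 × 100 setting; the full 1000 × 1000 is reachable through
  `pipeline_config()`.
* **Survival.** Breslow tie handling for Cox; log-rank with the exact
  hypergeometric variance; the 5-year restriction truncates times at the
  horizon and censors them (idempotent); continuous Cox covariates can be
  dichotomized at a quantile. Uncertain samples never enter two-group
  contrasts.
* **Seeding.** A single master seed is expanded into independent named
  per-stage streams (`stage_seed`), so changing one stage's internals
  cannot perturb another stage's draws; every generator and every seeded
  method is bit-reproducible.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
the default design above (44 methylation samples × 20,000 CpGs; expression
cohorts of 16–150 samples × 400–2,000 genes; survival cohorts of 100–400
patients; 20-seed trajectory replication; 100-replicate survival power and
20-replicate false-discovery checks; bagging at the 100 × 100 setting).
These sizes were chosen so that every property is measurable with clear
Monte-Carlo margins while the whole suite runs in minutes on one CPU.

## Known limitations

* The three clustering routes share the same signature space; their
  consensus measures method-robustness, not independent evidence.
* With three voting methods the default 0.75 consistency threshold turns
  every 2-of-3 majority into *uncertain*; a threshold of 0.66 restores
  strict-majority behavior (`consensus_call(threshold = 0.66)`).
* The moderated test applied to logCPM is a Gaussian working model for
  count data; it matches the published thresholds but is not a
  negative-binomial likelihood.
* Root selection assumes the first diffusion component aligns with the
  origin axis, which holds in signature space but not necessarily in
  arbitrary embeddings.
* The density-based route needs both origin lobes populated well above its
  minimum cluster size (4); very small cohorts should rely on the
  hierarchical route.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(sim_params(seed = 1), pipeline_config(seed = 1),
                    out_dir = "oriprint_run")
str(res$report)
```

The report collects the signature size and composition, the three-method
concordance, the pseudotime intersection verdict and tumor intermediacy,
the transcriptomic signature size, the uncertain fraction after the
bagging filter, and the log-rank / Cox summary of the survival contrast.
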