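# oriprint

Cell-of-origin tracing of high-grade serous ovarian cancer (HGSOC) from DNA
methylation, with transcriptomic transfer and survival stratification.

## The problem

HGSOC can arise from two epithelia: the fimbrial epithelium of the distal
fallopian tube (**FI**) or the ovarian surface epithelium (**OSE**).
Genome-wide, methylation variance in a mixed cohort is dominated by the
normal-vs-tumor axis, so global embeddings cannot split tumors by origin.
`oriprint` implements the two-step strategy of (1) learning the CpG set that
separates the two *normal* tissues — the **OriPrint** signature — and
(2) reading tumors only through that subspace, where the epigenetic trace of
the cell of origin is retained.

The statistical core:

* **Signature.** Per CpG, a moderated t statistic on M values
  (`m = log2(beta / (1 - beta))`) with moment-matched empirical-Bayes
  variance shrinkage,
  `t = (mean_OSE - mean_FI) / (s_post * sqrt(1/n1 + 1/n2))`; signature CpGs
  satisfy BH-adjusted `p < 0.05` and `|dM| > 1`, split into hyper- and
  hypomethylated in OSE.
* **Consensus classification.** Tumors are bipartitioned in signature space
  by Ward (`ward.D2`) clustering on `1 - r` Pearson distances, Louvain
  communities on a 20-NN graph over the top principal components, and a
  density hierarchy on diffusion-map coordinates, plus a 2-component
  Gaussian-mixture check (best of 2000 EM restarts). Votes below 75%
  agreement are called `uncertain`.
* **Trajectory.** Diffusion pseudotime rooted in FI and in OSE; the package
  tests whether the two paths intersect inside the tumor cloud and what
  fraction of tumors rank between the two normal groups.
* **Transcriptomic transfer.** TMM/logCPM normalization, moderated
  differential expression (`FDR < 0.05`, `|logFC| > 0.8`), a coherent
  two-cohort gene signature, Louvain resolution-scan classification of
  external cohorts with an `uncertain` band, and a bagging-consistency
  filter (random-patch decision trees, 75% rule).
* **Survival.** Kaplan-Meier, log-rank, median differences and Cox
  proportional hazards over a 5-year horizon, excluding uncertain samples.

A first-class synthetic-cohort module (`simulate_methylation()`,
`simulate_expression()`, `simulate_survival()`) generates methylation,
expression and survival data with known ground truth and the variance
hierarchy above, so the full pipeline is exercisable without any downloads.

## A worked example

```r
library(oriprint)
res <- run_pipeline(sim_params(seed = 1), pipeline_config(seed = 1),
                    out_dir = "oriprint_run")
str(res$report)
#> List of 15
#>  $ signature_size               : int 1000
#>  $ signature_hyper              : int 498
#>  $ signature_hypo               : int 502
#>  $ concordance                  : num 1
#>  $ gmm_best_loglik              : num -93
#>  $ intersection_sample          : chr "T_22"
#>  $ intersection_is_tumor        : logi TRUE
#>  $ tumor_intermediacy           : num 0.833
#>  $ transcriptomic_signature_size: int 100
#>  $ uncertain_fraction           : num 0
#>  $ logrank_chi2                 : num 20.6
#>  $ logrank_p                    : num 5.63e-06
#>  $ median_difference_days       : num 1095
#>  $ cox_hr_ose                   : num 2.45
```

Reading the report: all 1,000 planted origin-differential CpGs are
recovered (498 hyper- / 502 hypomethylated in OSE); the three clustering
routes agree on 100% of the 24 tumors; the FI- and OSE-rooted pseudotime
paths intersect at a tumor, and 83% of tumors rank between the two normal
groups; the transcriptomic signature carries all 100 planted DE genes; no
sample of the (cleanly bimodal) synthetic retrospective cohort is flagged
uncertain; and the survival contrast recovers the planted hazard ratio of 2
(Cox HR 2.45 on the 5-year window, log-rank p = 5.6e-06, median difference
1,095 days in favor of FI-like patients).

Per-stage functions (`call_oriprint()`, `classify_pearson_hclust()`,
`diffusion_pseudotime()`, `bagging_consistency()`, `logrank_test()`, ...)
expose every step individually; a thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`. The methods vignette
(`vignettes/oriprint-methods.Rmd`) documents the model, every tunable
parameter, and the design decisions.

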