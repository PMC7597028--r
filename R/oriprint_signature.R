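# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear; used by the moment estimator of the prior df.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated two-group t-test across features
#'
#' Empirical-Bayes moderated t statistic for a two-group comparison, computed
#' per feature (row): the pooled within-group variance `s2` with `d` residual
#' degrees of freedom is shrunk toward a prior variance `s0^2` with prior
#' degrees of freedom `d0`,
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)`, and
#' `t = delta / (s_post * sqrt(1/n1 + 1/n2))` is referred to a t distribution
#' on `d0 + d` degrees of freedom. The prior `(d0, s0^2)` is estimated by
#' moment matching of the log variances across features (the variance of
#' `log(s2)` in excess of `trigamma(d/2)` identifies `trigamma(d0/2)`).
#' With `d0 = 0` the statistic reduces to the ordinary pooled-variance t.
#'
#' @param m Feature x sample numeric matrix.
#' @param labels Two-level factor (or character) of group membership, one per
#'   column. `delta` is the mean of the second factor level minus the first
#'   (levels sorted alphabetically unless a factor is supplied), so with
#'   labels `FI`/`OSE` it is `mean(OSE) - mean(FI)`.
#' @param d0 Optional prior degrees-of-freedom override (`0` disables
#'   shrinkage, `Inf` fully pools); estimated from the data when `NULL`.
#' @return Data frame with one row per feature: `feature_id`, `delta_m`,
#'   `t_stat`, `df_total`, `p`, `p_adj` (Benjamini-Hochberg).
#' @export
moderated_t_test <- function(m, labels, d0 = NULL) {
  stopifnot(is.matrix(m), length(labels) == ncol(m))
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(f) != 2L)
    stop("moderated_t_test: exactly two groups required, got ", nlevels(f))
  n1 <- sum(f == levels(f)[1]); n2 <- sum(f == levels(f)[2])
  if (n1 < 2L || n2 < 2L)
    stop("moderated_t_test: each group needs at least 2 samples (",
         levels(f)[1], "=", n1, ", ", levels(f)[2], "=", n2, ")")
  if (nrow(m) < 2L)
    stop("moderated_t_test: at least 2 features required for shrinkage")
  i1 <- f == levels(f)[1]; i2 <- f == levels(f)[2]
  m1 <- rowMeans(m[, i1, drop = FALSE]); m2 <- rowMeans(m[, i2, drop = FALSE])
  delta <- m2 - m1
  ss1 <- rowSums((m[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, i2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / d

  if (is.null(d0)) {
    ok <- s2 > 1e-300
    if (sum(ok) >= 2L) {
      z <- log(s2[ok])
      excess <- stats::var(z) - trigamma(d / 2)
      if (is.finite(excess) && excess > 0) {
        d0 <- 2 * trigamma_inverse(excess)
        s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                     digamma(d0 / 2) - log(d0 / 2))
      } else {
        d0 <- Inf
        s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
      }
    } else {
      d0 <- 0; s02 <- 0
    }
  } else {
    s02 <- if (d0 > 0) {
      ok <- s2 > 1e-300
      if (any(ok)) exp(mean(log(s2[ok])) - digamma(d / 2) + log(d / 2)) else 0
    } else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  df_total <- min(d0 + d, .Machine$double.xmax)
  p <- 2 * stats::pt(abs(t_stat), df = df_total, lower.tail = FALSE)
  p[se == 0 & delta == 0] <- 1
  data.frame(feature_id = rownames(m) %||% seq_len(nrow(m)),
             delta_m = delta, t_stat = t_stat, df_total = df_total,
             p = p, p_adj = bh_adjust(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (`p * n / rank` with a cumulative minimum from
#' the largest p downward, capped at 1). Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call the OriPrint cell-of-origin methylation signature
#'
#' Tests every CpG for differential methylation between the FI and OSE normal
#' samples of the cohort (moderated t on M values) and retains CpGs with
#' BH-adjusted p below `dms_alpha` and |delta M| above `dms_min_abs_dm`,
#' split by direction: hypermethylated in OSE (`delta_m > 0`) versus
#' hypomethylated in OSE.
#'
#' @param cohort A [methyl_cohort()] containing FI and OSE samples (tumors,
#'   if present, are ignored by the test).
#' @param config A [pipeline_config()]; uses `dms_alpha`, `dms_min_abs_dm`.
#' @return Object of class `oriprint_signature`: list with `hyper_in_ose`,
#'   `hypo_in_ose` (CpG id vectors), `thresholds`, and the full `dms_table`.
#' @export
call_oriprint <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "methyl_cohort"))
  normals <- cohort$samples$tissue_class %in% c("FI", "OSE")
  cls <- cohort$samples$tissue_class[normals]
  if (!all(c("FI", "OSE") %in% cls))
    stop("call_oriprint: cohort must contain both FI and OSE samples")
  tab <- moderated_t_test(cohort$m[, normals, drop = FALSE],
                          factor(cls, levels = c("FI", "OSE")))
  sig <- tab$p_adj < config$dms_alpha & abs(tab$delta_m) > config$dms_min_abs_dm
  hyper <- tab$feature_id[sig & tab$delta_m > 0]
  hypo <- tab$feature_id[sig & tab$delta_m < 0]
  if (length(hyper) + length(hypo) == 0L)
    warning("call_oriprint: empty signature at the requested thresholds")
  structure(list(hyper_in_ose = hyper, hypo_in_ose = hypo,
                 thresholds = list(dms_alpha = config$dms_alpha,
                                   dms_min_abs_dm = config$dms_min_abs_dm),
                 dms_table = tab),
            class = "oriprint_signature")
}

#' @export
print.oriprint_signature <- function(x, ...) {
  cat("OriPrint signature: ", length(x$hyper_in_ose) + length(x$hypo_in_ose),
      " DMS (", length(x$hyper_in_ose), " hyper / ", length(x$hypo_in_ose),
      " hypo in OSE) at adj p < ", x$thresholds$dms_alpha, ", |dM| > ",
      x$thresholds$dms_min_abs_dm, "\n", sep = "")
  invisible(x)
}

#' @rdname call_oriprint
#' @param signature An `oriprint_signature`.
#' @export
signature_cpgs <- function(signature) {
  stopifnot(inherits(signature, "oriprint_signature"))
  c(signature$hyper_in_ose, signature$hypo_in_ose)
}
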