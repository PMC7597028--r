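#' Restrict survival records to a follow-up horizon
#'
#' Times beyond `horizon_days` are truncated to the horizon and their event
#' indicator set to 0 (administrative censoring); the operation is
#' idempotent. The default pipeline horizon is 5 years (1826 days).
#'
#' @param records Data frame with `time_days` and `event` columns.
#' @param horizon_days Positive horizon.
#' @return Records with truncated times.
#' @export
restrict_followup <- function(records, horizon_days = 1826) {
  stopifnot(horizon_days > 0, all(c("time_days", "event") %in% names(records)))
  over <- records$time_days > horizon_days
  records$event[over] <- 0L
  records$time_days[over] <- horizon_days
  records
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct event times, via the survival package. The median is the smallest
#' time at which the curve falls to 0.5 or below (flagged undefined when it
#' never does).
#'
#' @param records Data frame with `time_days` and `event`.
#' @return Object of class `km_curve`: `event_times`, `survival`, `at_risk`,
#'   `events`, `median` (NA when undefined), `median_defined`.
#' @export
kaplan_meier <- function(records) {
  stopifnot(nrow(records) >= 1L)
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1,
                           data = records)
  keep <- fit$n.event > 0
  surv <- fit$surv[keep]
  times <- fit$time[keep]
  med_idx <- which(surv <= 0.5)
  med <- if (length(med_idx)) times[med_idx[1L]] else NA_real_
  structure(list(event_times = times, survival = surv,
                 at_risk = fit$n.risk[keep], events = fit$n.event[keep],
                 median = med, median_defined = length(med_idx) > 0),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", sum(x$events), " events over ",
      length(x$event_times), " distinct times; median = ",
      if (x$median_defined) paste0(x$median, " days") else "undefined",
      "\n", sep = "")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with the exact hypergeometric variance at each
#' distinct event time (ties included), referred to chi-square with 1 degree
#' of freedom; via [survival::survdiff()].
#'
#' @param group_a,group_b Data frames with `time_days`, `event`.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) == 0L || nrow(group_b) == 0L)
    stop("logrank_test: both groups must be non-empty")
  if (sum(group_a$event) + sum(group_b$event) == 0L)
    stop("logrank_test: no events in either group")
  df <- rbind(data.frame(time_days = group_a$time_days, event = group_a$event,
                         g = "A"),
              data.frame(time_days = group_b$time_days, event = group_b$event,
                         g = "B"))
  sd_fit <- survival::survdiff(survival::Surv(time_days, event) ~ g, data = df)
  chi2 <- sd_fit$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Difference of median survival between two curves
#'
#' @param km_a,km_b [kaplan_meier()] curves.
#' @return List with `days` (`median_a - median_b`; NA when undefined) and
#'   `defined`.
#' @export
median_difference <- function(km_a, km_b) {
  if (!km_a$median_defined || !km_b$median_defined)
    return(list(days = NA_real_, defined = FALSE))
  list(days = km_a$median - km_b$median, defined = TRUE)
}

#' Cox proportional hazards model over origin calls
#'
#' Fits a Cox model (Breslow tie handling) on the supplied covariates via
#' [survival::coxph()]. Continuous covariates can be dichotomized at a
#' quantile threshold first with [dichotomize_quantile()]. Constant
#' covariates raise an error; possible monotone-likelihood separation is
#' flagged from coxph warnings.
#'
#' @param records Data frame with `time_days`, `event`, and the covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @return Data frame: `term`, `hr`, `ci_lo`, `ci_hi`, `p`, plus attribute
#'   `"separation"` (logical).
#' @export
cox_ph <- function(records, covariates) {
  stopifnot(all(covariates %in% names(records)),
            sum(records$event) > 0)
  for (cv in covariates) {
    if (length(unique(records[[cv]])) < 2L)
      stop("cox_ph: covariate '", cv, "' is constant")
  }
  fml <- stats::as.formula(paste("survival::Surv(time_days, event) ~",
                                 paste(covariates, collapse = " + ")))
  sep <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  out <- data.frame(term = rownames(sm$coefficients),
                    hr = sm$coefficients[, "exp(coef)"],
                    ci_lo = sm$conf.int[, "lower .95"],
                    ci_hi = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "separation") <- sep
  out
}

#' @rdname cox_ph
#' @param x Numeric vector.
#' @param q Quantile used as the dichotomization threshold.
#' @return Factor with levels `"low"`, `"high"`.
#' @export
dichotomize_quantile <- function(x, q = 0.5) {
  thr <- stats::quantile(x, q, na.rm = TRUE)
  factor(ifelse(x > thr, "high", "low"), levels = c("low", "high"))
}
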