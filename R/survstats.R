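## Standard time-to-event estimators on (reconstructed or simulated) IPD.
## Model fitting is delegated to the survival package; the thin wrappers
## here fix the conventions used throughout (Efron ties, complementary
## log-log median bands, exact normal quantiles) and expose step-function
## containers the reconstruction and RMST code can consume directly.

#' Kaplan-Meier product-limit estimate with Greenwood variance
#'
#' Wraps [survival::survfit()] and keeps, at every event time, the step
#' value, its Greenwood variance, and the at-risk and event counts.
#' Censorings sharing a time with events leave the risk set after the
#' events.
#'
#' @param ipd a data frame accepted by [as_ipd()] (single arm assumed; all
#'   rows are used regardless of arm label).
#' @return An object of class `km_estimate` with fields `event_times`,
#'   `surv`, `var_greenwood`, `n_risk_at`, `n_events_at`, `n_total`, and
#'   `max_time` (last observed time, the follow-up limit for RMST).
#' @export
kaplan_meier <- function(ipd) {
  ipd <- as_ipd(ipd)
  if (nrow(ipd) == 0L) stop("empty dataset")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd,
                          conf.type = "none")
  i <- sf$n.event > 0
  # sf$std.err is the SE of the cumulative hazard, i.e. sqrt of the
  # Greenwood sum; scaling by S gives the Greenwood variance of S itself.
  # Where S has reached 0 the variance is taken as 0.
  vg <- (sf$surv[i] * sf$std.err[i])^2
  vg[sf$surv[i] == 0] <- 0
  structure(
    list(event_times = sf$time[i],
         surv = sf$surv[i],
         var_greenwood = vg,
         n_risk_at = sf$n.risk[i],
         n_events_at = sf$n.event[i],
         n_total = nrow(ipd),
         max_time = max(ipd$time)),
    class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf(
    "KM estimate: n = %d, %d event times, follow-up to %g months, S(last event) = %.3f\n",
    x$n_total, length(x$event_times), x$max_time,
    if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' Evaluate a KM estimate as a right-continuous step function
#'
#' @param km a `km_estimate`.
#' @param times numeric vector of evaluation times.
#' @return Survival probabilities; 1 before the first event time.
#' @export
km_survival_at <- function(km, times) {
  stopifnot(inherits(km, "km_estimate"))
  c(1, km$surv)[findInterval(times, km$event_times) + 1L]
}

#' Median survival with complementary log-log confidence bounds
#'
#' The median is the smallest event time at which the survival estimate
#' drops to 0.5 or below; `NA` means not reached.  Confidence bounds are the
#' smallest times at which the lower and upper complementary log-log
#' confidence bands cross 0.5 (the band is bounded in `[0, 1]`).
#'
#' @param km a `km_estimate`.
#' @param level two-sided confidence level (default 0.95).
#' @return A list with `median`, `ci` (`lower`, `upper`; `NA` = not
#'   reached).
#' @export
median_survival <- function(km, level = 0.95) {
  stopifnot(inherits(km, "km_estimate"))
  z <- z_quantile(level)
  s <- km$surv
  first_at_or_below <- function(vals) {
    j <- which(vals <= 0.5)
    if (length(j)) km$event_times[j[1L]] else NA_real_
  }
  # cloglog band: S^exp(+-z * se(log(-log S)))
  se_cll <- ifelse(s > 0 & s < 1,
                   sqrt(km$var_greenwood) / (s * abs(log(s))), 0)
  lower_band <- ifelse(s > 0 & s < 1, s^exp(z * se_cll), s)
  upper_band <- ifelse(s > 0 & s < 1, s^exp(-z * se_cll), s)
  list(median = first_at_or_below(s),
       ci = c(lower = first_at_or_below(lower_band),
              upper = first_at_or_below(upper_band)))
}

#' Two-sample log-rank test
#'
#' @param ipd IPD data frame containing both arms.
#' @param arm_a,arm_b arm labels to compare.
#' @return A list with `chi_square` (1 df) and `p`.
#' @export
logrank <- function(ipd, arm_a, arm_b) {
  ipd <- as_ipd(ipd)
  sub <- ipd[ipd$arm %in% c(arm_a, arm_b), ]
  for (a in c(arm_a, arm_b))
    if (!any(sub$arm == a)) stop("arm label not present: ", a)
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = sub)
  chi <- unname(sd$chisq)
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit for a multi-level treatment factor
#'
#' Fits the partial likelihood with the treatment as a factor (non-reference
#' arms as indicators) using the Efron tie correction — reconstructed IPD
#' has many tied event times by construction.  Reports per-arm hazard
#' ratios versus the reference with Wald confidence intervals, plus the
#' likelihood-ratio and Wald chi-square statistics against the null model
#' on (number of arms - 1) degrees of freedom.
#'
#' @param ipd IPD data frame with >= 2 arms and >= 1 event.
#' @param reference_arm label of the reference (comparator) arm.
#' @param ci_level two-sided level for the hazard-ratio CIs (default 0.95).
#' @param strata_trial if `TRUE`, stratify the baseline hazard by
#'   `trial_id`.
#' @return An object of class `cox_result` with `coef`, `se`, `hr`, `ci`
#'   (matrix with `lower`/`upper` columns), `vcov`, `lrt_stat`, `lrt_df`,
#'   `lrt_p`, `wald_stat`, `wald_p`, `reference_arm`, `ci_level`.
#' @export
cox_fit <- function(ipd, reference_arm, ci_level = 0.95,
                    strata_trial = FALSE) {
  ipd <- as_ipd(ipd)
  arms <- unique(ipd$arm)
  if (length(arms) < 2L) stop("need >= 2 arms for a Cox fit")
  if (!reference_arm %in% arms)
    stop("reference arm not present: ", reference_arm)
  if (sum(ipd$event) == 0L)
    stop("no events: the partial likelihood carries no information")
  ipd$arm <- factor(ipd$arm,
                    levels = c(reference_arm, sort(setdiff(arms, reference_arm))))
  fml <- if (strata_trial)
    survival::Surv(time, event) ~ arm + survival::strata(trial_id)
  else survival::Surv(time, event) ~ arm
  fit <- survival::coxph(fml, data = ipd, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$converged == FALSE))
    stop("Cox fit did not converge")
  cf <- stats::coef(fit)
  names(cf) <- sub("^arm", "", names(cf))
  vc <- stats::vcov(fit)
  dimnames(vc) <- list(names(cf), names(cf))
  se <- sqrt(diag(vc))
  z <- z_quantile(ci_level)
  ci <- cbind(lower = exp(cf - z * se), upper = exp(cf + z * se))
  lrt <- 2 * diff(fit$loglik)
  df <- length(cf)
  structure(
    list(coef = cf, se = se, hr = exp(cf), ci = ci, vcov = vc,
         lrt_stat = lrt, lrt_df = df,
         lrt_p = stats::pchisq(lrt, df, lower.tail = FALSE),
         wald_stat = unname(fit$wald.test),
         wald_p = stats::pchisq(unname(fit$wald.test), df, lower.tail = FALSE),
         reference_arm = reference_arm, ci_level = ci_level),
    class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit (Efron ties), reference arm '%s':\n", x$reference_arm))
  for (a in names(x$coef))
    cat(sprintf("  %s vs %s: HR %.4f (%g%% CI %.4f to %.4f)\n",
                a, x$reference_arm, x$hr[a], 100 * x$ci_level,
                x$ci[a, "lower"], x$ci[a, "upper"]))
  cat(sprintf("  LRT %.3f on %d df (p = %.3g); Wald %.3f (p = %.3g)\n",
              x$lrt_stat, x$lrt_df, x$lrt_p, x$wald_stat, x$wald_p))
  invisible(x)
}

#' Hazard ratio between two non-reference arms from one fitted model
#'
#' Within a single Cox fit the pairwise hazard ratio between arms `a` and
#' `b` is `exp(coef_a - coef_b)`, with the standard error taken from the
#' coefficient covariance.  Either label may be the reference arm (whose
#' coefficient is 0).
#'
#' @param cox a `cox_result`.
#' @param arm_a,arm_b arm labels.
#' @return A list with `hr`, `se_log` and `ci` at the fit's `ci_level`.
#' @export
pairwise_hr <- function(cox, arm_a, arm_b) {
  stopifnot(inherits(cox, "cox_result"))
  get_cv <- function(a) {
    if (a == cox$reference_arm) return(list(cf = 0, idx = NA_integer_))
    if (!a %in% names(cox$coef)) stop("arm not in fit: ", a)
    list(cf = cox$coef[[a]], idx = match(a, names(cox$coef)))
  }
  ga <- get_cv(arm_a); gb <- get_cv(arm_b)
  est <- ga$cf - gb$cf
  v <- 0
  if (!is.na(ga$idx)) v <- v + cox$vcov[ga$idx, ga$idx]
  if (!is.na(gb$idx)) v <- v + cox$vcov[gb$idx, gb$idx]
  if (!is.na(ga$idx) && !is.na(gb$idx)) v <- v - 2 * cox$vcov[ga$idx, gb$idx]
  se <- sqrt(v)
  z <- z_quantile(cox$ci_level)
  list(hr = exp(est), se_log = se,
       ci = c(lower = exp(est - z * se), upper = exp(est + z * se)))
}

#' Restricted mean survival time (RMST)
#'
#' The area under the Kaplan-Meier step function on `[0, tau]`, with the
#' usual large-sample variance (sum over event times of the squared
#' remaining area times the Greenwood increment) and a normal-theory CI.
#' Truncation beyond the last observed follow-up time is refused rather
#' than extrapolated.
#'
#' @param km a `km_estimate`.
#' @param tau truncation time in months; must not exceed `km$max_time`.
#' @param ci_level two-sided confidence level (default 0.95).
#' @return An object of class `rmst_result`: `tau`, `estimate` (event-free
#'   months in `[0, tau]`), `se`, `ci`.
#' @export
rmst <- function(km, tau, ci_level = 0.95) {
  stopifnot(inherits(km, "km_estimate"), tau > 0)
  if (tau > km$max_time)
    stop(sprintf("tau = %g exceeds last follow-up time %g: refusing to extrapolate",
                 tau, km$max_time))
  in_tau <- km$event_times < tau
  tj <- km$event_times[in_tau]
  sj <- km$surv[in_tau]
  steps_t <- c(0, tj, tau)
  steps_s <- c(1, sj)
  est <- sum(diff(steps_t) * steps_s)
  # area remaining from each event time to tau, under the step function
  if (length(tj)) {
    area_after <- rev(cumsum(rev(diff(steps_t)[-1L] * steps_s[-1L])))
    dj <- km$n_events_at[in_tau]
    nj <- km$n_risk_at[in_tau]
    denom <- nj * (nj - dj)
    vterm <- ifelse(denom > 0, dj / denom, 0)
    v <- sum(area_after^2 * vterm)
  } else v <- 0
  se <- sqrt(v)
  z <- z_quantile(ci_level)
  structure(
    list(tau = tau, estimate = est, se = se,
         ci = c(lower = est - z * se, upper = est + z * se)),
    class = "rmst_result")
}

#' @export
print.rmst_result <- function(x, ...) {
  cat(sprintf("RMST(tau = %g): %.3f event-free months (SE %.3f, CI %.3f to %.3f)\n",
              x$tau, x$estimate, x$se, x$ci["lower"], x$ci["upper"]))
  invisible(x)
}
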