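## Non-inferiority on the RMST scale: a clinical margin expressed as a
## tolerated loss in event-free months over [0, tau], tested one-sided at
## the 0.05 level with the matching two-sided 90% confidence interval.

#' Difference of two RMST estimates from independent arms
#'
#' @param a,b `rmst_result` objects at the same truncation time.
#' @return A list with `estimate` (`a - b`, event-free months) and `se`
#'   (`sqrt(a.se^2 + b.se^2)`, valid for independent pooled arms).
#' @export
rmst_difference <- function(a, b) {
  stopifnot(inherits(a, "rmst_result"), inherits(b, "rmst_result"))
  if (!isTRUE(all.equal(a$tau, b$tau)))
    stop("RMST truncation times differ: ", a$tau, " vs ", b$tau)
  list(estimate = a$estimate - b$estimate, se = sqrt(a$se^2 + b$se^2))
}

#' Convert a normal-theory confidence interval to another level
#'
#' Recovers the standard error from the interval half-width at the source
#' level and rebuilds the interval at the target level around the same
#' point estimate.  Exact normal quantiles (e.g. 1.959964, 1.644854) are
#' used so third-decimal endpoints reproduce.
#'
#' @param point the point estimate.
#' @param ci_from numeric `(lower, upper)` at `level_from`.
#' @param level_from,level_to two-sided confidence levels in (0, 1).
#' @return Numeric `(lower, upper)` at `level_to`.
#' @export
convert_ci <- function(point, ci_from, level_from = 0.95, level_to = 0.90) {
  stopifnot(length(ci_from) == 2L,
            level_from > 0, level_from < 1, level_to > 0, level_to < 1)
  lo <- ci_from[[1L]]; up <- ci_from[[2L]]
  if (lo > up) stop("interval bounds out of order")
  if (point < lo || point > up)
    stop("point estimate lies outside the source interval")
  if (up == lo) {
    warning("degenerate (zero-width) source interval")
    return(c(lower = point, upper = point))
  }
  se <- (up - lo) / (2 * z_quantile(level_from))
  z <- z_quantile(level_to)
  c(lower = point - z * se, upper = point + z * se)
}

#' One-sided non-inferiority z-test on the RMST loss scale
#'
#' Tests H0: loss >= margin against H1: loss < margin, where "loss" is the
#' RMST deficit of the test arm relative to the reference (positive = test
#' arm worse).  `z = (margin - loss) / se`; the p-value is the upper normal
#' tail under the boundary null.  Non-inferiority at the one-sided 0.05
#' level is algebraically equivalent to the upper bound of the two-sided
#' 90% CI for the loss lying below the margin; both forms are reported.
#'
#' @param loss estimated RMST loss in event-free months.
#' @param se its standard error (must be positive).
#' @param margin non-inferiority margin in event-free months (positive).
#' @param comparison optional character pair `(test arm, reference arm)`.
#' @return An object of class `ni_result`: `comparison`, `loss`, `se`,
#'   `ci90`, `ci95`, `margin`, `z`, `p_noninf`, `noninferior`.
#' @export
ni_test <- function(loss, se, margin, comparison = c("test", "reference")) {
  if (!is.finite(se) || se <= 0) stop("se must be positive")
  if (margin <= 0) stop("margin must be positive")
  z90 <- z_quantile(0.90); z95 <- z_quantile(0.95)
  z <- (margin - loss) / se
  p <- pnorm(z, lower.tail = FALSE)
  structure(
    list(comparison = comparison, loss = loss, se = se,
         ci90 = c(lower = loss - z90 * se, upper = loss + z90 * se),
         ci95 = c(lower = loss - z95 * se, upper = loss + z95 * se),
         margin = margin, z = z, p_noninf = p,
         noninferior = p < 0.05),
    class = "ni_result")
}

#' @export
print.ni_result <- function(x, ...) {
  cat(sprintf(
    "Non-inferiority, %s vs %s: loss %.3f months (90%% CI %.3f to %.3f), margin %.3g\n  z = %.3f, p_noninf = %.3g -> %s\n",
    x$comparison[1L], x$comparison[2L], x$loss,
    x$ci90["lower"], x$ci90["upper"], x$margin, x$z, x$p_noninf,
    if (x$noninferior) "non-inferior" else "not shown non-inferior"))
  invisible(x)
}

#' Forest-plot-ready table of non-inferiority results
#'
#' @param results a list of `ni_result` objects.
#' @return A data frame with one row per comparison: `label`, `loss`,
#'   `ci90_lower`, `ci90_upper`, `margin`, `verdict`.
#' @export
forest_data <- function(results) {
  if (inherits(results, "ni_result")) results <- list(results)
  if (!length(results)) stop("need at least one result")
  do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "ni_result"))
    data.frame(label = paste(r$comparison[1L], "vs", r$comparison[2L]),
               loss = r$loss,
               ci90_lower = unname(r$ci90["lower"]),
               ci90_upper = unname(r$ci90["upper"]),
               margin = r$margin,
               verdict = r$noninferior,
               stringsAsFactors = FALSE)
  }))
}

#' Full analysis of a pooled IPD dataset
#'
#' Convenience pipeline: per-treatment Kaplan-Meier estimates, medians and
#' RMST at `tau`, a pooled Cox fit versus the reference arm, and a
#' non-inferiority test of every non-reference arm against the reference
#' using the configured margin.
#'
#' @param ipd pooled IPD data frame.
#' @param config an [analysis_config()].
#' @return A list with `km` (per-arm `km_estimate`s), `median` (per-arm
#'   median + CI), `rmst` (per-arm `rmst_result`s), `cox` (`cox_result`),
#'   `ni` (per-comparison `ni_result`s), `forest` (data frame).
#' @export
analyze_ipd <- function(ipd, config = analysis_config()) {
  ipd <- as_ipd(ipd)
  stopifnot(inherits(config, "analysis_config"))
  arms <- unique(ipd$arm)
  if (!config$reference_arm %in% arms)
    stop("reference arm not present: ", config$reference_arm)
  km <- lapply(setNames(arms, arms),
               function(a) kaplan_meier(ipd[ipd$arm == a, ]))
  med <- lapply(km, median_survival, level = config$ci_level_main)
  rm <- lapply(km, rmst, tau = config$tau, ci_level = config$ci_level_main)
  cox <- cox_fit(ipd, config$reference_arm, ci_level = config$ci_level_main)
  tests <- setdiff(arms, config$reference_arm)
  ni <- lapply(setNames(tests, tests), function(a) {
    d <- rmst_difference(rm[[config$reference_arm]], rm[[a]])
    ni_test(d$estimate, d$se, config$margin,
            comparison = c(a, config$reference_arm))
  })
  list(km = km, median = med, rmst = rm, cox = cox, ni = ni,
       forest = forest_data(ni))
}
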