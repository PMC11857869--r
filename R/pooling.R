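## Pooling of reconstructed per-trial arms into per-treatment datasets:
## all patients who received the same treatment are combined into one
## group, keeping trial_id on every record so stratified analyses remain
## possible downstream.

#' Map from (trial, source arm) pairs to canonical treatment labels
#'
#' @param trial_id,arm,treatment character vectors of equal length; each
#'   `(trial_id, arm)` pair must be unique.
#' @return An object of class `trial_arm_map` (a data frame).
#' @export
trial_arm_map <- function(trial_id, arm, treatment) {
  m <- data.frame(trial_id = as.character(trial_id),
                  arm = as.character(arm),
                  treatment = as.character(treatment),
                  stringsAsFactors = FALSE)
  key <- paste(m$trial_id, m$arm, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (trial, arm) pair in map: ",
         gsub("\r", " / ", d, fixed = TRUE))
  }
  structure(m, class = c("trial_arm_map", "data.frame"))
}

#' Read a trial-arm map from CSV (trial_id, arm, treatment)
#'
#' @param path CSV file path with a header row.
#' @return A [trial_arm_map()].
#' @export
read_map_csv <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("trial_id", "arm", "treatment")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("map CSV is missing column(s): ", paste(miss, collapse = ", "))
  trial_arm_map(m$trial_id, m$arm, m$treatment)
}

#' Pool per-trial IPD into per-treatment datasets
#'
#' Concatenates the inputs, replacing each record's arm label by the
#' canonical treatment label from the map.  Trial identity is retained on
#' every record.
#'
#' @param datasets a list of IPD data frames (or a single one).
#' @param map a [trial_arm_map()] covering every (trial, arm) pair present.
#' @return A pooled IPD data frame with `nrow` equal to the sum of the
#'   inputs' row counts.
#' @export
pool_arms <- function(datasets, map) {
  stopifnot(inherits(map, "trial_arm_map"))
  if (is.data.frame(datasets)) datasets <- list(datasets)
  ipd <- do.call(rbind, lapply(datasets, as_ipd))
  key <- paste(ipd$trial_id, ipd$arm, sep = "\r")
  mkey <- paste(map$trial_id, map$arm, sep = "\r")
  hit <- match(key, mkey)
  if (anyNA(hit)) {
    bad <- key[which(is.na(hit))[1L]]
    stop("unmapped (trial, arm) pair: ", gsub("\r", " / ", bad, fixed = TRUE))
  }
  ipd$arm <- map$treatment[hit]
  rownames(ipd) <- NULL
  ipd
}

#' Heterogeneity diagnostics on pooled IPD
#'
#' In `treatment_factor` mode, reports the likelihood-ratio and Wald
#' chi-square statistics of the pooled Cox treatment factor (df = number of
#' arms - 1).  In `trial_strata` mode, reports a nested likelihood-ratio
#' test of between-trial baseline differences, comparing the treatment-only
#' Cox model with one adding trial as a factor (df = number of trials - 1),
#' together with the Wald test of the trial coefficients.
#'
#' @param ipd pooled IPD data frame.
#' @param mode `"treatment_factor"` or `"trial_strata"`.
#' @return A list with `lrt` and `wald`, each `(stat, df, p)`.
#' @export
heterogeneity <- function(ipd, mode = c("treatment_factor", "trial_strata")) {
  mode <- match.arg(mode)
  ipd <- as_ipd(ipd)
  if (mode == "treatment_factor") {
    ref <- sort(unique(ipd$arm))[1L]   # LRT/Wald are invariant to the reference
    cx <- cox_fit(ipd, reference_arm = ref)
    list(lrt = c(stat = cx$lrt_stat, df = cx$lrt_df, p = cx$lrt_p),
         wald = c(stat = cx$wald_stat, df = cx$lrt_df, p = cx$wald_p))
  } else {
    trials <- sort(unique(ipd$trial_id))
    if (length(trials) < 2L)
      stop("trial_strata mode needs >= 2 trials")
    ipd$arm <- factor(ipd$arm)
    ipd$trial_id <- factor(ipd$trial_id)
    f0 <- survival::coxph(survival::Surv(time, event) ~ arm, data = ipd,
                          ties = "efron")
    f1 <- survival::coxph(survival::Surv(time, event) ~ arm + trial_id,
                          data = ipd, ties = "efron")
    df <- length(trials) - 1L
    lrt <- 2 * (f1$loglik[2L] - f0$loglik[2L])
    idx <- grep("^trial_id", names(stats::coef(f1)))
    b <- stats::coef(f1)[idx]
    w <- drop(t(b) %*% solve(stats::vcov(f1)[idx, idx, drop = FALSE]) %*% b)
    list(lrt = c(stat = lrt, df = df,
                 p = stats::pchisq(lrt, df, lower.tail = FALSE)),
         wald = c(stat = w, df = df,
                  p = stats::pchisq(w, df, lower.tail = FALSE)))
  }
}
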