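## Ingestion of digitizer output and published risk tables, plus the IPD
## CSV round trip.  All times are in months throughout the package.

#' Digitized survival curve for one arm of one trial
#'
#' Holds the ordered (time, survival) coordinates clicked out of a published
#' Kaplan-Meier figure, after sanitization.  A Kaplan-Meier estimate is
#' non-increasing by construction, so digitizer jitter that makes the
#' sequence locally increasing is removed by [sanitize_monotone()].
#'
#' @param time numeric vector of months, strictly increasing, `>= 0`.
#' @param survival numeric vector of survival probabilities in `[0, 1]`.
#' @param trial_id,arm text labels identifying the source arm.
#' @param sanitize if `TRUE` (default) apply [sanitize_monotone()] before
#'   validating the monotonicity invariant.
#' @return An object of class `digitized_curve`: a list with elements
#'   `time`, `survival`, `trial_id`, `arm`.
#' @seealso [read_curve_csv()], [sanitize_monotone()]
#' @export
digitized_curve <- function(time, survival, trial_id = "trial", arm = "arm",
                            sanitize = TRUE) {
  if (length(time) != length(survival))
    stop("`time` and `survival` must have equal length")
  if (length(time) < 2L)
    stop("a digitized curve needs at least 2 clicks, got ", length(time))
  if (anyNA(time) || anyNA(survival))
    stop("digitized curve contains missing values")
  if (any(time < 0))
    stop("click times must be >= 0")
  o <- order(time, survival)          # ties: lowest survival first
  time <- time[o]; survival <- survival[o]
  # duplicate times collapse to the minimum survival (bottom of a step
  # digitized twice)
  if (anyDuplicated(time)) {
    keep <- !duplicated(time)         # first occurrence = lowest survival
    time <- time[keep]; survival <- survival[keep]
  }
  survival <- pmin(pmax(survival, 0), 1)
  obj <- structure(
    list(time = time, survival = survival,
         trial_id = as.character(trial_id), arm = as.character(arm)),
    class = "digitized_curve")
  if (sanitize) obj <- sanitize_monotone(obj)
  if (is.unsorted(rev(obj$survival)))
    stop("survival values are not non-increasing after sanitization")
  obj
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("Digitized KM curve: trial '%s', arm '%s', %d clicks over [%g, %g] months\n",
              x$trial_id, x$arm, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Project clicked survival values onto the nearest non-increasing sequence
#'
#' Least-squares isotonic (antitonic) regression via pool-adjacent-violators,
#' applied to the survival coordinates with times held fixed.  Identity on
#' already-monotone input, and idempotent.  Values are clamped to `[0, 1]`
#' afterwards.
#'
#' @param curve a `digitized_curve` (clicks sorted by time).
#' @return The curve with `survival` replaced by its best non-increasing
#'   least-squares approximation.
#' @export
sanitize_monotone <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  if (is.unsorted(curve$time)) stop("clicks must be sorted by time")
  y <- curve$survival
  if (is.unsorted(rev(y))) {
    # isoreg fits non-decreasing; negate for the non-increasing projection
    y <- -isoreg(seq_along(y), -y)$yf
  }
  curve$survival <- pmin(pmax(y, 0), 1)
  curve
}

#' Read a digitizer-output CSV into a digitized curve
#'
#' Consumes the two-column (time, survival) CSV that point-and-click
#' digitizer tools such as WebPlotDigitizer export.  Rows may be unsorted
#' and noisy; they are sorted, rescaled, clamped, de-duplicated and
#' monotonized.  The survival scale is never auto-detected: a curve that
#' never drops below 1 is indistinguishable from a percent-scale curve near
#' 100, so the caller must state the scale.
#'
#' @param path CSV file path.
#' @param trial_id,arm labels attached to the curve.
#' @param survival_scale `"probability"` (values in 0-1) or `"percent"`
#'   (values in 0-100, divided by 100 on read).
#' @param header `TRUE` if the file has a header row (the default dialect);
#'   set `FALSE` for bare two-column exports.
#' @return A [digitized_curve()].
#' @export
read_curve_csv <- function(path, trial_id = "trial", arm = "arm",
                           survival_scale = c("probability", "percent"),
                           header = TRUE) {
  survival_scale <- match.arg(survival_scale)
  raw <- read.csv(path, header = header, colClasses = "character",
                  strip.white = TRUE)
  if (ncol(raw) < 2L)
    stop("curve CSV must have two columns (time, survival): ", path)
  tm <- suppressWarnings(as.numeric(raw[[1L]]))
  sv <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- which(is.na(tm) | is.na(sv))
  if (length(bad))
    stop(sprintf("non-numeric cell in '%s' at data row %d", path, bad[1L]))
  if (length(tm) < 2L)
    stop("fewer than 2 usable rows in curve CSV: ", path)
  if (survival_scale == "percent") sv <- sv / 100
  digitized_curve(tm, sv, trial_id = trial_id, arm = arm)
}

#' Published numbers-at-risk table for one arm
#'
#' The row of "numbers at risk" printed beneath a published Kaplan-Meier
#' plot, at fixed times starting at 0.  `n_risk[1]` is the enrolled arm
#' size; an optional total event count (from the publication's results
#' table) can be attached for exact event-total matching during
#' reconstruction.
#'
#' @param times ordered months, first element 0.
#' @param n_risk positive integers, non-increasing, same length as `times`.
#' @param total_events optional non-negative integer.
#' @param trial_id,arm text labels.
#' @return An object of class `risk_table`.
#' @export
risk_table <- function(times, n_risk, total_events = NULL,
                       trial_id = "trial", arm = "arm") {
  if (length(times) != length(n_risk))
    stop("`times` and `n_risk` must have equal length")
  if (length(times) < 1L) stop("risk table is empty")
  if (times[1L] != 0) stop("risk table must start at time 0")
  if (is.unsorted(times, strictly = TRUE))
    stop("risk-table times must be strictly increasing")
  n_risk <- as.integer(round(n_risk))
  if (any(n_risk <= 0L)) stop("n_risk must be positive")
  if (is.unsorted(rev(n_risk))) stop("n_risk must be non-increasing")
  if (!is.null(total_events)) {
    total_events <- as.integer(round(total_events))
    if (total_events < 0L) stop("total_events must be non-negative")
  }
  structure(
    list(times = as.numeric(times), n_risk = n_risk,
         total_events = total_events,
         trial_id = as.character(trial_id), arm = as.character(arm)),
    class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  cat(sprintf("Risk table: trial '%s', arm '%s', N = %d, %d rows%s\n",
              x$trial_id, x$arm, x$n_risk[1L], length(x$times),
              if (is.null(x$total_events)) ""
              else sprintf(", total events = %d", x$total_events)))
  invisible(x)
}

#' Read a risk-table CSV (time, n_risk)
#'
#' @inheritParams read_curve_csv
#' @param total_events optional total event count to attach.
#' @return A [risk_table()].
#' @export
read_risk_csv <- function(path, trial_id = "trial", arm = "arm",
                          total_events = NULL, header = TRUE) {
  raw <- read.csv(path, header = header, colClasses = "character",
                  strip.white = TRUE)
  if (ncol(raw) < 2L)
    stop("risk-table CSV must have two columns (time, n_risk): ", path)
  tm <- suppressWarnings(as.numeric(raw[[1L]]))
  nr <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- which(is.na(tm) | is.na(nr))
  if (length(bad))
    stop(sprintf("non-numeric cell in '%s' at data row %d", path, bad[1L]))
  o <- order(tm)
  risk_table(tm[o], nr[o], total_events = total_events,
             trial_id = trial_id, arm = arm)
}

#' Validate an individual-patient-data frame
#'
#' IPD is carried as a plain data frame with columns `time` (months, `>= 0`),
#' `event` (1 = event, 0 = censored), `arm` and `trial_id`.
#'
#' @param x a data frame.
#' @return The validated data frame (character arm/trial columns, numeric
#'   time, integer event).
#' @export
as_ipd <- function(x) {
  req <- c("time", "event", "arm", "trial_id")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("IPD data frame is missing column(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[req]
  x$time <- as.numeric(x$time)
  x$arm <- as.character(x$arm)
  x$trial_id <- as.character(x$trial_id)
  ev <- suppressWarnings(as.numeric(x$event))
  bad <- which(is.na(x$time) | x$time < 0)
  if (length(bad)) stop("invalid time at row ", bad[1L])
  bad <- which(is.na(ev) | !(ev %in% c(0, 1)))
  if (length(bad))
    stop("event must be 0 or 1; invalid value at row ", bad[1L])
  x$event <- as.integer(ev)
  rownames(x) <- NULL
  x
}

#' Write / read reconstructed IPD as CSV
#'
#' The on-disk format is a four-column CSV (`time,event,arm,trial_id`) with
#' header; `read_ipd_csv(write_ipd_csv(x))` is the identity on valid data.
#'
#' @param ipd a data frame accepted by [as_ipd()].
#' @param path file path.
#' @return `write_ipd_csv` returns `path` invisibly; `read_ipd_csv` returns
#'   the validated data frame.
#' @export
write_ipd_csv <- function(ipd, path) {
  ipd <- as_ipd(ipd)
  write.csv(ipd, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_ipd_csv
#' @export
read_ipd_csv <- function(path) {
  as_ipd(read.csv(path, stringsAsFactors = FALSE))
}

#' Analysis configuration
#'
#' Bundles the truncation time, the non-inferiority margin (a tolerated loss
#' in event-free months, so always positive), the two confidence levels and
#' the reference arm.
#'
#' @param tau truncation time in months (default 30).
#' @param margin non-inferiority margin in event-free months (default 2).
#' @param ci_level_main two-sided level for descriptive CIs (default 0.95).
#' @param ci_level_ni two-sided level paired with the one-sided 0.05
#'   non-inferiority test (default 0.90).
#' @param reference_arm label of the comparator arm.
#' @param seed integer seed for any downstream simulation.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(tau = 30, margin = 2, ci_level_main = 0.95,
                            ci_level_ni = 0.90, reference_arm = "warfarin",
                            seed = 1L) {
  stopifnot(tau > 0, margin > 0,
            ci_level_main > 0, ci_level_main < 1,
            ci_level_ni > 0, ci_level_ni < 1)
  structure(
    list(tau = tau, margin = margin, ci_level_main = ci_level_main,
         ci_level_ni = ci_level_ni,
         reference_arm = as.character(reference_arm),
         seed = as.integer(seed)),
    class = "analysis_config")
}
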