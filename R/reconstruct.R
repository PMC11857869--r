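## Iterative reconstruction of individual patient data from a digitized
## Kaplan-Meier curve plus its numbers-at-risk table.  The algorithm inverts
## the product-limit relation click by click, while choosing an integer
## censoring count per risk-table interval so that the implied number at
## risk at the next boundary reproduces the published one.  It is fully
## deterministic: no random numbers are used anywhere in reconstruction.

#' Assign curve clicks to risk-table intervals
#'
#' Intervals are left-closed: interval `i` is `[times[i], times[i+1])`, and
#' the last interval is right-open up to the last click.  A click exactly at
#' a boundary belongs to the interval starting there.  Empty intervals are
#' allowed.
#'
#' @param curve a [digitized_curve()].
#' @param risk a [risk_table()].
#' @return A list of integer vectors, one per risk-table row, holding the
#'   indices of the clicks falling in that interval.
#' @export
assign_intervals <- function(curve, risk) {
  stopifnot(inherits(curve, "digitized_curve"), inherits(risk, "risk_table"))
  if (any(curve$time < 0)) stop("click before time 0")
  iv <- findInterval(curve$time, risk$times)
  if (any(iv == 0L))
    stop("click at t = ", curve$time[which(iv == 0L)[1L]],
         " precedes the first risk-table time")
  lapply(seq_along(risk$times), function(i) which(iv == i))
}

# Allocate events over the clicks of one interval, given a fixed set of
# censoring times inside it.  Censorings occurring strictly before a click
# leave the risk set first; at a shared time the event is processed first
# (the usual KM convention).  Event counts come from inverting
# S_k = S_lastevent * (1 - d_k / n_k), with the rounding residue carried to
# the next click so that a vertical drop digitized as several clicks is not
# systematically undercounted.
.alloc_interval <- function(n0, s_le, resid, click_t, click_s, cens_t) {
  n <- n0
  ev_t <- numeric(0); ev_d <- integer(0)
  cens_used <- 0L
  nc <- length(cens_t)
  for (k in seq_along(click_t)) {
    while (cens_used < nc && cens_t[cens_used + 1L] < click_t[k] && n > 0L) {
      cens_used <- cens_used + 1L
      n <- n - 1L
    }
    if (n <= 0L) break
    d_raw <- if (s_le > 0) n * (1 - click_s[k] / s_le) else 0
    d <- round(d_raw + resid)
    d <- max(0L, min(as.integer(d), n))
    resid <- d_raw + resid - d
    if (d > 0L) {
      s_le <- s_le * (1 - d / n)
      n <- n - d
      ev_t <- c(ev_t, click_t[k]); ev_d <- c(ev_d, d)
    }
  }
  # censorings after the last click still leave before the boundary
  drop_rest <- min(nc - cens_used, n)
  n <- n - drop_rest
  cens_used <- cens_used + drop_rest
  list(n_end = n, s_le = s_le, resid = resid,
       ev_t = ev_t, ev_d = ev_d, cens_used = cens_used)
}

# Midpoint-spaced censoring times: positions (j - 0.5)/c of the interval,
# which avoids collisions with clicks at boundaries.
.censor_times <- function(t_lo, t_hi, c) {
  if (c <= 0L) return(numeric(0))
  t_lo + (seq_len(c) - 0.5) / c * (t_hi - t_lo)
}

#' Reconstruct individual patient data from a curve and a risk table
#'
#' For each risk-table interval the censoring count is chosen by monotone
#' integer bisection over `[0, n at interval start]` so that the implied
#' number at risk at the next published boundary matches the published
#' value; within an interval, censoring times are spread at interval
#' midpoint positions and event counts are read off the survival drops by
#' inverting the product-limit formula with rounding-residue carry.  With no
#' interior risk-table boundaries the censoring search is skipped: events
#' come from the survival drops and all remaining patients are censored at
#' the last click time.  If a total event count is supplied, events and
#' censorings are rebalanced (latest records first, which leaves every
#' published at-risk count untouched) so the reconstructed total matches it
#' exactly when feasible.
#'
#' @param curve a sanitized [digitized_curve()].
#' @param risk a [risk_table()] with `n_risk[1] >= 2`.
#' @param total_events optional total event count for the arm; defaults to
#'   the one attached to `risk`, if any.
#' @return A list with components `ipd` (data frame: time, event, arm,
#'   trial_id; one row per reconstructed patient, `nrow == risk$n_risk[1]`)
#'   and `report` (a `reconstruction_report`: `max_abs_dev`, `rmse`,
#'   `n_events_reconstructed`, `n_censored_reconstructed`, `risk_match`,
#'   `converged`).
#' @export
reconstruct_ipd <- function(curve, risk, total_events = risk$total_events) {
  stopifnot(inherits(curve, "digitized_curve"), inherits(risk, "risk_table"))
  n0 <- risk$n_risk[1L]
  if (n0 < 2L) stop("need n_risk[1] >= 2 to reconstruct")
  idx <- assign_intervals(curve, risk)
  I <- length(risk$times)
  t_all <- curve$time; s_all <- curve$survival
  last_click_t <- t_all[length(t_all)]

  n <- n0; s_le <- 1; resid <- 0
  ev_t <- numeric(0); ev_d <- integer(0); cn_t <- numeric(0)
  implied <- integer(max(I - 1L, 0L))
  converged <- TRUE

  for (i in seq_len(I)) {
    ks <- idx[[i]]
    ct <- t_all[ks]; cs <- s_all[ks]
    t_lo <- risk$times[i]
    if (i < I) {
      t_hi <- risk$times[i + 1L]
      target <- risk$n_risk[i + 1L]
      eval_c <- function(c) .alloc_interval(n, s_le, resid, ct, cs,
                                            .censor_times(t_lo, t_hi, c))
      # implied n at the boundary is non-increasing in the censoring count:
      # bisect, then refine locally in case event rounding perturbs it
      lo <- 0L; hi <- n
      a <- eval_c(lo)
      if (a$n_end <= target) {
        best_c <- lo; best <- a
      } else {
        b <- eval_c(hi)
        while (hi - lo > 1L) {
          mid <- (lo + hi) %/% 2L
          m <- eval_c(mid)
          if (m$n_end > target) { lo <- mid; a <- m } else { hi <- mid; b <- m }
        }
        best_c <- hi; best <- b
        # local refinement: prefer exact match, ties toward fewer censorings
        cand <- max(0L, best_c - 2L):min(n, best_c + 2L)
        for (c in cand) {
          r <- if (c == best_c) best else eval_c(c)
          better <- abs(r$n_end - target) < abs(best$n_end - target) ||
            (abs(r$n_end - target) == abs(best$n_end - target) && c < best_c)
          if (better) { best_c <- c; best <- r }
        }
      }
      if (best$n_end != target) converged <- FALSE
      implied[i] <- best$n_end
      cn_t <- c(cn_t, .censor_times(t_lo, t_hi, best_c)[seq_len(best$cens_used)])
      ev_t <- c(ev_t, best$ev_t); ev_d <- c(ev_d, best$ev_d)
      n <- best$n_end; s_le <- best$s_le; resid <- best$resid
    } else {
      # final interval: no published boundary to match
      r <- .alloc_interval(n, s_le, resid, ct, cs, numeric(0))
      ev_t <- c(ev_t, r$ev_t); ev_d <- c(ev_d, r$ev_d)
      n <- r$n_end
      if (n < 0L) stop("implied negative at-risk count in interval ", i)
      # everyone still at risk is administratively censored at the last click
      if (n > 0L) cn_t <- c(cn_t, rep(last_click_t, n))
    }
  }

  # Optional exact event-total matching.  Swapping an event for a censoring
  # (or vice versa) at the same time never changes the at-risk count at any
  # later boundary, so the published risk table stays matched.  The swap is
  # applied as late as possible: end-censored patients first when events
  # must be added, the latest events first when events must be removed.
  if (!is.null(total_events)) {
    delta <- as.integer(total_events) - sum(ev_d)
    if (delta > 0L) {
      o_cn <- order(cn_t, decreasing = TRUE)
      take <- min(delta, length(cn_t))
      if (take > 0L) {
        conv <- o_cn[seq_len(take)]
        ev_t <- c(ev_t, cn_t[conv]); ev_d <- c(ev_d, rep(1L, take))
        cn_t <- cn_t[-conv]
      }
      if (take < delta)
        warning("could not raise reconstructed events to total_events (",
                total_events, "); short by ", delta - take)
    } else if (delta < 0L) {
      need <- -delta
      j <- length(ev_t)
      while (need > 0L && j >= 1L) {
        take <- min(need, ev_d[j])
        ev_d[j] <- ev_d[j] - take
        cn_t <- c(cn_t, rep(ev_t[j], take))
        need <- need - take
        j <- j - 1L
      }
      keep <- ev_d > 0L
      ev_t <- ev_t[keep]; ev_d <- ev_d[keep]
      if (need > 0L)
        warning("could not lower reconstructed events to total_events (",
                total_events, "); excess ", need)
    }
  }

  times <- c(rep(ev_t, ev_d), cn_t)
  event <- c(rep(1L, sum(ev_d)), rep(0L, length(cn_t)))
  o <- order(times, -event)
  ipd <- as_ipd(data.frame(time = times[o], event = event[o],
                           arm = curve$arm, trial_id = curve$trial_id,
                           stringsAsFactors = FALSE))
  stopifnot(nrow(ipd) == n0)

  km <- kaplan_meier(ipd)
  fid <- fidelity(curve, km)
  report <- structure(
    list(max_abs_dev = fid$max_abs_dev, rmse = fid$rmse,
         n_events_reconstructed = sum(ipd$event),
         n_censored_reconstructed = sum(1L - ipd$event),
         risk_match = if (I > 1L)
           data.frame(time = risk$times[-1L],
                      published = risk$n_risk[-1L],
                      reconstructed = implied)
         else data.frame(time = numeric(0), published = integer(0),
                         reconstructed = integer(0)),
         converged = converged),
    class = "reconstruction_report")
  list(ipd = ipd, report = report)
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf(
    "IPD reconstruction: %d events + %d censored; max |dev| = %.4f, RMSE = %.4f, converged: %s\n",
    x$n_events_reconstructed, x$n_censored_reconstructed,
    x$max_abs_dev, x$rmse, x$converged))
  invisible(x)
}

#' Fidelity of a reconstructed curve to the digitized clicks
#'
#' Evaluates the re-estimated Kaplan-Meier step function (right-continuous)
#' at every click time and summarizes the deviations.
#'
#' @param curve the input [digitized_curve()].
#' @param km a [kaplan_meier()] estimate from the reconstructed IPD.
#' @return A list with `max_abs_dev` and `rmse` (both on the probability
#'   scale; `max_abs_dev >= rmse`).
#' @export
fidelity <- function(curve, km) {
  stopifnot(inherits(curve, "digitized_curve"), inherits(km, "km_estimate"))
  s_hat <- km_survival_at(km, curve$time)
  dev <- curve$survival - s_hat
  list(max_abs_dev = max(abs(dev)), rmse = sqrt(mean(dev^2)))
}
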