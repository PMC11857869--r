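# Independent oracles used by the unit tests.  These deliberately avoid the
# package's own code paths (and the survival package's fitting routines) so
# that agreement is evidence, not circularity.

# Brute-force two-sample Cox partial log-likelihood for a 0/1 indicator
# covariate and untied event times (Breslow = Efron = exact when no ties).
oracle_cox_loglik <- function(time, event, x, beta) {
  ll <- 0
  for (i in which(event == 1L)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# Maximize the brute-force partial likelihood by golden-section search on a
# bracket, refined to ~1e-9 in beta.
oracle_cox_mle <- function(time, event, x) {
  stats::optimize(function(b) oracle_cox_loglik(time, event, x, b),
                  interval = c(-10, 10), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Two-sample log-rank statistic from first principles (hypergeometric
# moments at each distinct event time).
oracle_logrank <- function(time, event, group) {
  stopifnot(all(group %in% c(0L, 1L)))
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(time[event == 1L]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1L)
    d <- sum(event == 1L & time == t)
    d1 <- sum(event == 1L & time == t & group == 1L)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# Exact least-squares non-increasing fit by exhaustive enumeration of
# consecutive-block partitions: the antitonic LS optimum is blockwise
# constant at block means with non-increasing means, so the minimum-SSE
# candidate over all such feasible partitions is the optimum.
oracle_antitonic <- function(y) {
  k <- length(y)
  best <- NULL; best_sse <- Inf
  for (mask in 0:(2^(k - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(k - 2))) > 0)  # block ends
    ends <- c(cuts, k); starts <- c(1, head(ends, -1) + 1)
    fit <- numeric(k)
    for (b in seq_along(ends))
      fit[starts[b]:ends[b]] <- mean(y[starts[b]:ends[b]])
    if (is.unsorted(rev(fit))) next
    sse <- sum((y - fit)^2)
    if (sse < best_sse) { best_sse <- sse; best <- fit }
  }
  best
}

# Small simulated arm for reuse across tests.
sim_one_arm <- function(n, hazard, censor_hazard = 0.02, admin = 30,
                        risk_interval = 6, seed = 1, label = "A") {
  sim_trial_config(arms = list(list(label = label, hazard = hazard, n = n)),
                   censor_hazard = censor_hazard, admin_censor_time = admin,
                   risk_interval = risk_interval, click_grid = 3, seed = seed)
}
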