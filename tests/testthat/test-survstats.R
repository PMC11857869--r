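hand_ipd <- data.frame(time = 1:4, event = c(1L, 1L, 0L, 1L),
                       arm = "A", trial_id = "t")

test_that("product-limit steps and Greenwood variance match the hand example", {
  km <- kaplan_meier(hand_ipd)
  expect_equal(km$event_times, c(1, 2, 4))
  expect_equal(km$surv, c(0.75, 0.50, 0))
  # Greenwood at t = 2: S^2 (1/(4*3) + 1/(3*2)) = 0.25 * 0.25 = 0.0625
  expect_equal(km$var_greenwood[2], 0.0625, tolerance = 1e-12)
  expect_equal(km$n_risk_at, c(4, 3, 1))
  expect_equal(km$n_events_at, c(1, 1, 1))

  # no events: flat survival
  km0 <- kaplan_meier(data.frame(time = c(2, 5), event = 0L,
                                 arm = "A", trial_id = "t"))
  expect_equal(length(km0$event_times), 0L)
  expect_equal(km_survival_at(km0, c(0, 3, 5)), c(1, 1, 1))

  expect_error(kaplan_meier(hand_ipd[0, ]), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(3)
  tt <- round(rexp(40, 0.2), 2)
  ipd <- data.frame(time = tt, event = 1L, arm = "A", trial_id = "t")
  km <- kaplan_meier(ipd)
  probe <- sort(unique(tt))
  expect_equal(km_survival_at(km, probe),
               sapply(probe, function(t) mean(tt > t)), tolerance = 1e-12)
})

test_that("median survival follows the smallest-crossing convention", {
  km <- kaplan_meier(hand_ipd)
  expect_equal(median_survival(km)$median, 2)   # first time S <= 0.5
  # survival never reaches 0.5: not reached
  km_high <- kaplan_meier(data.frame(time = 1:10, event = c(1L, rep(0L, 9)),
                                     arm = "A", trial_id = "t"))
  expect_true(is.na(median_survival(km_high)$median))
})

test_that("median of a large exponential sample is near the closed form", {
  set.seed(77)
  n <- 5000
  ipd <- data.frame(time = rexp(n, 0.1), event = 1L, arm = "A", trial_id = "t")
  ms <- median_survival(kaplan_meier(ipd))
  true_med <- log(2) / 0.1
  # 3 Monte-Carlo SEs of a sample median of an exponential
  mc3 <- 3 * 0.5 / (0.1 * exp(-0.1 * true_med) * sqrt(n))
  expect_lt(abs(ms$median - true_med), mc3)
  expect_true(ms$ci["lower"] < true_med && true_med < ms$ci["upper"])
})

test_that("log-rank matches the hypergeometric oracle and is symmetric", {
  # 4-record hand example: arm A events at 1, 2; arm B events at 3, 4
  ipd <- data.frame(time = 1:4, event = 1L,
                    arm = c("A", "A", "B", "B"), trial_id = "t")
  lr <- logrank(ipd, "A", "B")
  expect_equal(lr$chi_square, 49 / 17, tolerance = 1e-10)   # hand value 2.88235
  expect_equal(lr$chi_square,
               oracle_logrank(ipd$time, ipd$event, as.integer(ipd$arm == "A")),
               tolerance = 1e-10)
  # invariance to label order
  expect_equal(logrank(ipd, "B", "A")$chi_square, lr$chi_square)

  # identical arms: statistic 0, p about 1
  dup <- rbind(transform(hand_ipd, arm = "X"), transform(hand_ipd, arm = "Y"))
  lr0 <- logrank(dup, "X", "Y")
  expect_lt(lr0$chi_square, 1e-10)
  expect_gt(lr0$p, 0.999)

  expect_error(logrank(ipd, "A", "nope"), "nope")
})

test_that("log-rank type-I error is calibrated under equal hazards", {
  set.seed(2024)
  reject <- replicate(1000, {
    ipd <- data.frame(time = rexp(50, 0.1),
                      event = rbinom(50, 1, 0.8),
                      arm = rep(c("A", "B"), each = 25), trial_id = "t")
    logrank(ipd, "A", "B")$p < 0.05
  })
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("Cox coefficients match brute-force partial-likelihood maximization", {
  set.seed(9)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    ipd <- data.frame(time = sample(seq(1, 40, by = 0.5), n),  # no ties
                      event = rbinom(n, 1, 0.8),
                      arm = sample(c("ctrl", "trt"), n, replace = TRUE),
                      trial_id = "t")
    if (sum(ipd$event) == 0 || length(unique(ipd$arm)) < 2) next
    fit <- tryCatch(suppressWarnings(cox_fit(ipd, "ctrl")),
                    error = function(e) NULL)
    if (is.null(fit) || is.na(fit$coef[["trt"]]) ||
        abs(fit$coef[["trt"]]) > 8) next  # monotone likelihood
    beta_star <- oracle_cox_mle(ipd$time, ipd$event,
                                as.integer(ipd$arm == "trt"))
    expect_equal(unname(fit$coef[["trt"]]), beta_star, tolerance = 1e-6)
  }
})

test_that("Cox symmetry: identical arms give HR 1, label swap negates coefficients", {
  dup <- rbind(transform(hand_ipd, arm = "X"), transform(hand_ipd, arm = "Y"))
  fit <- cox_fit(dup, "X")
  expect_equal(unname(fit$coef[["Y"]]), 0, tolerance = 1e-8)
  expect_equal(unname(fit$hr[["Y"]]), 1, tolerance = 1e-8)

  set.seed(21)
  ipd <- data.frame(time = rexp(60, 0.1), event = rbinom(60, 1, 0.7),
                    arm = rep(c("a", "b"), 30), trial_id = "t")
  f_ab <- cox_fit(ipd, "a")
  f_ba <- cox_fit(ipd, "b")
  expect_equal(unname(f_ab$coef[["b"]]), -unname(f_ba$coef[["a"]]),
               tolerance = 1e-8)
  expect_error(cox_fit(transform(ipd, event = 0L), "a"), "no events|information")
  expect_error(cox_fit(transform(ipd, arm = "a"), "a"), "2 arms")
})

test_that("3-arm Cox recovers simulated hazard ratios and pairwise HRs are transitive", {
  cfg <- sim_trial_config(
    arms = list(list(label = "ref", hazard = 0.05, n = 5000),
                list(label = "hi",  hazard = 0.05 * 1.25, n = 5000),
                list(label = "lo",  hazard = 0.05 * 1.05, n = 5000)),
    censor_hazard = 0.02, admin_censor_time = 60, seed = 31)
  ipd <- simulate_ipd(cfg)
  fit <- cox_fit(ipd, "ref")
  for (arm in c("hi", "lo")) {
    truth <- log(c(hi = 1.25, lo = 1.05)[[arm]])
    expect_lt(abs(fit$coef[[arm]] - truth), 3 * fit$se[[arm]])
  }
  pw <- pairwise_hr(fit, "hi", "lo")
  expect_equal(pw$hr, exp(fit$coef[["hi"]] - fit$coef[["lo"]]), tolerance = 1e-12)
  # Wald and LRT agree asymptotically
  expect_lt(abs(fit$wald_stat - fit$lrt_stat) / max(fit$lrt_stat, 1), 0.10)
  expect_equal(fit$lrt_df, 2L)
})

test_that("RMST matches the step-area hand example and refuses extrapolation", {
  # S = 1 on [0,1), 0.75 on [1,2), 0.5 on [2,4): area to tau = 4 is 2.75
  ipd <- data.frame(time = c(1, 2, 3, 4), event = c(1L, 1L, 0L, 0L),
                    arm = "A", trial_id = "t")
  km <- kaplan_meier(ipd)
  r <- rmst(km, 4)
  expect_equal(r$estimate, 2.75, tolerance = 1e-12)
  expect_error(rmst(km, 5), "extrapolat")

  # no events: estimate = tau, se = 0
  km0 <- kaplan_meier(data.frame(time = 10, event = 0L, arm = "A",
                                 trial_id = "t"))
  r0 <- rmst(km0, 8)
  expect_equal(r0$estimate, 8)
  expect_equal(r0$se, 0)
})

test_that("RMST is monotone in tau, bounded by tau, and matches the exponential closed form", {
  set.seed(55)
  n <- 5000
  ipd <- data.frame(time = pmin(rexp(n, 0.1), 40), event = 1L,
                    arm = "A", trial_id = "t")
  ipd$event[ipd$time == 40] <- 0L
  km <- kaplan_meier(ipd)
  taus <- c(5, 10, 20, 30)
  ests <- sapply(taus, function(tau) rmst(km, tau)$estimate)
  expect_false(is.unsorted(ests))
  expect_true(all(ests <= taus))
  r30 <- rmst(km, 30)
  closed <- (1 - exp(-30 * 0.1)) / 0.1
  expect_lt(abs(r30$estimate - closed), 3 * r30$se)
})
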