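test_that("clicks are binned into left-closed risk intervals", {
  cv <- digitized_curve(c(0, 3, 6, 9), c(1, 0.9, 0.8, 0.7))
  rk <- risk_table(c(0, 6), c(10, 8))
  iv <- assign_intervals(cv, rk)
  expect_equal(iv[[1]], c(1L, 2L))
  expect_equal(iv[[2]], c(3L, 4L))   # boundary click t=6 goes right

  # degenerate risk table: everything in one interval
  rk1 <- risk_table(0, 10)
  expect_equal(assign_intervals(cv, rk1)[[1]], 1:4)
})

test_that("a no-drop curve forces zero events and censorings match the risk table", {
  cv <- digitized_curve(c(0, 12), c(1, 1))
  rk <- risk_table(c(0, 12), c(10, 5))
  r <- reconstruct_ipd(cv, rk)
  expect_equal(r$report$n_events_reconstructed, 0L)
  expect_equal(r$report$n_censored_reconstructed, 10L)
  expect_true(r$report$converged)
  # five censorings strictly inside (0, 12), the rest at the end
  inside <- r$ipd$time > 0 & r$ipd$time < 12
  expect_equal(sum(inside), 5L)
  expect_equal(sum(r$ipd$time == 12), 5L)
  expect_equal(r$report$max_abs_dev, 0)
})

test_that("exact product-limit inversion on the 4-patient hand example", {
  cv <- digitized_curve(0:4, c(1, 0.75, 0.5, 0.25, 0))
  rk <- risk_table(0, 4)
  r <- reconstruct_ipd(cv, rk, total_events = 4)
  expect_equal(sort(r$ipd$time[r$ipd$event == 1]), 1:4)
  expect_equal(sum(r$ipd$event), 4L)
  expect_equal(r$report$max_abs_dev, 0)
  expect_equal(r$report$rmse, 0)
})

test_that("fidelity measures step-function deviation at the click times", {
  ipd <- data.frame(time = c(1, 2, 3), event = c(1L, 1L, 0L),
                    arm = "A", trial_id = "t")
  km <- kaplan_meier(ipd)
  cv_same <- digitized_curve(c(0, 1, 2), c(1, 2/3, 1/3))
  f <- fidelity(cv_same, km)
  expect_equal(f$max_abs_dev, 0)
  # perturb one click by 0.01: max dev 0.01, rmse = 0.01/sqrt(K)
  cv_off <- digitized_curve(c(0, 1, 2), c(1, 2/3, 1/3 - 0.01))
  f <- fidelity(cv_off, km)
  expect_equal(f$max_abs_dev, 0.01, tolerance = 1e-12)
  expect_equal(f$rmse, 0.01 / sqrt(3), tolerance = 1e-12)
  expect_gte(f$max_abs_dev, f$rmse)
})

test_that("reconstruction conserves patients and matches supplied event totals", {
  for (seed in 1:6) {
    cfg <- sim_one_arm(n = 150 + 50 * seed, hazard = 0.004 * seed,
                       seed = 100 + seed)
    ipd <- simulate_ipd(cfg)
    art <- publish_artifacts(ipd, cfg, "A")
    r <- suppressWarnings(reconstruct_ipd(art$curve, art$risk, art$total_events))
    expect_identical(nrow(r$ipd), art$risk$n_risk[1] + 0L)
    expect_equal(r$report$n_events_reconstructed +
                   r$report$n_censored_reconstructed, art$risk$n_risk[1])
    expect_equal(r$report$n_events_reconstructed, art$total_events)
    # and without the event total, conservation still holds
    r2 <- reconstruct_ipd(art$curve, art$risk, total_events = NULL)
    expect_equal(r2$report$n_events_reconstructed +
                   r2$report$n_censored_reconstructed, art$risk$n_risk[1])
  }
})

test_that("interior risk-table boundaries recover the censoring pattern", {
  # Click fidelity is high with or without interior rows (the inversion is
  # self-consistent either way); what the published at-risk counts add is
  # the censoring pattern, visible as event-count recovery.  Median over 20
  # replicates: interior rows keep the event-count error near zero, the
  # bare enrollment count does not.
  res <- sapply(1:20, function(i) {
    cfg <- sim_one_arm(n = 300, hazard = 0.01, seed = 200 + i)
    ipd <- simulate_ipd(cfg)
    art <- publish_artifacts(ipd, cfg, "A")
    truth <- sum(ipd$event)
    coarse <- risk_table(0, art$risk$n_risk[1], trial_id = "sim", arm = "A")
    r_fine <- reconstruct_ipd(art$curve, art$risk, NULL)$report
    r_coarse <- reconstruct_ipd(art$curve, coarse, NULL)$report
    c(dev_fine = r_fine$max_abs_dev, dev_coarse = r_coarse$max_abs_dev,
      everr_fine = abs(r_fine$n_events_reconstructed - truth),
      everr_coarse = abs(r_coarse$n_events_reconstructed - truth))
  })
  expect_lt(median(res["dev_fine", ]), 0.02)
  expect_lt(median(res["dev_coarse", ]), 0.02)
  expect_lt(median(res["everr_fine", ]), median(res["everr_coarse", ]))
  expect_lte(median(res["everr_fine", ]), 2)
})

test_that("reconstruction is deterministic", {
  cfg <- sim_one_arm(n = 250, hazard = 0.012, seed = 5)
  ipd <- simulate_ipd(cfg)
  art <- publish_artifacts(ipd, cfg, "A")
  r1 <- reconstruct_ipd(art$curve, art$risk, art$total_events)
  r2 <- reconstruct_ipd(art$curve, art$risk, art$total_events)
  expect_identical(r1$ipd, r2$ipd)
})
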