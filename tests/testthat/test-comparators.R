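test_that("noise-free MMRM recovers the vertical effect exactly", {
  # linear trajectory: 20% time delay equals a 20% score reduction
  trial <- generate_trial(linear_traj(), 0.20, 5, 36, seed = 1)
  m <- fit_mmrm(trial)
  expect_equal(m$percent_reduction, 0.20, tolerance = 1e-8)
  expect_equal(m$cfb_diff_final, 0.6, tolerance = 1e-8)
  # convex trajectory: the vertical percent exceeds the 20% horizontal delay
  trial2 <- generate_trial(convex_traj(), 0.20, 5, 36, seed = 1)
  m2 <- fit_mmrm(trial2)
  expect_equal(m2$cfb_diff_final, 2.2 - 1.48, tolerance = 1e-8)
  expect_equal(m2$percent_reduction, (2.2 - 1.48) / 2.2, tolerance = 1e-8)
  expect_gt(m2$percent_reduction, 0.20)
})

test_that("identical arms yield a near-zero vertical contrast", {
  trial <- generate_trial(default_trajectory(), 0, 400, 36, seed = 8)
  m <- fit_mmrm(trial)
  expect_lt(abs(m$cfb_diff_final), 3 * m$se)
})

test_that("cLDA and PMRM agree on fitted placebo means and likelihood", {
  # both models saturate the same mean manifold (shared baseline, free
  # placebo means, freely warped active means), so their ML fits coincide
  trial <- generate_trial(default_trajectory(), 0.20, 500, 36, seed = 12)
  pf <- fit_pmrm(trial)
  mf <- fit_mmrm(trial)
  expect_equal(unname(pf$ref_means),
               unname(mf$means_by_arm_visit["placebo", ]),
               tolerance = 5e-3)
  expect_equal(pf$loglik, mf$loglik, tolerance = 1e-4)
})

test_that("the classic CFB-with-baseline MMRM variant is consistent", {
  trial <- generate_trial(default_trajectory(), 0.20, 600, 36, seed = 13)
  a <- fit_mmrm(trial, method = "clda")
  b <- fit_mmrm(trial, method = "cfb")
  expect_true(b$converged)
  # same estimand; estimates agree within sampling-equivalent precision
  expect_lt(abs(a$cfb_diff_final - b$cfb_diff_final), 2 * a$se)
  expect_lt(abs(a$percent_reduction - b$percent_reduction), 0.1)
})

test_that("dichotomization follows the first-crossing rule", {
  mk <- function(values, visits = c(0, 6, 12, 18)) {
    data.frame(subject_id = 1L,
               arm = factor("placebo", levels = c("placebo", "active")),
               visit_month = visits, cdr_sb = values)
  }
  ev <- dichotomize_progression(mk(c(1.5, 2.0, 4.5, 6.0)))
  expect_equal(ev$event_time, 12)
  expect_equal(ev$event, 1L)
  # never crossing: censored at the last visit
  ev2 <- dichotomize_progression(mk(c(1.5, 2.0, 3.0, 4.4)))
  expect_equal(ev2$event_time, 18)
  expect_equal(ev2$event, 0L)
  # baseline above threshold is ignored; first post-baseline crossing counts
  ev3 <- dichotomize_progression(mk(c(4.6, 4.7, 3.0, 3.0)))
  expect_equal(ev3$event_time, 6)
  expect_equal(ev3$event, 1L)
  # raising the threshold never makes an event earlier
  trial <- generate_trial(default_trajectory(), 0.2, 100, 36, seed = 3)
  lo <- dichotomize_progression(trial, 4.5)
  hi <- dichotomize_progression(trial, 6.0)
  expect_true(all(hi$event_time >= lo$event_time))
  expect_true(all(hi$event <= lo$event | hi$event_time >= lo$event_time))
})

test_that("Cox fit matches a brute-force Efron partial likelihood", {
  toy <- data.frame(
    subject_id = 1:6,
    arm = factor(rep(c("placebo", "active"), each = 3),
                 levels = c("placebo", "active")),
    event_time = c(6, 12, 18, 12, 18, 36),
    event = 1L)
  fit <- fit_cox(toy)
  z <- as.integer(toy$arm == "active")
  oracle <- optimize(function(b)
    -efron_loglik(b, toy$event_time, toy$event, z), c(-10, 10))$minimum
  expect_true(fit$estimable)
  expect_equal(fit$log_hr, oracle, tolerance = 1e-4)
  expect_equal(fit$n_events, c(placebo = 3L, active = 3L))
})

test_that("Cox null, effect direction and time-rescaling invariance", {
  # identical event data in both arms: HR of exactly 1
  same <- data.frame(
    subject_id = 1:8,
    arm = factor(rep(c("placebo", "active"), 4),
                 levels = c("placebo", "active")),
    event_time = rep(c(6, 12, 18, 36), each = 2),
    event = rep(c(1L, 1L, 1L, 0L), each = 2))
  expect_equal(fit_cox(same)$hazard_ratio, 1, tolerance = 1e-8)
  # months -> years leaves the hazard ratio unchanged
  trial <- generate_trial(default_trajectory(), 0.2, 300, 36, seed = 21)
  ev <- dichotomize_progression(trial)
  f1 <- fit_cox(ev)
  ev$event_time <- ev$event_time / 12
  f2 <- fit_cox(ev)
  expect_equal(f1$hazard_ratio, f2$hazard_ratio, tolerance = 1e-10)
  expect_lt(f1$hazard_ratio, 1)   # true slowing reduces progression hazard
  # zero events: flagged non-estimable, not an error
  none <- same; none$event <- 0L
  expect_false(fit_cox(none)$estimable)
})
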