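test_that("reference_curve interpolates, flattens and linearizes correctly", {
  v <- c(0, 6, 12, 18, 24, 36)
  # flat data give a constant function everywhere, including extrapolation
  g <- reference_curve(rep(2, 6), v)
  expect_equal(g(c(-10, 3, 17, 36, 50)), rep(2, 5))
  # collinear data give back the line (natural spline of a line is the line)
  g <- reference_curve(0.5 + 0.1 * v, v)
  xs <- c(-6, 2.5, 9, 28.8, 36, 45)
  expect_equal(g(xs), 0.5 + 0.1 * xs)
  # knot values are reproduced exactly
  set.seed(4)
  y <- cumsum(runif(6))
  g <- reference_curve(y, v)
  expect_equal(g(v), y)
  # fewer than 3 visits: linear fallback with a warning
  expect_warning(g2 <- reference_curve(c(0, 1), c(0, 12)), "linear")
  expect_equal(g2(6), 0.5)
})

test_that("noise-free proportional slowing is recovered at every visit", {
  trial <- generate_trial(gentle_traj(), 0.20, 5, 36, seed = 1)
  fit <- fit_pmrm(trial)
  expect_true(fit$converged)
  # generation interpolates linearly, the model inverts a spline: a small
  # discrepancy is inherent, but stays below one percentage point
  expect_true(all(abs(fit$percent_slowing - 0.20) < 0.01))
})

test_that("null data give near-zero delays with honest coverage", {
  traj <- default_trajectory()
  hits <- 0L; total <- 0L
  for (r in 1:40) {
    trial <- generate_trial(traj, 0, 150, 36, seed = 300 + r)
    fit <- fit_pmrm(trial)
    if (!fit$converged || !fit$se_available) next
    hits <- hits + sum(abs(fit$delays) <= 2 * fit$delay_se)
    total <- total + length(fit$delays)
  }
  expect_gt(total, 150)
  expect_gt(hits / total, 0.85)   # ~95% nominal, binomial slack
})

test_that("optimized likelihood beats the generative parameters", {
  traj <- default_trajectory()
  trial <- generate_trial(traj, 0.20, 200, 36, seed = 17)
  fit <- fit_pmrm(trial)
  v <- traj$visit_months
  gen_ll <- progdelay:::full_loglik(
    trial, traj$placebo_means,
    active_mean_at(traj, 0.20, v), traj$covariance)
  expect_gte(fit$loglik, gen_ll)
})

test_that("delays are equivariant to score shifts and time rescaling", {
  traj <- default_trajectory()
  trial <- generate_trial(traj, 0.20, 120, 36, seed = 23)
  fit <- fit_pmrm(trial)
  shifted <- trial
  shifted$cdr_sb <- shifted$cdr_sb + 3
  fs <- fit_pmrm(shifted)
  expect_equal(unname(fs$ref_means), unname(fit$ref_means) + 3,
               tolerance = 1e-4)
  expect_equal(unname(fs$delays), unname(fit$delays), tolerance = 1e-3)
  scaled <- trial
  scaled$visit_month <- scaled$visit_month * 2
  fk <- fit_pmrm(scaled)
  expect_equal(unname(fk$delays), 2 * unname(fit$delays), tolerance = 2e-3)
  expect_equal(unname(fk$percent_slowing), unname(fit$percent_slowing),
               tolerance = 5e-3)
})

test_that("PMRM delay and MMRM reduction coincide for linear trajectories", {
  # noise-free: both equal the generative 20% exactly
  trial0 <- generate_trial(linear_traj(), 0.20, 5, 36, seed = 1)
  expect_equal(unname(fit_pmrm(trial0)$percent_slowing),
               rep(0.20, 3), tolerance = 1e-6)
  expect_equal(fit_mmrm(trial0)$percent_reduction, 0.20, tolerance = 1e-6)
  # with noise the fitted reference curve is no longer exactly straight, so
  # the horizontal and vertical percents agree only up to sampling curvature
  trial <- generate_trial(linear_traj(noise = 1), 0.20, 800, 36, seed = 2)
  pf <- fit_pmrm(trial); mf <- fit_mmrm(trial)
  expect_lt(abs(unname(pf$percent_slowing[3]) - mf$percent_reduction), 0.02)
})

test_that("Wald confidence intervals follow the normal quantiles", {
  traj <- default_trajectory()
  trial <- generate_trial(traj, 0.20, 150, 36, seed = 31)
  fit <- fit_pmrm(trial)
  # frozen arithmetic example: 7.2 +/- 1.959964 * 1.0
  fake <- fit
  fake$delays[] <- c(1, 2, 3, 5, 7.2)
  fake$delay_se[] <- c(rep(0.5, 4), 1.0)
  ci <- delay_confidence_interval(fake, 36, 0.95)
  expect_equal(ci$lower, 5.240036, tolerance = 1e-5)
  expect_equal(ci$upper, 9.159964, tolerance = 1e-5)
  expect_equal(ci$percent_lower, ci$lower / 36)
  expect_equal(ci$percent_upper, ci$upper / 36)
  # degenerate SE = 0 collapses to the point estimate
  fake$delay_se[] <- 0
  ci0 <- delay_confidence_interval(fake, 36)
  expect_equal(ci0$lower, ci0$estimate)
  expect_equal(ci0$upper, ci0$estimate)
  # unavailable SEs are reported, not silently dropped
  fake$se_available <- FALSE
  ciNA <- delay_confidence_interval(fake, 36)
  expect_false(ciNA$available)
  expect_true(is.na(ciNA$lower))
  expect_error(delay_confidence_interval(fit, 7), "post-baseline")
})
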