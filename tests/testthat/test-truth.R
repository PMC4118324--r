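## configurations with closed-form expectations use exponential
## intensities, for which the delayed-entry correction leaves the
## post-exposure hazard unchanged (memorylessness)

exp_config <- function(l12 = 0.004, l13 = 0.003, ratio = 1, beta23 = c(0, 0, 0)) {
  scenario_config(
    spec12 = transition_spec("exponential", rate = l12),
    spec13 = transition_spec("exponential", rate = l13),
    spec23 = transition_spec("exponential", rate = l13 * ratio,
                             beta = beta23),
    censoring = censoring_scheme("none"), n_per_profile = 250, tmax = 1000)
}

test_that("full homogeneity gives a hazard ratio of one everywhere", {
  tr <- truth_curves(exp_config(ratio = 1), K = 500)
  expect_equal(tr$hr_bar, rep(1, 500), tolerance = 1e-3)
  expect_equal(tr$hr_profile, matrix(1, 8, 500), tolerance = 1e-3)
})

test_that("a proportional exposure effect is recovered exactly", {
  tr <- truth_curves(exp_config(ratio = 1.8), K = 500)
  expect_equal(tr$hr_bar, rep(1.8, 500), tolerance = 2e-3)
})

test_that("risk-mass weights are normalized and masses behave at the boundaries", {
  cfg <- reference_scenario()
  tr <- truth_curves(cfg, K = 400)
  expect_equal(colSums(tr$w13), rep(1, 400), tolerance = 1e-12)
  expect_equal(colSums(tr$w23), rep(1, 400), tolerance = 1e-12)
  ## transition 1->3 masses start at the profile size and never increase
  rm <- risk_masses(cfg, c(0, 0, 0), K = 400)
  expect_lt(abs(rm$n13[1] - 250), 5)
  expect_true(all(diff(rm$n13) <= 1e-9))
  ## exposed-state mass starts empty, grows, then drains
  expect_lt(rm$n23[1], 5)
  expect_gt(max(rm$n23), 50)
  ## no censoring: entries - deaths only (mass stays non-negative)
  expect_true(all(rm$n23 >= -1e-9))
})

test_that("the exposed-state survival collapses to the duration survival under instant exposure", {
  ## 1->2 nearly instantaneous: everyone is exposed at t ~ 0, so the
  ## delayed-entry correction vanishes and S23 equals the raw survival
  cfg <- scenario_config(
    spec12 = transition_spec("exponential", rate = 5),
    spec13 = transition_spec("exponential", rate = 1e-4),
    spec23 = transition_spec("weibull", scale = 0.0039, shape = 1.1881),
    censoring = censoring_scheme("none"), n_per_profile = 250, tmax = 1000)
  s <- s23_left_truncated(cfg, c(0, 0, 0), K = 2000)
  expect_true(all(diff(s$s23) <= 1e-12))
  expect_lt(s$s23[1], 1 + 1e-9)
  raw <- survival_value(cfg$spec23, s$time, c(0, 0, 0))
  expect_equal(s$s23[s$time >= 50], raw[s$time >= 50], tolerance = 0.02)
})

test_that("exchangeable exponential transitions give matching hazards", {
  cfg <- exp_config(ratio = 1)
  s <- s23_left_truncated(cfg, c(1, 0, 1), K = 1000)
  expect_equal(s$lam23[s$time > 20], rep(0.003, sum(s$time > 20)),
               tolerance = 1e-4)
})

test_that("the discretization converges under grid refinement", {
  cfg <- reference_scenario()
  t1 <- truth_curves(cfg, K = 500)
  t2 <- truth_curves(cfg, K = 1000)
  on_coarse <- approx(t2$time, t2$hr_bar, xout = t1$time)$y
  rel <- abs(on_coarse - t1$hr_bar) / t1$hr_bar
  expect_lt(max(rel[t1$time > 25], na.rm = TRUE), 0.005)
})

test_that("truth curves match Monte-Carlo binned hazard ratios", {
  cfg <- reference_scenario(n_per_profile = 125000)  # one million subjects
  coh <- simulate_cohort(cfg, seed = 314)
  breaks <- seq(50, 800, by = 75)
  mc <- mc_binned_hazards(coh, breaks)
  tr <- truth_curves(reference_scenario(), K = 2000)
  idx <- findInterval(tr$time, breaks)
  for (b in seq_len(length(breaks) - 1)) {
    sel <- idx == b & tr$time > breaks[1]
    ## person-time weighted average of the theoretical hazards in the bin
    th23 <- sum((colSums(tr$N23 * tr$lam23))[sel]) / sum(colSums(tr$N23)[sel])
    th13 <- sum((colSums(tr$N13 * tr$lam13))[sel]) / sum(colSums(tr$N13)[sel])
    expect_equal(mc$hr[b], th23 / th13, tolerance = 0.05)
    expect_equal(mc$h23[b], th23, tolerance = 0.05)
    expect_equal(mc$h13[b], th13, tolerance = 0.05)
  }
})

test_that("risk masses match Monte-Carlo at-risk counts", {
  cfg <- reference_scenario(n_per_profile = 125000)
  coh <- simulate_cohort(cfg, seed = 2718)
  tr <- truth_curves(reference_scenario(), K = 2000)
  scale <- 125000 / 250
  for (tt in c(100, 300, 600)) {
    k <- which.min(abs(tr$time - tt))
    for (w in c(1, 8)) {
      prof <- rownames(covariate_profiles())[w]
      sub <- coh[coh$profile == prof, ]
      mc13 <- sum(sub$t_exposure > tt & sub$t_final >= tt)
      mc23 <- sum(sub$t_exposure <= tt & sub$t_final >= tt)
      expect_equal(tr$N13[w, k] * scale, mc13, tolerance = 0.02)
      expect_equal(tr$N23[w, k] * scale, mc23, tolerance = 0.02)
    }
  }
})

test_that("per-profile truth reduces to one under exchangeable transitions", {
  tr <- truth_curves(exp_config(ratio = 1, beta23 = c(0, 0, 0)), K = 300)
  expect_equal(tr$hr_profile[3, ], rep(1, 300), tolerance = 2e-3)
})

test_that("empirical large-sample curves agree with the theoretical engine", {
  ## the consistency check between the discretized theoretical curve and
  ## the large-cohort regression approximation of the same quantity
  cfg <- reference_scenario()
  coh <- simulate_cohort(reference_scenario(n_per_profile = 250), seed = 5)
  grid <- default_interval_grid(coh, L = 4)
  emp <- empirical_hr_curves(cfg, grid, n_large = 120000, seed = 55)
  tr <- truth_curves(cfg, K = 2000)
  ## information weighting concentrates where exposed events occur; use
  ## the exposed-event density as weight when averaging the curve
  idx <- findInterval(tr$time, c(grid$cuts, Inf)) + 1
  w23 <- colSums(tr$N23 * tr$lam23)
  for (l in 1:4) {
    thlog <- weighted.mean(log(tr$hr_bar)[idx == l], w23[idx == l])
    expect_lt(abs(emp$log_hr_bar[l] - thlog), 0.12)
  }
  ## per-profile empirical curves follow the theoretical profile ordering
  expect_gt(mean(emp$log_hr_profile[1, 2:4]), 0.8)
  expect_lt(mean(emp$log_hr_profile[8, 2:4]), -0.8)
})

test_that("constant-ratio scenarios give flat empirical interval estimates", {
  cfg <- exp_config(l12 = 0.005, l13 = 0.003, ratio = 1.5)
  grid <- interval_grid(c(150, 300, 500), tmax = 1000)
  emp <- empirical_hr_curves(cfg, grid, n_large = 80000, seed = 21)
  expect_equal(emp$hr_bar, rep(1.5, 4), tolerance = 0.08)
  expect_equal(emp$hr_bar_adjusted, rep(1.5, 4), tolerance = 0.08)
})
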