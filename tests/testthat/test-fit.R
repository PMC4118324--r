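grid1 <- interval_grid(numeric(), tmax = 1000)

test_that("the stratified fit matches a brute-force partial-likelihood oracle", {
  for (seed in c(99, 123, 7)) {
    p <- oracle_toy_pairs(3, seed)
    tab <- build_counting_process(p, "hp", grid1)
    ft <- suppressWarnings(fit_stratified_cox(tab, grid1))
    if (!ft$converged) next  # separable toys checked separately
    bhat <- oracle_coxmle(matrix(tab$e1, ncol = 1), tab$start, tab$stop,
                          tab$event, stratum = tab$pair_id)
    expect_equal(unname(ft$gamma), bhat, tolerance = 1e-6)
  }
})

test_that("the marginal fit matches brute-force likelihood and sandwich oracles", {
  p <- oracle_toy_pairs(4, 42)
  tab <- build_counting_process(p, "lwa", grid1)
  ft <- fit_marginal_cox(tab, grid1, "unadjusted")
  X <- matrix(tab$e1, ncol = 1)
  bhat <- oracle_coxmle(X, tab$start, tab$stop, tab$event)
  expect_equal(unname(ft$gamma), bhat, tolerance = 1e-6)
  V <- oracle_sandwich(bhat, X, tab$start, tab$stop, tab$event, tab$pair_id)
  expect_equal(as.numeric(ft$vcov_robust), as.numeric(V), tolerance = 1e-4)
  ## adjusted variant against the multi-parameter oracle (a larger toy so
  ## no coefficient is separable)
  p12 <- oracle_toy_pairs(12, 8)
  tab12 <- build_counting_process(p12, "lwa", grid1)
  fta <- suppressWarnings(fit_marginal_cox(tab12, grid1, "adjusted"))
  Xa <- as.matrix(tab12[, c("e1", "z1", "z2", "z3")])
  keep <- !is.na(fta$coef)
  Xk <- Xa[, keep, drop = FALSE]
  bk <- oracle_coxmle(Xk, tab12$start, tab12$stop, tab12$event)
  expect_equal(unname(fta$coef[keep]), bk, tolerance = 1e-5)
})

test_that("marginal point estimates equal the unclustered fit", {
  cfg <- reference_scenario(n_per_profile = 80)
  coh <- simulate_cohort(cfg, seed = 61)
  p2 <- match_cohort(coh, 2, seed = 62)
  grid <- default_interval_grid(coh, L = 2)
  tab <- build_counting_process(p2, "lwa", grid)
  ft <- fit_marginal_cox(tab, grid, "unadjusted")
  plain <- survival::coxph(survival::Surv(start, stop, event) ~ e1 + e2,
                           data = as.data.frame(tab), ties = "breslow")
  expect_equal(unname(ft$gamma), unname(coef(plain)), tolerance = 1e-10)
  ## the sandwich only changes the covariance, not the estimates
  expect_false(isTRUE(all.equal(ft$vcov_robust, ft$vcov_naive)))
})

test_that("the sandwich reduces to the naive variance for singleton clusters", {
  p <- oracle_toy_pairs(6, 11)
  tab <- build_counting_process(p, "lwa", grid1)
  tab$pair_id <- seq_len(nrow(tab))     # every row its own cluster
  ft <- fit_marginal_cox(tab, grid1, "unadjusted")
  ## with one row per cluster the robust estimator is the usual
  ## infinitesimal-jackknife form D'D; check it against the oracle B
  X <- matrix(tab$e1, ncol = 1)
  V <- oracle_sandwich(unname(ft$gamma), X, tab$start, tab$stop, tab$event,
                       tab$pair_id)
  expect_equal(as.numeric(ft$vcov_robust), as.numeric(V), tolerance = 1e-6)
})

test_that("time-fixed and time-dependent codings agree for stratified a posteriori fits", {
  cfg <- reference_scenario(n_per_profile = 80)
  for (s in 1:3) {
    coh <- simulate_cohort(cfg, seed = 70 + s)
    p1 <- match_cohort(coh, 1, seed = 80 + s)
    grid <- default_interval_grid(coh, L = 4)
    td <- build_counting_process(p1, "hp", grid)
    fx <- build_counting_process(p1, "hp", grid, exposure_coding = "fixed")
    f1 <- fit_stratified_cox(td, grid)
    f2 <- fit_stratified_cox(fx, grid)
    expect_equal(f1$gamma, f2$gamma, tolerance = 1e-8)
  }
})

test_that("a single discordant pair gives a monotone likelihood that is flagged", {
  coh <- toy_cohort(data.frame(
    id = 1:2, z1 = 0, z2 = 0, z3 = 0,
    t_exposure = c(1, Inf), t_final = c(5, 9),
    exposed = c(1L, 0L), event = c(1L, 0L)))
  p <- structure(data.frame(pair_id = 1, exposed_id = 1, control_id = 2,
                            t_formation = 1, perfect = 1L, profile = "000",
                            z1 = 0, z2 = 0, z3 = 0),
                 cohort = coh, method = 1, class = c("rsm_pairs", "data.frame"))
  tab <- build_counting_process(p, "hp", grid1)
  ft <- suppressWarnings(fit_stratified_cox(tab, grid1))
  expect_false(ft$converged)
  expect_gt(ft$gamma, 10)
})

test_that("fits refuse event-free tables", {
  p <- oracle_toy_pairs(3, 5)
  tab <- build_counting_process(p, "lwa", grid1)
  tab$event <- 0L
  expect_error(fit_marginal_cox(tab, grid1), "no events")
  expect_error(fit_stratified_cox(tab, grid1), "no events")
})

test_that("interaction fits expose profile-specific effects", {
  cfg <- reference_scenario(n_per_profile = 150)
  coh <- simulate_cohort(cfg, seed = 91)
  p2 <- match_cohort(coh, 2, seed = 92)
  grid <- default_interval_grid(coh, L = 2)
  tab <- build_counting_process(p2, "lwa", grid)
  ft <- fit_marginal_cox(tab, grid, "interaction")
  expect_equal(dim(ft$alpha), c(2L, 3L))
  ## gamma_l + alpha_l' z, by hand
  z <- c(1, 0, 1)
  expect_equal(profile_loghr(ft, z),
               unname(unname(ft$gamma) + ft$alpha[, 1] + ft$alpha[, 3]))
  ## the healthy-exposure scenario induces opposite-signed effects in the
  ## extreme profiles
  expect_gt(mean(profile_loghr(ft, c(0, 0, 0))),
            mean(profile_loghr(ft, c(1, 1, 1))))
})

test_that("the proportional-hazards check behaves at null and alternative", {
  ## strongly time-varying true effect, L = 1: the test must reject
  ## (checked on the full cohort, where the effect curve is steepest)
  cfg <- reference_scenario()
  coh <- simulate_cohort(cfg, seed = 101)
  tabc <- cohort_counting_process(coh, grid1)
  tabc$pair_id <- seq_len(nrow(tabc))
  ftc <- fit_marginal_cox(tabc, grid1, "unadjusted")
  ph <- ph_assumption_check(ftc)
  expect_true(all(ph$p >= 0 & ph$p <= 1))
  expect_lt(ph$p[ph$term == "e1"], 0.01)
  ## constant-hazard-ratio data: no rejection expected most of the time
  cfg0 <- hr_configuration("constant", n_per_profile = 150)
  coh0 <- simulate_cohort(cfg0, seed = 103)
  p0 <- match_cohort(coh0, 2, seed = 104)
  tab0 <- build_counting_process(p0, "lwa", grid1)
  ft0 <- fit_marginal_cox(tab0, grid1, "unadjusted")
  ph0 <- ph_assumption_check(ft0)
  expect_gt(ph0$p[ph0$term == "e1"], 0.01)
  ## degenerate input
  ft_small <- ft0
  ft_small$n_events <- 2L
  expect_error(ph_assumption_check(ft_small), "fewer than 3")
})

test_that("fit results serialize to JSON and back", {
  p <- oracle_toy_pairs(4, 13)
  tab <- build_counting_process(p, "lwa", grid1)
  ft <- suppressWarnings(fit_marginal_cox(tab, grid1, "adjusted"))
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_json(ft, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$gamma$e1, unname(ft$gamma), tolerance = 1e-12)
  expect_equal(back$n_events, ft$n_events)
})
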