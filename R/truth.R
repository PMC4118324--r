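## True exposure effects of an illness-death scenario.
##
## The hazard ratio of interest compares, on the time-since-origin scale,
## the final-event hazard of exposed subjects with that of unexposed
## ones.  Because a subject only enters the exposed state at her own
## exposure time (delayed entry), the population hazard after exposure is
## a left-truncation-corrected mixture, not the raw duration intensity:
## it is recovered on a fine discretization grid from the convolution of
## the entry density into the exposed state with the duration density of
## the final event.

cumtrapz_uniform <- function(y, dt) c(0, cumsum((y[-1] + y[-length(y)]) / 2) * dt)

## trapezoid convolution integral r(t_j) = int_0^{t_j} x(u) y(t_j - u) du
## on a uniform grid including t = 0, via FFT
conv_trapz <- function(x, y, dt) {
  n <- length(x)
  cc <- stats::convolve(x, rev(y), type = "open")[seq_len(n)]
  r <- dt * (cc - 0.5 * x[1] * y - 0.5 * x * y[1])
  pmax(r, 0)
}

#' True hazard-ratio curves of a scenario
#'
#' Computes, on a uniform grid of \code{K} steps over
#' \eqn{[0, t_{max}]}, the per-profile final-event hazards with and
#' without exposure, the at-risk masses of both transitions, and the
#' population-average exposure hazard ratio
#' \deqn{\overline{HR}(t) = \frac{\sum_z N_{23z}(t)\lambda_{23z}(t) / \sum_z N_{23z}(t)}
#'                               {\sum_z N_{13z}(t)\lambda_{13z}(t) / \sum_z N_{13z}(t)},}
#' where \eqn{\lambda_{23z}} is the left-truncation-corrected hazard of
#' the final event after exposure.  The exposed-state construction
#' follows the step-by-step product of one-step conditional survival
#' factors (entries minus accumulated deaths); its per-step conditional
#' hazard -- the death density over the current at-risk mass, evaluated
#' at the step midpoint for second-order accuracy -- is the default
#' (\code{hazard_form = "conditional"}), with the cumulative-average
#' reading \eqn{-\log S_{23}(t_k)/(t_k - t_{k-1})} kept available for
#' comparison.  All curves are reported at the step midpoints.
#'
#' At-risk masses follow the closed forms
#' \eqn{N_{13z}(t) = n_z S_{13z}(t)\bar G(t) S_{12z}(t)} and
#' \eqn{N_{23z}(t) = n_z\{E_{23z}(t) - D_{23z}(t) - C_{23z}(t)\}}
#' (entries minus deaths minus censorings, each a quadrature of the
#' corresponding density).
#'
#' @param config a \code{\link{scenario_config}}.
#' @param K number of discretization steps (default 2000 over the
#'   horizon; refine and compare to check convergence).
#' @param hazard_form \code{"conditional"} or \code{"cumulative"}.
#' @return object of class \code{"rsm_truth"}: \code{time} (the K step
#'   right endpoints), \code{hr_bar}, \code{log_hr_bar},
#'   \code{hr_profile} (8 x K), \code{lam13}, \code{lam23}, \code{N13},
#'   \code{N23} (8 x K), and the weight matrices \code{w13}, \code{w23}
#'   whose columns sum to one.
#' @examples
#' tr <- truth_curves(reference_scenario(), K = 400)
#' range(tr$hr_bar)
#' @export
truth_curves <- function(config, K = 2000L, hazard_form = c("conditional", "cumulative")) {
  stopifnot(inherits(config, "rsm_scenario"))
  hazard_form <- match.arg(hazard_form)
  tmax <- config$tmax
  dt <- tmax / K
  tg <- seq(0, tmax, length.out = K + 1L)   # t_0 .. t_K
  tm <- tg[-1] - dt / 2                     # step midpoints
  profs <- covariate_profiles()
  npp <- config$n_per_profile
  cens <- config$censoring
  Gbar <- censoring_survival(cens, tg)
  gdens <- censoring_density(cens, tg)
  lam13 <- lam23 <- hrp <- N13 <- N23 <- matrix(NA_real_, 8L, K)
  for (w in 1:8) {
    z <- profs[w, ]
    rr12 <- relative_risk(config$spec12, z, config$zbar)
    rr13 <- relative_risk(config$spec13, z, config$zbar)
    rr23 <- relative_risk(config$spec23, z, config$zbar)
    s12 <- exp(-base_cumhaz(config$spec12, tg) * rr12)
    s13 <- exp(-base_cumhaz(config$spec13, tg) * rr13)
    f12 <- base_hazard(config$spec12, tg) * rr12 * s12
    ## entry density into the exposed state (exposure before any event)
    q <- f12 * s13
    A <- cumtrapz_uniform(q, dt)
    ## duration density/survival of the final event after exposure
    h23 <- base_hazard(config$spec23, tg) * rr23
    s23raw <- exp(-base_cumhaz(config$spec23, tg) * rr23)
    f23raw <- h23 * s23raw
    ftilde <- conv_trapz(q, f23raw, dt)       # final-event subdensity
    D <- cumtrapz_uniform(ftilde, dt)
    ## per-step conditional hazard of the exposed state, evaluated at the
    ## step midpoint for second-order accuracy: deaths density over the
    ## at-risk mass (entries minus accumulated deaths)
    AD <- A - D
    fmid <- (ftilde[-1] + ftilde[-length(ftilde)]) / 2
    admid <- (AD[-1] + AD[-length(AD)]) / 2
    rate <- ifelse(admid > 1e-300, fmid / admid, 0)
    lam23[w, ] <- switch(hazard_form,
      conditional = rate,
      cumulative = -log(pmax(cumprod(1 - pmin(rate * dt, 1)), 1e-300)) / dt)
    lam13[w, ] <- base_hazard(config$spec13, tm) * rr13
    hrp[w, ] <- lam23[w, ] / lam13[w, ]
    ## at-risk masses at the step midpoints
    N13[w, ] <- npp * exp(-base_cumhaz(config$spec13, tm) * rr13) *
      exp(-base_cumhaz(config$spec12, tm) * rr12) * censoring_survival(cens, tm)
    E23 <- cumtrapz_uniform(Gbar * q, dt)
    D23 <- cumtrapz_uniform(Gbar * ftilde, dt)
    C23 <- if (cens$kind == "none") rep_len(0, K + 1L)
           else cumtrapz_uniform(gdens * conv_trapz(q, s23raw, dt), dt)
    M <- E23 - D23 - C23
    N23[w, ] <- npp * (M[-1] + M[-length(M)]) / 2
  }
  sum23 <- colSums(N23)
  sum13 <- colSums(N13)
  lbar23 <- colSums(N23 * lam23) / sum23
  lbar13 <- colSums(N13 * lam13) / sum13
  hr_bar <- ifelse(sum23 > 0 & sum13 > 0, lbar23 / lbar13, NA_real_)
  structure(list(time = tm, dt = dt, K = K,
                 hr_bar = hr_bar, log_hr_bar = log(hr_bar),
                 hr_profile = hrp,
                 lam13 = lam13, lam23 = lam23,
                 N13 = N13, N23 = N23,
                 w13 = sweep(N13, 2, sum13, "/"),
                 w23 = sweep(N23, 2, sum23, "/"),
                 hazard_form = hazard_form,
                 config = config),
            class = "rsm_truth")
}

#' @export
print.rsm_truth <- function(x, ...) {
  cat(sprintf("<truth curves: K = %d over [0, %g]; HR range %.3f - %.3f>\n",
              x$K, x$config$tmax, min(x$hr_bar, na.rm = TRUE),
              max(x$hr_bar, na.rm = TRUE)))
  invisible(x)
}

#' Left-truncation-corrected survival of the exposed state
#'
#' The discretized survival \eqn{S_{23z}(t_k)} of the final event among
#' exposed subjects of one profile, on the time-since-origin scale.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param profile binary vector \eqn{(z_1, z_2, z_3)}.
#' @param K discretization steps.
#' @return data.frame with \code{time}, \code{s23} (non-increasing from
#'   1) and the per-step hazard \code{lam23}.
#' @export
s23_left_truncated <- function(config, profile, K = 2000L) {
  cfg <- config
  tr <- truth_curves(cfg, K = K)
  w <- profile_index(profile[1], profile[2], profile[3])
  lam <- tr$lam23[w, ]
  data.frame(time = tr$time, s23 = exp(-cumsum(lam) * tr$dt), lam23 = lam)
}

#' At-risk masses of the two final-event transitions
#'
#' @inheritParams s23_left_truncated
#' @return data.frame with \code{time}, \code{n13}, \code{n23}.
#' @export
risk_masses <- function(config, profile, K = 2000L) {
  tr <- truth_curves(config, K = K)
  w <- profile_index(profile[1], profile[2], profile[3])
  data.frame(time = tr$time, n13 = tr$N13[w, ], n23 = tr$N23[w, ])
}

#' Population-average exposure hazard ratio
#'
#' @inheritParams truth_curves
#' @return data.frame with \code{time} and \code{hr_bar}.
#' @export
average_hr_unadjusted <- function(config, K = 2000L) {
  tr <- truth_curves(config, K = K)
  data.frame(time = tr$time, hr_bar = tr$hr_bar)
}

#' Average true log hazard ratios over an interval grid
#'
#' Plain time-average of the log truth curve inside each interval
#' \eqn{I_l}, used as the per-interval reference value when comparing
#' piecewise-constant estimates with the continuous truth.
#'
#' @param truth an \code{rsm_truth}.
#' @param grid an \code{\link{interval_grid}}.
#' @param what \code{"bar"} for the population-average curve,
#'   \code{"profile"} for the 8 per-profile curves.
#' @return length-L vector, or 8 x L matrix for \code{"profile"}.
#' @export
interval_average_loghr <- function(truth, grid, what = c("bar", "profile")) {
  what <- match.arg(what)
  idx <- interval_of(truth$time, grid)
  avg <- function(v) vapply(seq_len(grid$L),
                            function(l) mean(log(v[idx == l]), na.rm = TRUE),
                            numeric(1))
  if (what == "bar") avg(truth$hr_bar)
  else t(vapply(1:8, function(w) avg(truth$hr_profile[w, ]), numeric(grid$L)))
}

#' Empirical large-sample reference hazard ratios
#'
#' Simulates one large cohort from the scenario and fits the three
#' proportional-hazards specifications with per-interval exposure
#' indicators to its counting-process form: exposure effects only,
#' exposure plus covariate main effects (whose exposure coefficients
#' define the covariate-adjusted average \eqn{\overline{HR}_a} per
#' interval), and exposure-by-covariate interactions (giving the
#' per-profile \eqn{HR_i}).  The adjusted average has no closed form;
#' this empirical procedure is its definition.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param grid an \code{\link{interval_grid}}.
#' @param n_large total cohort size (split equally over the 8 profiles).
#' @param seed integer seed (mandatory; recorded in the result).
#' @return object of class \code{"rsm_truth_empirical"} with per-interval
#'   \code{hr_bar}, \code{hr_bar_adjusted}, \code{hr_profile} (8 x L) and
#'   their logs.
#' @export
empirical_hr_curves <- function(config, grid, n_large = 200000L, seed) {
  stopifnot(inherits(grid, "rsm_grid"))
  cfg <- config
  cfg$n_per_profile <- as.integer(ceiling(n_large / 8))
  coh <- simulate_cohort(cfg, seed)
  tab <- cohort_counting_process(coh, grid)
  df <- as.data.frame(tab)
  fit1 <- survival::coxph(formula_for(grid, "unadjusted"), data = df,
                          ties = "breslow")
  fit2 <- survival::coxph(formula_for(grid, "adjusted"), data = df,
                          ties = "breslow")
  fit3 <- survival::coxph(formula_for(grid, "interaction"), data = df,
                          ties = "breslow")
  gam <- function(f) stats::coef(f)[exposure_colnames(grid$L)]
  cf3 <- stats::coef(fit3)
  profs <- covariate_profiles()
  lhp <- matrix(NA_real_, 8L, grid$L)
  for (w in 1:8) {
    z <- as.numeric(profs[w, ])
    for (l in seq_len(grid$L)) {
      anm <- paste0("e", l, ":z", 1:3)
      lhp[w, l] <- cf3[paste0("e", l)] + sum(cf3[anm] * z)
    }
  }
  structure(list(grid = grid,
                 log_hr_bar = unname(gam(fit1)),
                 log_hr_bar_adjusted = unname(gam(fit2)),
                 log_hr_profile = lhp,
                 hr_bar = exp(unname(gam(fit1))),
                 hr_bar_adjusted = exp(unname(gam(fit2))),
                 hr_profile = exp(lhp),
                 n_large = 8L * cfg$n_per_profile, seed = seed),
            class = "rsm_truth_empirical")
}

formula_for <- function(grid, variant) {
  stats::as.formula(paste("Surv(start, stop, event) ~",
                          paste(fit_names(grid, variant), collapse = " + ")))
}
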