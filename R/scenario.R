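#' The eight covariate profiles of the balanced design
#'
#' Subjects carry three binary matching covariates, giving \eqn{2^3 = 8}
#' profiles.  Rows are ordered with \eqn{z_3} varying fastest, i.e.
#' (0,0,0), (0,0,1), (0,1,0), ..., (1,1,1).
#'
#' @return an 8 x 3 integer matrix with columns \code{z1}, \code{z2},
#'   \code{z3} and row names like \code{"010"}.
#' @export
covariate_profiles <- function() {
  m <- as.matrix(expand.grid(z3 = 0:1, z2 = 0:1, z1 = 0:1))[, 3:1]
  colnames(m) <- c("z1", "z2", "z3")
  rownames(m) <- apply(m, 1L, paste, collapse = "")
  storage.mode(m) <- "integer"
  m
}

profile_index <- function(z1, z2, z3) 4L * z1 + 2L * z2 + z3 + 1L

#' Censoring scheme
#'
#' Independent uniform censoring over \eqn{[0, c_{max}]}, or none.  The
#' designs studied use \eqn{c_{max} \in \{t_{max}, 2 t_{max}, +\infty\}}.
#'
#' @param kind \code{"none"} or \code{"uniform"}.
#' @param cmax upper bound of the uniform support; ignored when
#'   \code{kind = "none"}.
#' @export
censoring_scheme <- function(kind = c("none", "uniform"), cmax = Inf) {
  kind <- match.arg(kind)
  if (kind == "uniform" && (!is.finite(cmax) || cmax <= 0))
    stop("uniform censoring needs a finite cmax > 0")
  structure(list(kind = kind, cmax = if (kind == "none") Inf else cmax),
            class = "rsm_censoring")
}

## survival function and density of the censoring time
censoring_survival <- function(cens, t) {
  if (cens$kind == "none") rep_len(1, length(t))
  else pmax(0, 1 - t / cens$cmax)
}
censoring_density <- function(cens, t) {
  if (cens$kind == "none") rep_len(0, length(t))
  else as.numeric(t >= 0 & t <= cens$cmax) / cens$cmax
}

#' Scenario configuration for the illness-death simulator
#'
#' Bundles the three transition intensities (initial state to exposure,
#' initial state to final event, exposure to final event), the censoring
#' scheme, the per-profile sample size and the administrative horizon.
#' All transitions are timed from the origin (diagnosis); the duration
#' spent in the exposed state before the final event is drawn from the
#' 2-to-3 intensity and added to the exposure time.
#'
#' @param spec12,spec13,spec23 \code{\link{transition_spec}} objects for
#'   transitions 1-2, 1-3 and 2-3.
#' @param censoring a \code{\link{censoring_scheme}}.
#' @param n_per_profile subjects allocated to each of the 8 profiles.
#' @param tmax administrative horizon; every subject still under follow-up
#'   at \code{tmax} is censored there.
#' @param zbar anchoring profile for the average-intensity parametrization.
#' @param label free-text scenario label.
#' @export
scenario_config <- function(spec12, spec13, spec23,
                            censoring = censoring_scheme("none"),
                            n_per_profile = 250L, tmax = 1000,
                            zbar = c(0.5, 0.5, 0.5), label = "") {
  stopifnot(inherits(spec12, "rsm_transition"),
            inherits(spec13, "rsm_transition"),
            inherits(spec23, "rsm_transition"),
            inherits(censoring, "rsm_censoring"))
  if (n_per_profile < 1L) stop("'n_per_profile' must be >= 1")
  if (tmax <= 0) stop("'tmax' must be > 0")
  structure(list(spec12 = spec12, spec13 = spec13, spec23 = spec23,
                 censoring = censoring,
                 n_per_profile = as.integer(n_per_profile),
                 tmax = tmax, zbar = zbar, label = label),
            class = "rsm_scenario")
}

#' @export
print.rsm_scenario <- function(x, ...) {
  cat(sprintf("<scenario%s: %d x 8 subjects, tmax = %g, censoring = %s>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$n_per_profile, x$tmax,
              if (x$censoring$kind == "none") "none"
              else sprintf("uniform[0, %g]", x$censoring$cmax)))
  for (tr in c("spec12", "spec13", "spec23")) {
    cat(" ", sub("spec", "", tr), ": ", sep = "")
    print(x[[tr]])
  }
  invisible(x)
}

## Average-profile intensities of the four named hazard-ratio shapes.
## Each entry: family and parameters for transitions 1->2, 1->3, 2->3.
hr_shape_table <- function() {
  list(
    constant = list(
      t12 = list("exponential", rate = 0.0050),
      t13 = list("weibull", scale = 0.0039, shape = 1.1881),
      t23 = list("weibull", scale = 0.0039, shape = 1.1881)),
    increasing = list(
      t12 = list("exponential", rate = 0.0075),
      t13 = list("weibull", scale = 0.0022, shape = 1.1881),
      t23 = list("weibull", scale = 0.0028, shape = 1.5439)),
    decreasing = list(
      t12 = list("exponential", rate = 0.0025),
      t13 = list("loglogistic", mu = 5.7146, sigma = 0.2390),
      t23 = list("loglogistic", mu = 5.6778, sigma = 0.2463)),
    increasing_decreasing = list(
      t12 = list("exponential", rate = 0.0020),
      t13 = list("weibull", scale = 0.0018, shape = 1.1881),
      t23 = list("loglogistic", mu = 5.9858, sigma = 0.4971)))
}

spec_from_entry <- function(entry, beta) {
  do.call(transition_spec, c(entry[1], entry[-1], list(beta = beta)))
}

#' Preset hazard-ratio configurations
#'
#' Builds a \code{\link{scenario_config}} from one of the four named
#' average-intensity configurations (constant, increasing, decreasing, or
#' increasing-then-decreasing exposure hazard ratio) together with a
#' covariate-effect scenario.
#'
#' @param shape name of the configuration.
#' @param beta12,beta13,beta23 length-3 covariate log-effects for the
#'   three transitions.
#' @inheritParams scenario_config
#' @return a \code{\link{scenario_config}}.
#' @examples
#' cfg <- hr_configuration("increasing_decreasing",
#'                         beta12 = c(-.2, -.4, -.8),
#'                         beta13 = c(.2, .4, .8),
#'                         beta23 = c(-.2, -.4, -.8))
#' @export
hr_configuration <- function(shape = c("constant", "increasing", "decreasing",
                                       "increasing_decreasing"),
                             beta12 = c(0, 0, 0), beta13 = c(0, 0, 0),
                             beta23 = c(0, 0, 0),
                             censoring = censoring_scheme("none"),
                             n_per_profile = 250L, tmax = 1000) {
  shape <- match.arg(shape)
  tab <- hr_shape_table()[[shape]]
  scenario_config(spec12 = spec_from_entry(tab$t12, beta12),
                  spec13 = spec_from_entry(tab$t13, beta13),
                  spec23 = spec_from_entry(tab$t23, beta23),
                  censoring = censoring, n_per_profile = n_per_profile,
                  tmax = tmax, label = shape)
}

#' The reference simulation scenario
#'
#' The increasing-then-decreasing hazard-ratio configuration with a
#' "healthy exposed subject" covariate pattern:
#' \eqn{\beta_{12} = (-0.2, -0.4, -0.8)} (good-prognosis subjects are
#' exposed more often), \eqn{\beta_{13} = -\beta_{12}} and
#' \eqn{\beta_{23} = -\beta_{13}} (which forces an exposure-by-covariate
#' interaction), without censoring, 250 subjects in each of the 8
#' profiles, and horizon 1000.
#'
#' @param censoring optional \code{\link{censoring_scheme}} overriding the
#'   default of no censoring.
#' @param n_per_profile subjects per profile.
#' @return a \code{\link{scenario_config}}.
#' @export
reference_scenario <- function(censoring = censoring_scheme("none"),
                               n_per_profile = 250L) {
  b12 <- c(-0.2, -0.4, -0.8)
  hr_configuration("increasing_decreasing",
                   beta12 = b12, beta13 = -b12, beta23 = b12,
                   censoring = censoring, n_per_profile = n_per_profile)
}
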