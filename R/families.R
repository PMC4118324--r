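#' Transition intensity specification
#'
#' Describes the intensity of one transition of the illness-death model:
#' a parametric family for the intensity at the average covariate value,
#' plus a vector of log-hazard-ratio effects for the three binary matching
#' covariates.  Covariates act proportionally on the hazard,
#' \eqn{\lambda_z(t) = \bar\lambda(t)\exp\{\beta'(z - \bar z)\}}, so that the
#' declared parametric function is the intensity of a subject with the
#' average profile \eqn{\bar z} (by default \eqn{(0.5, 0.5, 0.5)}, the mean
#' of a balanced allocation over the eight profiles).
#'
#' Parametrizations: the exponential family has constant hazard
#' \code{rate}; the Weibull family has hazard
#' \eqn{h(t) = \lambda_0 \gamma (\lambda_0 t)^{\gamma - 1}} with
#' \code{scale} \eqn{= \lambda_0} and \code{shape} \eqn{= \gamma}
#' (rate parametrization, cumulative hazard \eqn{(\lambda_0 t)^\gamma});
#' the log-logistic family has survival
#' \eqn{S(t) = 1 / (1 + \exp\{(\log t - \mu)/\sigma\})}, whose hazard
#' rises and then falls when \eqn{\sigma < 1}.
#'
#' @param family one of \code{"exponential"}, \code{"weibull"},
#'   \code{"loglogistic"}.
#' @param rate exponential hazard (1/time); exponential family only.
#' @param scale,shape Weibull rate-scale \eqn{\lambda_0} and shape
#'   \eqn{\gamma}; Weibull family only.
#' @param mu,sigma location and scale of \eqn{\log t}; log-logistic family
#'   only.
#' @param beta numeric length-3 vector of per-covariate log hazard ratios.
#' @return an object of class \code{"rsm_transition"}.
#' @examples
#' transition_spec("weibull", scale = 0.0039, shape = 1.1881,
#'                 beta = c(0.2, 0.4, 0.8))
#' @export
transition_spec <- function(family = c("exponential", "weibull", "loglogistic"),
                            rate = NULL, scale = NULL, shape = NULL,
                            mu = NULL, sigma = NULL,
                            beta = c(0, 0, 0)) {
  family <- match.arg(family)
  beta <- as.numeric(beta)
  if (length(beta) != 3L || anyNA(beta))
    stop("'beta' must be a numeric vector of length 3")
  params <- switch(family,
    exponential = {
      if (is.null(rate) || rate <= 0) stop("exponential family needs rate > 0")
      list(rate = rate)
    },
    weibull = {
      if (is.null(scale) || is.null(shape) || scale <= 0 || shape <= 0)
        stop("weibull family needs scale > 0 and shape > 0")
      list(scale = scale, shape = shape)
    },
    loglogistic = {
      if (is.null(mu) || is.null(sigma) || sigma <= 0)
        stop("loglogistic family needs mu and sigma > 0")
      list(mu = mu, sigma = sigma)
    })
  structure(list(family = family, params = params, beta = beta),
            class = "rsm_transition")
}

#' @export
print.rsm_transition <- function(x, ...) {
  cat(sprintf("<transition: %s(%s), beta = (%s)>\n", x$family,
              paste(sprintf("%g", unlist(x$params)), collapse = ", "),
              paste(sprintf("%g", x$beta), collapse = ", ")))
  invisible(x)
}

## hazard / cumulative hazard of the average-profile intensity
base_hazard <- function(spec, t) {
  p <- spec$params
  switch(spec$family,
    exponential = rep_len(p$rate, length(t)),
    weibull = {
      h <- p$scale * p$shape * (p$scale * t)^(p$shape - 1)
      ## shape > 1 makes h(0) = 0; shape < 1 diverges at 0, cap via t = 0+
      h[t == 0 & p$shape > 1] <- 0
      h
    },
    loglogistic = {
      x <- exp((log(pmax(t, .Machine$double.xmin)) - p$mu) / p$sigma)
      h <- x / (p$sigma * t * (1 + x))
      h[t == 0] <- 0
      h
    })
}

base_cumhaz <- function(spec, t) {
  p <- spec$params
  switch(spec$family,
    exponential = p$rate * t,
    weibull = (p$scale * t)^p$shape,
    loglogistic = log1p(exp((log(t) - p$mu) / p$sigma)))
}

## inverse of the average-profile cumulative hazard
base_cumhaz_inv <- function(spec, h) {
  p <- spec$params
  switch(spec$family,
    exponential = h / p$rate,
    weibull = h^(1 / p$shape) / p$scale,
    loglogistic = exp(p$mu) * expm1(h)^p$sigma)
}

## proportional-hazards multiplier of a profile relative to the anchor zbar
relative_risk <- function(spec, profile, zbar = c(0.5, 0.5, 0.5)) {
  profile <- as.numeric(profile)
  exp(sum(spec$beta * (profile - zbar)))
}

#' Transition hazard for a covariate profile
#'
#' Evaluates \eqn{\lambda_z(t) = \bar\lambda(t)\exp\{\beta'(z - \bar z)\}}
#' for one transition specification.
#'
#' @param spec an \code{\link{transition_spec}} object.
#' @param t vector of non-negative times.
#' @param profile binary vector \eqn{(z_1, z_2, z_3)}.
#' @param zbar anchoring profile at which the declared parametric intensity
#'   applies; defaults to the balanced-design average \code{c(.5, .5, .5)}.
#' @return vector of hazard rates (1/time).
#' @export
hazard_value <- function(spec, t, profile = c(0, 0, 0), zbar = c(0.5, 0.5, 0.5)) {
  stopifnot(inherits(spec, "rsm_transition"))
  if (any(t < 0)) stop("'t' must be non-negative")
  base_hazard(spec, t) * relative_risk(spec, profile, zbar)
}

#' Survival and density of one transition for a profile
#'
#' @inheritParams hazard_value
#' @return \code{survival_value} gives \eqn{S_z(t)};
#'   \code{density_value} gives \eqn{f_z(t) = \lambda_z(t) S_z(t)}.
#' @export
survival_value <- function(spec, t, profile = c(0, 0, 0), zbar = c(0.5, 0.5, 0.5)) {
  exp(-base_cumhaz(spec, t) * relative_risk(spec, profile, zbar))
}

#' @rdname survival_value
#' @export
density_value <- function(spec, t, profile = c(0, 0, 0), zbar = c(0.5, 0.5, 0.5)) {
  hazard_value(spec, t, profile, zbar) * survival_value(spec, t, profile, zbar)
}

## inverse-transform sampler; uses the current RNG stream
sample_time <- function(spec, n, profile = c(0, 0, 0), zbar = c(0.5, 0.5, 0.5)) {
  rr <- relative_risk(spec, profile, zbar)
  base_cumhaz_inv(spec, stats::rexp(n) / rr)
}
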