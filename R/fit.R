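## Model fitting.  Both models maximize a Cox partial likelihood on the
## counting-process rows (Breslow ties); fitting is delegated to
## survival::coxph.  The stratified model puts one baseline hazard per
## pair; the marginal models share one baseline and get a cluster-robust
## sandwich variance summing score residuals within pairs.

DIVERGENCE_BOUND <- 10  # |log HR| beyond this flags a monotone likelihood

fit_names <- function(grid, variant) {
  L <- grid$L
  gam <- exposure_colnames(L)
  switch(variant,
    none = ,
    unadjusted = gam,
    adjusted = c(gam, c("z1", "z2", "z3")),
    interaction = c(gam, c("z1", "z2", "z3"),
                    as.vector(t(outer(gam, c("z1", "z2", "z3"),
                                      paste, sep = ":")))))
}

new_fit <- function(cox, model, variant, grid, tab, ties) {
  L <- grid$L
  cf <- stats::coef(cox)
  gam <- cf[exposure_colnames(L)]
  beta <- alpha <- NULL
  if (variant %in% c("adjusted", "interaction"))
    beta <- cf[c("z1", "z2", "z3")]
  if (variant == "interaction") {
    alpha <- matrix(NA_real_, L, 3L,
                    dimnames = list(exposure_colnames(L), c("z1", "z2", "z3")))
    for (l in seq_len(L)) for (k in 1:3) {
      nm <- paste0(exposure_colnames(L)[l], ":z", k)
      if (nm %in% names(cf)) alpha[l, k] <- cf[nm]
    }
  }
  vn <- if (is.null(cox$naive.var)) cox$var else cox$naive.var
  structure(list(model = model, variant = variant,
                 gamma = gam, beta = beta, alpha = alpha,
                 coef = cf,
                 vcov_naive = vn,
                 vcov_robust = if (is.null(cox$naive.var)) NULL else cox$var,
                 n_pairs = length(unique(tab$pair_id)),
                 n_events = sum(tab$event),
                 grid = grid, ties = ties,
                 converged = is.null(cox$fail) &&
                   all(abs(cf) < DIVERGENCE_BOUND | is.na(cf)),
                 iter = cox$iter,
                 fit = cox),
            class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("<%s fit%s: %d pairs, %d events%s>\n",
              toupper(x$model),
              if (is.null(x$variant) || x$variant == "none") ""
              else paste0(" (", x$variant, ")"),
              x$n_pairs, x$n_events,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(rbind(`log HR` = x$gamma,
              `se` = sqrt(diag(as.matrix(x$vcov_naive))[seq_along(x$gamma)])))
  invisible(x)
}

check_events <- function(tab) {
  if (sum(tab$event) == 0L) stop("no events; estimation impossible")
}

ensure_split <- function(tab, grid) {
  if (!all(exposure_colnames(grid$L) %in% names(tab)))
    tab <- split_by_grid(tab, grid)
  tab
}

#' Stratified (Holt-Prentice) Cox fit of a paired dataset
#'
#' Maximizes the Cox partial likelihood stratified on the pair: each pair
#' has its own unspecified baseline hazard and the exposure log hazard
#' ratio \eqn{\gamma_l} is common across pairs within each time interval.
#' Pairs without a discordant event contribute nothing.  Matching
#' covariates are constant within a stratum and therefore inadmissible;
#' the model has no adjustment arguments by design.  A coefficient
#' walking beyond |10| is flagged as a monotone-likelihood divergence.
#'
#' @param tab counting-process table built with \code{model = "hp"}.
#' @param grid \code{\link{interval_grid}} for the step effect.
#' @param ties tie handling passed to \code{survival::coxph}.
#' @return an \code{"rsm_fit"} with elements \code{gamma} (per-interval
#'   log hazard ratios), \code{vcov_naive}, counts and diagnostics.
#' @export
fit_stratified_cox <- function(tab, grid, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  check_events(tab)
  tab <- ensure_split(tab, grid)
  fml <- stats::as.formula(paste(
    "Surv(start, stop, event) ~",
    paste(exposure_colnames(grid$L), collapse = " + "),
    "+ survival::strata(pair_id)"))
  cox <- survival::coxph(fml, data = as.data.frame(tab), ties = ties)
  out <- new_fit(cox, "hp", "none", grid, tab, ties)
  if (!out$converged)
    warning("monotone likelihood suspected: |log HR| > ", DIVERGENCE_BOUND)
  out
}

#' Marginal (Lee-Wei-Amato) Cox fit of a paired dataset
#'
#' Maximizes the ordinary (unstratified) partial likelihood treating all
#' rows as independent, then computes a cluster-robust sandwich
#' covariance \eqn{I^{-1} B I^{-1}} with \eqn{B} the sum over pairs of
#' squared summed score residuals.  The \code{variant} controls the
#' linear predictor: exposure interval effects only
#' (\code{"unadjusted"}), plus matching covariate main effects
#' (\code{"adjusted"}), plus per-interval exposure-by-covariate
#' interactions (\code{"interaction"}); under the latter the
#' profile-specific log hazard ratio in interval \eqn{l} is
#' \eqn{\gamma_l + \alpha_l' z}.
#'
#' @param tab counting-process table built with \code{model = "lwa"}.
#' @param grid \code{\link{interval_grid}}.
#' @param variant \code{"unadjusted"}, \code{"adjusted"} or
#'   \code{"interaction"}.
#' @param ties tie handling.
#' @return an \code{"rsm_fit"}; \code{gamma} holds the per-interval
#'   exposure effects, \code{beta} the covariate effects (if any),
#'   \code{alpha} the L x 3 interaction matrix (if any),
#'   \code{vcov_robust} the pair-clustered sandwich.
#' @export
fit_marginal_cox <- function(tab, grid,
                             variant = c("unadjusted", "adjusted", "interaction"),
                             ties = c("breslow", "efron")) {
  variant <- match.arg(variant)
  ties <- match.arg(ties)
  check_events(tab)
  tab <- ensure_split(tab, grid)
  rhs <- fit_names(grid, variant)
  fml <- stats::as.formula(paste(
    "Surv(start, stop, event) ~",
    paste(rhs, collapse = " + ")))
  cox <- survival::coxph(fml, data = as.data.frame(tab), ties = ties,
                         cluster = pair_id, robust = TRUE)
  if (anyNA(stats::coef(cox)))
    warning("collinear or inestimable terms dropped (NA coefficients)")
  out <- new_fit(cox, "lwa", variant, grid, tab, ties)
  if (!out$converged)
    warning("monotone likelihood suspected: |log HR| > ", DIVERGENCE_BOUND)
  out
}

#' Profile-specific log hazard ratio from a fit
#'
#' For an interaction fit, returns \eqn{\gamma_l + \alpha_l' z} per
#' interval for the requested profile; otherwise the interval effects
#' \eqn{\gamma_l} themselves.
#'
#' @param fit an \code{rsm_fit}.
#' @param profile binary vector \eqn{(z_1, z_2, z_3)}.
#' @return numeric vector of length \code{L}.
#' @export
profile_loghr <- function(fit, profile) {
  g <- unname(fit$gamma)
  if (is.null(fit$alpha)) return(g)
  g + as.vector(fit$alpha %*% as.numeric(profile))
}

#' Proportional-hazards assumption check
#'
#' Harrell's test correlating the scaled Schoenfeld residuals with time,
#' per coefficient, as implemented by \code{survival::cox.zph}.
#'
#' @param fit an \code{rsm_fit}.
#' @param transform time transform passed to \code{cox.zph}.
#' @return data.frame with columns \code{term}, \code{chisq}, \code{df},
#'   \code{p}.
#' @export
ph_assumption_check <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "rsm_fit"))
  if (fit$n_events < 3L)
    stop("fewer than 3 events; the proportional-hazards test is undefined")
  zp <- survival::cox.zph(fit$fit, transform = transform, terms = FALSE)
  tb <- as.data.frame(zp$table)
  data.frame(term = rownames(tb), chisq = tb$chisq, df = tb$df, p = tb$p,
             row.names = NULL)
}

#' Serialize a fit to JSON
#'
#' Estimates, covariance matrices (nested arrays), grid and diagnostics.
#' @param fit an \code{rsm_fit}.
#' @param file path.
#' @export
write_fit_json <- function(fit, file) {
  x <- list(model = fit$model, variant = fit$variant,
            gamma = as.list(fit$gamma),
            beta = if (is.null(fit$beta)) NULL else as.list(fit$beta),
            alpha = if (is.null(fit$alpha)) NULL else unclass(as.data.frame(fit$alpha)),
            vcov_naive = fit$vcov_naive,
            vcov_robust = fit$vcov_robust,
            n_pairs = fit$n_pairs, n_events = fit$n_events,
            grid = list(cuts = fit$grid$cuts, tmax = fit$grid$tmax),
            converged = fit$converged)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
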