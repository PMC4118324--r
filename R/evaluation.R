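## Replication framework: simulate cohorts, match with both methods, fit
## the four models, and measure bias and RMSE of the estimated exposure
## log hazard ratios against the truth engine.

#' Bias, empirical variance and RMSE of one estimate cell
#'
#' For the S replicated estimates of one (interval, profile) cell:
#' bias is the mean estimate minus the true value; the empirical variance
#' uses the S - 1 denominator,
#' \eqn{V = \frac{1}{S-1}\{\sum_s \hat\theta_s^2 - (\sum_s \hat\theta_s)^2 / S\}};
#' and \eqn{RMSE = \sqrt{bias^2 + V}}.
#'
#' @param estimates numeric vector of per-replication estimates
#'   (\code{NA}s from non-converged fits are dropped and counted).
#' @param truth scalar true value.
#' @return list with \code{bias}, \code{variance}, \code{rmse},
#'   \code{n_used}.
#' @export
bias_rmse_cell <- function(estimates, truth) {
  x <- estimates[!is.na(estimates)]
  S <- length(x)
  if (S < 2L) stop("need at least 2 converged replications")
  bias <- mean(x) - truth
  v <- max((sum(x^2) - sum(x)^2 / S) / (S - 1), 0)
  list(bias = bias, variance = v, rmse = sqrt(bias^2 + v),
       n_used = S)
}

#' Aggregate a grid of bias/variance cells
#'
#' From per-interval, per-profile cells \eqn{b_{lZ^{(w)}}} and
#' \eqn{V_{lw}}, computes the printed aggregations: per-profile averages
#' over intervals \eqn{b_{\cdot Z^{(w)}}}, per-interval averages over the
#' 8 profiles \eqn{b_{l\cdot}}, and the overall \eqn{b_{\cdot\cdot}};
#' RMSE aggregates are the corresponding plain means of the per-cell
#' \eqn{\sqrt{b^2 + V}} (means of RMSEs, not roots of mean squares).
#'
#' @param bias L x 8 matrix of per-cell biases.
#' @param variance L x 8 matrix of per-cell empirical variances.
#' @return object of class \code{"rsm_bias_table"} with components
#'   \code{bias}, \code{variance}, \code{rmse} (L x 8), \code{b_dot_z}
#'   (8), \code{b_l_dot} (L), \code{b_overall}, \code{rmse_dot_z},
#'   \code{rmse_l_dot}, \code{rmse_overall}.
#' @export
aggregate_bias <- function(bias, variance) {
  stopifnot(is.matrix(bias), identical(dim(bias), dim(variance)),
            ncol(bias) == 8L)
  rmse <- sqrt(bias^2 + variance)
  structure(list(bias = bias, variance = variance, rmse = rmse,
                 b_dot_z = colMeans(bias),
                 b_l_dot = rowMeans(bias),
                 b_overall = mean(colMeans(bias)),
                 rmse_dot_z = colMeans(rmse),
                 rmse_l_dot = rowMeans(rmse),
                 rmse_overall = mean(colMeans(rmse)),
                 partial = anyNA(bias)),
            class = "rsm_bias_table")
}

#' @export
print.rsm_bias_table <- function(x, ...) {
  cat(sprintf("<bias table: L = %d; overall bias %.3f, overall RMSE %.3f>\n",
              nrow(x$bias), x$b_overall, x$rmse_overall))
  invisible(x)
}

model_codes <- c("hp", "lwa_u", "lwa_a", "lwa_i")

fit_one <- function(model, tab_hp, tab_lwa, grid) {
  f <- switch(model,
    hp = function() fit_stratified_cox(tab_hp, grid),
    lwa_u = function() fit_marginal_cox(tab_lwa, grid, "unadjusted"),
    lwa_a = function() fit_marginal_cox(tab_lwa, grid, "adjusted"),
    lwa_i = function() fit_marginal_cox(tab_lwa, grid, "interaction"))
  tryCatch(suppressWarnings(f()), error = function(e) NULL)
}

#' Run a replication study of the matching-method by model grid
#'
#' For each replication: simulate a cohort, form pairs with the requested
#' matching methods, build the counting-process tables and fit the
#' requested models; then compare the per-interval (and, for the
#' interaction model, per-profile) log hazard ratio estimates with the
#' truth engine and summarize bias and RMSE.  The whole run is
#' deterministic given \code{seed}: per-replication seeds are drawn up
#' front from the root seed, so any execution order gives the same
#' archive.
#'
#' Truth mapping: the stratified and unadjusted marginal fits estimate
#' the population-average \eqn{\log \overline{HR}} per interval, the
#' adjusted marginal fit \eqn{\log \overline{HR}_a}, and the interaction
#' fit the per-profile \eqn{\log HR_i}.  With
#' \code{reference = "empirical"} (the default) the per-interval
#' reference values are the large-sample empirical fits of
#' \code{\link{empirical_hr_curves}}, whose event weighting matches what
#' a partial-likelihood estimator of a piecewise-constant effect
#' converges to; \code{reference = "theoretical"} instead uses the plain
#' time average of the continuous \code{\link{truth_curves}} over each
#' interval (the adjusted average has no closed form and always uses the
#' empirical reference).  The continuous theoretical curves are kept in
#' the result either way.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param reps number of replications.
#' @param seed root integer seed.
#' @param methods subset of \code{c(1, 2)}.
#' @param models subset of \code{c("hp", "lwa_u", "lwa_a", "lwa_i")}.
#' @param grid optional \code{\link{interval_grid}}; by default L
#'   intervals at the event-time quartiles of a dedicated calibration
#'   cohort.
#' @param L intervals for the default grid.
#' @param K truth discretization steps.
#' @param n_large cohort size for the empirical reference fits.
#' @param reference \code{"empirical"} or \code{"theoretical"} (see
#'   Details).
#' @param truth optionally, a precomputed \code{rsm_truth} for this
#'   configuration.
#' @param progress print a dot every 10 replications.
#' @return object of class \code{"rsm_study"}: \code{estimates} (nested
#'   list \code{[[method]][[model]]} of replication x interval x profile
#'   arrays), \code{bias_tables} (same nesting,
#'   \code{\link{aggregate_bias}} outputs), \code{summary} (per-profile
#'   exposure fractions, pair counts, imperfect-pair proportions, RD),
#'   \code{grid}, \code{truth}, \code{failures}.
#' @export
run_study <- function(config, reps, seed, methods = c(1, 2),
                      models = model_codes, grid = NULL, L = 4L,
                      K = 2000L, n_large = 200000L,
                      reference = c("empirical", "theoretical"),
                      truth = NULL, progress = FALSE) {
  stopifnot(all(methods %in% c(1, 2)), all(models %in% model_codes),
            reps >= 2L)
  reference <- match.arg(reference)
  set.seed(as.integer(seed))
  aux_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  if (is.null(grid)) {
    calib <- simulate_cohort(config, aux_seeds[1])
    grid <- default_interval_grid(calib, L = L)
  }
  Lg <- grid$L
  if (is.null(truth)) truth <- truth_curves(config, K = K)
  emp <- NULL
  if (reference == "empirical" || "lwa_a" %in% models)
    emp <- empirical_hr_curves(config, grid, n_large = n_large,
                               seed = aux_seeds[2])
  if (reference == "empirical") {
    truth_bar <- emp$log_hr_bar
    truth_prof <- emp$log_hr_profile                          # 8 x L
  } else {
    truth_bar <- interval_average_loghr(truth, grid, "bar")
    truth_prof <- interval_average_loghr(truth, grid, "profile")
  }
  methods <- sort(unique(as.integer(methods)))
  est <- lapply(methods, function(m)
    lapply(models, function(mod)
      array(NA_real_, c(reps, Lg, 8L))))
  names(est) <- paste0("method", methods)
  for (m in seq_along(est)) names(est[[m]]) <- models
  profs <- covariate_profiles()
  prof_lab <- rownames(profs)
  expo_frac <- matrix(NA_real_, reps, 8L, dimnames = list(NULL, prof_lab))
  npairs <- array(NA_real_, c(reps, length(methods), 8L),
                  dimnames = list(NULL, names(est), prof_lab))
  nimp <- matrix(0, reps, 8L, dimnames = list(NULL, prof_lab))   # method 2
  rd <- rep(NA_real_, reps)
  failures <- 0L
  total_fits <- 0L
  for (s in seq_len(reps)) {
    coh <- simulate_cohort(config, rep_seeds[s])
    expo_frac[s, ] <- tapply(coh$exposed, coh$profile, mean)[prof_lab]
    paired <- list()
    for (m in methods)
      paired[[paste0("method", m)]] <- match_cohort(coh, method = m)
    if (all(c(1, 2) %in% methods))
      rd[s] <- relative_pair_difference(paired$method1, paired$method2)
    for (mi in seq_along(methods)) {
      pm <- paired[[mi]]
      cnt <- table(factor(pm$profile, levels = prof_lab))
      npairs[s, mi, ] <- as.numeric(cnt)
      if (methods[mi] == 2L)
        nimp[s, ] <- as.numeric(tapply(1 - pm$perfect,
                                       factor(pm$profile, levels = prof_lab),
                                       sum, default = 0))
      tab_hp <- if ("hp" %in% models)
        build_counting_process(pm, "hp", grid) else NULL
      tab_lwa <- if (any(models != "hp"))
        build_counting_process(pm, "lwa", grid) else NULL
      for (mod in models) {
        total_fits <- total_fits + 1L
        ft <- fit_one(mod, tab_hp, tab_lwa, grid)
        if (is.null(ft) || !ft$converged) {
          failures <- failures + 1L
          next
        }
        if (mod == "lwa_i") {
          for (w in 1:8)
            est[[mi]][[mod]][s, , w] <- profile_loghr(ft, profs[w, ])
        } else {
          est[[mi]][[mod]][s, , ] <- unname(ft$gamma)
        }
      }
    }
    if (progress && s %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  if (failures > 0.2 * total_fits)
    stop("more than 20% of model fits failed (", failures, "/", total_fits, ")")
  ## bias tables
  bias_tables <- lapply(seq_along(methods), function(mi) {
    out <- lapply(models, function(mod) {
      ref <- switch(mod,
        hp = , lwa_u = matrix(truth_bar, Lg, 8L),
        lwa_a = matrix(emp$log_hr_bar_adjusted, Lg, 8L),
        lwa_i = t(truth_prof))
      b <- v <- matrix(NA_real_, Lg, 8L)
      for (l in seq_len(Lg)) for (w in 1:8) {
        cell <- bias_rmse_cell(est[[mi]][[mod]][, l, w], ref[l, w])
        b[l, w] <- cell$bias
        v[l, w] <- cell$variance
      }
      aggregate_bias(b, v)
    })
    names(out) <- models
    out
  })
  names(bias_tables) <- names(est)
  summary <- list(
    exposure_fraction = colMeans(expo_frac),
    mean_pairs = apply(npairs, c(2, 3), mean),
    imperfect_prop = if (2 %in% methods)
      colSums(nimp) / colSums(npairs[, "method2", ]) else NULL,
    rd = rd)
  structure(list(estimates = est, bias_tables = bias_tables,
                 summary = summary, grid = grid, truth = truth,
                 empirical_reference = emp, reference = reference,
                 config = config, reps = reps, seed = seed,
                 rep_seeds = rep_seeds, failures = failures,
                 total_fits = total_fits),
            class = "rsm_study")
}

#' @export
print.rsm_study <- function(x, ...) {
  cat(sprintf("<study: %d replications, %d failures/%d fits, L = %d>\n",
              x$reps, x$failures, x$total_fits, x$grid$L))
  for (m in names(x$bias_tables)) {
    cat(m, "\n")
    for (mod in names(x$bias_tables[[m]])) {
      bt <- x$bias_tables[[m]][[mod]]
      cat(sprintf("  %-6s b.. = %+.3f  RMSE.. = %.3f\n",
                  mod, bt$b_overall, bt$rmse_overall))
    }
  }
  invisible(x)
}
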