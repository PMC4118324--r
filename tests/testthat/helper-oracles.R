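## Hand-coded oracles, independent of survival::coxph and of the package
## internals they check.

## Breslow log partial likelihood on counting-process rows.
## X: matrix of covariates (one column per parameter); stratum: vector
## (constant for an unstratified fit).  Events at 'stop', risk set
## {j : start_j < t <= stop_j} within the stratum.
oracle_coxpl <- function(b, X, start, stop, event, stratum = rep(1, nrow(X))) {
  lp <- as.vector(X %*% b)
  ll <- 0
  for (s in unique(stratum)) {
    rows <- which(stratum == s)
    etimes <- sort(unique(stop[rows][event[rows] == 1]))
    for (t in etimes) {
      atrisk <- rows[start[rows] < t & stop[rows] >= t]
      dead <- rows[stop[rows] == t & event[rows] == 1]
      ll <- ll + sum(lp[dead]) - length(dead) * log(sum(exp(lp[atrisk])))
    }
  }
  ll
}

## maximize the oracle likelihood
oracle_coxmle <- function(X, start, stop, event, stratum = rep(1, nrow(X)),
                          init = rep(0, ncol(X))) {
  fn <- function(b) -oracle_coxpl(b, X, start, stop, event, stratum)
  opt <- stats::optim(init, fn, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  opt$par
}

## cluster sandwich at parameter b: I^-1 B I^-1 with B the sum over
## clusters of squared summed score residuals and I the observed
## information (numerical Hessian of the oracle likelihood)
oracle_sandwich <- function(b, X, start, stop, event, cluster) {
  n <- nrow(X)
  p <- ncol(X)
  lp <- as.vector(X %*% b)
  U <- matrix(0, n, p)
  etimes <- sort(unique(stop[event == 1]))
  for (t in etimes) {
    atrisk <- which(start < t & stop >= t)
    dead <- which(stop == t & event == 1)
    s0 <- sum(exp(lp[atrisk]))
    s1 <- colSums(X[atrisk, , drop = FALSE] * exp(lp[atrisk]))
    xbar <- s1 / s0
    dlam <- length(dead) / s0
    for (i in atrisk) {
      dn <- as.numeric(i %in% dead)
      U[i, ] <- U[i, ] + (X[i, ] - xbar) * (dn - exp(lp[i]) * dlam)
    }
  }
  cl <- split(seq_len(n), cluster)
  B <- matrix(0, p, p)
  for (rows in cl) {
    s <- colSums(U[rows, , drop = FALSE])
    B <- B + outer(s, s)
  }
  H <- stats::optimHess(b, function(bb)
    -oracle_coxpl(bb, X, start, stop, event))
  Iinv <- solve(H)
  Iinv %*% B %*% Iinv
}

## naive two-pass bias/variance/rmse, independent re-implementation
oracle_bias_rmse <- function(x, truth) {
  m <- mean(x)
  v <- sum((x - m)^2) / (length(x) - 1)
  b <- m - truth
  c(bias = b, variance = v, rmse = sqrt(b^2 + v))
}

## small deterministic toy cohort for matching tests
toy_cohort <- function(df) {
  df$profile <- paste0(df$z1, df$z2, df$z3)
  structure(df, class = c("rsm_cohort", "data.frame"))
}

## binned occurrence/exposure hazard estimate from a simulated cohort:
## events and person-time of the 2->3 (post-exposure) and 1->3
## (pre-exposure) transitions per time bin, on the time-since-origin scale
mc_binned_hazards <- function(cohort, breaks) {
  nb <- length(breaks) - 1L
  res <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                    ev13 = 0, pt13 = 0, ev23 = 0, pt23 = 0)
  ## pre-exposure interval (0, min(tE, tfinal)]; post (tE, tfinal]
  end_pre <- pmin(cohort$t_exposure, cohort$t_final)
  ev_pre <- cohort$event == 1 & cohort$exposed == 0
  st_post <- ifelse(cohort$exposed == 1, cohort$t_exposure, NA)
  end_post <- ifelse(cohort$exposed == 1, cohort$t_final, NA)
  ev_post <- cohort$event == 1 & cohort$exposed == 1
  for (b in seq_len(nb)) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    res$pt13[b] <- sum(pmax(0, pmin(end_pre, hi) - lo))
    res$ev13[b] <- sum(ev_pre & end_pre > lo & end_pre <= hi)
    res$pt23[b] <- sum(pmax(0, pmin(end_post, hi) - pmax(st_post, lo)),
                       na.rm = TRUE)
    res$ev23[b] <- sum(ev_post & end_post > lo & end_post <= hi, na.rm = TRUE)
  }
  res$h13 <- res$ev13 / res$pt13
  res$h23 <- res$ev23 / res$pt23
  res$hr <- res$h23 / res$h13
  res
}

## small paired datasets with known structure for the likelihood oracles
oracle_toy_pairs <- function(n_pairs = 4, seed = 99) {
  set.seed(seed)
  form <- sort(runif(n_pairs, 0, 3))
  coh <- toy_cohort(data.frame(
    id = seq_len(2 * n_pairs),
    z1 = rep(rbinom(n_pairs, 1, 0.5), each = 2),
    z2 = rep(rbinom(n_pairs, 1, 0.5), each = 2),
    z3 = 0,
    t_exposure = as.vector(rbind(form, Inf)),
    t_final = as.vector(rbind(form + rexp(n_pairs, 0.2),
                              form + rexp(n_pairs, 0.25))),
    exposed = rep(c(1L, 0L), n_pairs),
    event = rbinom(2 * n_pairs, 1, 0.85)))
  coh$profile <- paste0(coh$z1, coh$z2, coh$z3)
  structure(data.frame(pair_id = seq_len(n_pairs),
                       exposed_id = seq(1, 2 * n_pairs, 2),
                       control_id = seq(2, 2 * n_pairs, 2),
                       t_formation = form, perfect = 1L,
                       profile = coh$profile[seq(1, 2 * n_pairs, 2)],
                       z1 = coh$z1[seq(1, 2 * n_pairs, 2)],
                       z2 = coh$z2[seq(1, 2 * n_pairs, 2)],
                       z3 = 0),
            cohort = coh, method = 1, class = c("rsm_pairs", "data.frame"))
}

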