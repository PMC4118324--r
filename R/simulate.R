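#' Draw the four latent times of the illness-death model
#'
#' For one covariate profile, draws \code{n} independent quadruplets
#' (t12, t13, t23, C): the latent times to exposure and to the final
#' event from the initial state, the latent duration from exposure to the
#' final event, and the censoring time (\code{Inf} when the scheme has no
#' censoring).  Uses the current RNG stream; seed it with
#' \code{set.seed()} before calling for reproducible draws.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param profile binary vector \eqn{(z_1, z_2, z_3)}.
#' @param n number of draws.
#' @return data.frame with columns \code{t12}, \code{t13}, \code{t23},
#'   \code{C}.
#' @export
sample_transition_times <- function(config, profile, n = 1L) {
  stopifnot(inherits(config, "rsm_scenario"))
  t12 <- sample_time(config$spec12, n, profile, config$zbar)
  t13 <- sample_time(config$spec13, n, profile, config$zbar)
  t23 <- sample_time(config$spec23, n, profile, config$zbar)
  C <- if (config$censoring$kind == "none") rep_len(Inf, n)
       else stats::runif(n, 0, config$censoring$cmax)
  data.frame(t12 = t12, t13 = t13, t23 = t23, C = C)
}

#' Derive the observed outcome from the latent times
#'
#' Applies the four mutually exclusive outcome rules of the illness-death
#' design.  With \eqn{E} the exposure indicator and \eqn{\Delta} the final
#' event indicator, the observed quadruplet \eqn{(t_E, t_i, E, \Delta)} is
#' \itemize{
#'   \item \eqn{(\infty, C, 0, 0)} if \eqn{C < \min(t_{12}, t_{13})}
#'     (censored before anything happens);
#'   \item \eqn{(\infty, t_{13}, 0, 1)} if \eqn{t_{13} \le \min(t_{12}, C)}
#'     (final event without exposure; events win exact ties);
#'   \item \eqn{(t_{12}, C, 1, 0)} if \eqn{t_{12} < \min(t_{13}, C)} and
#'     \eqn{t_{12} + t_{23} > C} (exposed, then censored);
#'   \item \eqn{(t_{12}, t_{12} + t_{23}, 1, 1)} if
#'     \eqn{t_{12} < \min(t_{13}, C)} and \eqn{t_{12} + t_{23} \le C}
#'     (exposed, then final event).
#' }
#' Follow-up is then administratively truncated at \code{tmax}: a subject
#' whose recorded time exceeds \code{tmax} is censored there, and an
#' exposure after \code{tmax} is never observed.  Unexposed subjects carry
#' \code{t_exposure = Inf} as a sentinel.
#'
#' @param t12,t13,t23,C numeric vectors of latent times (\code{C} may be
#'   \code{Inf}).
#' @param tmax administrative horizon.
#' @return data.frame with columns \code{t_exposure}, \code{t_final},
#'   \code{exposed}, \code{event}.
#' @export
derive_outcome <- function(t12, t13, t23, C, tmax = Inf) {
  n <- length(t12)
  stopifnot(length(t13) == n, length(t23) == n, length(C) == n)
  if (any(c(t12, t13, t23) <= 0, na.rm = TRUE))
    stop("latent times must be > 0")
  ## exact ties are measure-zero under continuous intensities; precedence
  ## is event over exposure over censoring
  if (any(t12 == t13 | t12 == C | t13 == C, na.rm = TRUE))
    warning("exact ties among latent times; resolved as event < exposure < censoring")
  exposed <- t12 < t13 & t12 <= C
  t_exposure <- ifelse(exposed, t12, Inf)
  event <- ifelse(exposed, t12 + t23 <= C, t13 <= C)
  t_final <- ifelse(exposed,
                    pmin(t12 + t23, C),
                    pmin(t13, C))
  ## administrative horizon
  late_exposure <- exposed & t_exposure > tmax
  exposed[late_exposure] <- FALSE
  t_exposure[late_exposure] <- Inf
  over <- t_final > tmax
  event[over] <- FALSE
  t_final[over] <- tmax
  data.frame(t_exposure = t_exposure, t_final = t_final,
             exposed = as.integer(exposed), event = as.integer(event))
}

#' Simulate a cohort from the illness-death model
#'
#' Allocates \code{n_per_profile} subjects to each of the 8 covariate
#' profiles, draws their latent transition times from the profile-specific
#' intensities and derives the observed exposure and outcome of every
#' subject.  Fully deterministic given \code{seed}.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param seed integer seed; stored in the result.
#' @return a data.frame of class \code{"rsm_cohort"} with one row per
#'   subject and columns \code{id}, \code{z1}, \code{z2}, \code{z3},
#'   \code{profile}, \code{t_exposure}, \code{t_final}, \code{exposed},
#'   \code{event}.  The scenario and seed are kept as attributes.
#' @examples
#' coh <- simulate_cohort(reference_scenario(n_per_profile = 50), seed = 1)
#' table(coh$profile, coh$exposed)
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "rsm_scenario"))
  set.seed(as.integer(seed))
  profs <- covariate_profiles()
  npp <- config$n_per_profile
  parts <- vector("list", nrow(profs))
  for (w in seq_len(nrow(profs))) {
    z <- profs[w, ]
    lat <- sample_transition_times(config, z, npp)
    out <- derive_outcome(lat$t12, lat$t13, lat$t23, lat$C, config$tmax)
    parts[[w]] <- data.frame(z1 = z[[1]], z2 = z[[2]], z3 = z[[3]],
                             profile = rownames(profs)[w], out)
  }
  coh <- do.call(rbind, parts)
  coh <- cbind(id = seq_len(nrow(coh)), coh)
  rownames(coh) <- NULL
  structure(coh, scenario = config, seed = as.integer(seed),
            class = c("rsm_cohort", "data.frame"))
}

#' Write / read a cohort as delimited text
#'
#' Plain CSV with \code{#}-prefixed metadata lines (scenario label, seed)
#' before the header.  \code{t_exposure} is empty for never-exposed
#' subjects and restored as \code{Inf} on reading.
#'
#' @param cohort an \code{rsm_cohort} (or compatible data.frame).
#' @param file path.
#' @export
write_cohort <- function(cohort, file) {
  con <- file(file, "w")
  on.exit(close(con))
  lab <- attr(cohort, "scenario")$label
  writeLines(c(sprintf("# scenario: %s", if (is.null(lab)) "" else lab),
               sprintf("# seed: %s", as.character(attr(cohort, "seed")))), con)
  out <- as.data.frame(cohort)
  out$t_exposure[!is.finite(out$t_exposure)] <- NA
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  coh <- utils::read.csv(file, comment.char = "#")
  need <- c("id", "z1", "z2", "z3", "t_exposure", "t_final", "exposed", "event")
  if (!all(need %in% names(coh)))
    stop("cohort file lacks columns: ",
         paste(setdiff(need, names(coh)), collapse = ", "))
  coh$t_exposure[is.na(coh$t_exposure)] <- Inf
  ## rebuild the profile label: type conversion strips leading zeros
  coh$profile <- paste0(coh$z1, coh$z2, coh$z3)
  if (anyDuplicated(coh$id)) stop("duplicate subject ids")
  bad <- coh$exposed == 1 & coh$t_exposure > coh$t_final
  if (any(bad)) stop("exposed subjects must have t_exposure <= t_final")
  structure(coh, class = c("rsm_cohort", "data.frame"))
}
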