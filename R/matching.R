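## Matching of exposed subjects to unexposed controls, exact on the
## covariate profile.  Two eligibility rules:
##   Method 1 (a posteriori): controls are subjects never exposed during
##     the whole study, still under follow-up at the exposure time.
##   Method 2 (real time): controls are subjects not yet exposed at the
##     exposure time (strictly later or never), still under follow-up.

match_method_label <- function(method) paste0("method", method)

eligible_core <- function(cohort, j, method) {
  jr <- match(j, cohort$id)
  if (is.na(jr)) stop("unknown subject id")
  if (cohort$exposed[jr] != 1L) stop("subject is not exposed")
  tE <- cohort$t_exposure[jr]
  same <- cohort$profile == cohort$profile[jr] & seq_len(nrow(cohort)) != jr
  atrisk <- cohort$t_final >= tE
  ok <- if (method == 1L) cohort$t_exposure == Inf
        else cohort$t_exposure > tE
  which(same & atrisk & ok)
}

#' Eligible control sets for one exposed subject
#'
#' \code{eligible_set_method1} returns the subjects with the same
#' covariate profile as \code{j}, still under follow-up at the exposure
#' time of \code{j}, and never exposed over the whole study.
#' \code{eligible_set_method2} returns those not yet exposed at that time
#' (strictly later, or never), minus controls already consumed by pairs
#' formed earlier.  The Method-2 set is always a superset of the Method-1
#' set before control consumption.
#'
#' @param cohort an \code{rsm_cohort} (or compatible data.frame).
#' @param j id of an exposed subject.
#' @param already_used ids of controls consumed by earlier pairs.
#' @return integer vector of eligible subject ids.
#' @export
eligible_set_method1 <- function(cohort, j, already_used = integer()) {
  setdiff(cohort$id[eligible_core(cohort, j, 1L)], already_used)
}

#' @rdname eligible_set_method1
#' @export
eligible_set_method2 <- function(cohort, j, already_used = integer()) {
  setdiff(cohort$id[eligible_core(cohort, j, 2L)], already_used)
}

#' Create a matched-pair dataset from a cohort
#'
#' Processes the exposed subjects in ascending order of exposure time
#' (ties broken by id).  For each, a control with the same covariate
#' profile is drawn uniformly at random from the eligible set of the
#' chosen method; by default a subject serves as control in at most one
#' pair.  A pair is \emph{perfect} when its control is never exposed
#' during follow-up, \emph{imperfect} (Method 2 only) when the control is
#' exposed later; an imperfect control may afterwards head her own pair as
#' the exposed member.  Exposed subjects with an empty eligible set are
#' excluded and reported.
#'
#' @param cohort an \code{rsm_cohort}.
#' @param method 1 (a posteriori) or 2 (real time).
#' @param seed optional integer; when given, seeds the RNG so the pairing
#'   is replayable.
#' @param replace_controls allow a control to serve in several pairs
#'   (off by default).
#' @return a data.frame of class \code{"rsm_pairs"} with columns
#'   \code{pair_id}, \code{exposed_id}, \code{control_id},
#'   \code{t_formation}, \code{perfect}, \code{profile}, \code{z1},
#'   \code{z2}, \code{z3}; the method, unmatched exposed ids, seed and
#'   source cohort are attributes.
#' @examples
#' coh <- simulate_cohort(reference_scenario(n_per_profile = 50), seed = 1)
#' p2 <- match_cohort(coh, method = 2, seed = 2)
#' table(p2$profile, p2$perfect)
#' @export
match_cohort <- function(cohort, method = c(1, 2), seed = NULL,
                         replace_controls = FALSE) {
  method <- as.integer(method)[1]
  if (!method %in% c(1L, 2L)) stop("'method' must be 1 or 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ord <- order(cohort$t_exposure, cohort$id)
  ord <- ord[cohort$exposed[ord] == 1L]
  used <- logical(nrow(cohort))          # consumed as control
  exp_row <- ctl_row <- integer(length(ord))
  unmatched <- integer()
  k <- 0L
  texp <- cohort$t_exposure
  tfin <- cohort$t_final
  prof <- cohort$profile
  ## pre-split candidate rows by profile to keep the scan local
  by_prof <- split(seq_len(nrow(cohort)), prof)
  for (j in ord) {
    tE <- texp[j]
    cand <- by_prof[[prof[j]]]
    elig <- cand[tfin[cand] >= tE &
                   (if (method == 1L) texp[cand] == Inf else texp[cand] > tE) &
                   cand != j]
    if (!replace_controls) elig <- elig[!used[elig]]
    if (length(elig) == 0L) {
      unmatched <- c(unmatched, cohort$id[j])
      next
    }
    ctrl <- elig[sample.int(length(elig), 1L)]
    used[ctrl] <- TRUE
    k <- k + 1L
    exp_row[k] <- j
    ctl_row[k] <- ctrl
  }
  exp_row <- exp_row[seq_len(k)]
  ctl_row <- ctl_row[seq_len(k)]
  pairs <- data.frame(pair_id = seq_len(k),
                      exposed_id = cohort$id[exp_row],
                      control_id = cohort$id[ctl_row],
                      t_formation = texp[exp_row],
                      perfect = as.integer(texp[ctl_row] == Inf),
                      profile = prof[exp_row],
                      z1 = cohort$z1[exp_row], z2 = cohort$z2[exp_row],
                      z3 = cohort$z3[exp_row],
                      stringsAsFactors = FALSE)
  structure(pairs, method = method, unmatched = unmatched,
            seed = seed, cohort = cohort,
            class = c("rsm_pairs", "data.frame"))
}

#' Relative difference in pair numbers between the two methods
#'
#' \eqn{RD = (n_{pairs}^{(2)} - n_{pairs}^{(1)}) / n_{pairs}^{(1)}},
#' comparing the real-time and a posteriori matchings of the same cohort.
#'
#' @param paired1,paired2 \code{rsm_pairs} from Method 1 and Method 2 on
#'   the same cohort.
#' @return a proportion (0.55 means 55\% more pairs with Method 2).
#' @export
relative_pair_difference <- function(paired1, paired2) {
  n1 <- nrow(paired1); n2 <- nrow(paired2)
  if (n1 == 0L) stop("Method-1 pair count is zero; RD undefined")
  (n2 - n1) / n1
}

#' Write / read a pairs table as delimited text
#'
#' CSV with \code{#}-prefixed metadata lines (method, seed).
#' @param pairs an \code{rsm_pairs}.
#' @param file path.
#' @export
write_pairs <- function(pairs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# method: %s", as.character(attr(pairs, "method"))),
               sprintf("# seed: %s", as.character(attr(pairs, "seed"))),
               sprintf("# unmatched: %s",
                       paste(attr(pairs, "unmatched"), collapse = " "))), con)
  utils::write.csv(as.data.frame(pairs), con, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(file, cohort = NULL) {
  p <- utils::read.csv(file, comment.char = "#",
                       colClasses = c(profile = "character"))
  structure(p, cohort = cohort, class = c("rsm_pairs", "data.frame"))
}
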