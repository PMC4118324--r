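#' Time-interval grid for piecewise-constant exposure effects
#'
#' The exposure log hazard ratio \eqn{\gamma(t)} is modelled as a step
#' function on intervals \eqn{I_l = [a_{l-1}, a_l)} with
#' \eqn{a_0 = 0 < a_1 < \dots < a_L = t_{max}}.
#'
#' @param boundaries strictly increasing interior cut points
#'   \eqn{a_1 < \dots < a_{L-1}} (may be empty for a single interval).
#' @param tmax right end of the last interval.
#' @return object of class \code{"rsm_grid"} with elements \code{cuts}
#'   (interior boundaries), \code{tmax} and \code{L}.
#' @export
interval_grid <- function(boundaries = numeric(), tmax = 1000) {
  boundaries <- as.numeric(boundaries)
  if (any(diff(c(0, boundaries, tmax)) <= 0))
    stop("interval boundaries must satisfy 0 < a_1 < ... < tmax")
  structure(list(cuts = boundaries, tmax = tmax,
                 L = length(boundaries) + 1L),
            class = "rsm_grid")
}

#' @export
print.rsm_grid <- function(x, ...) {
  cat(sprintf("<interval grid: L = %d, boundaries = [%s]>\n", x$L,
              paste(sprintf("%g", c(0, x$cuts, x$tmax)), collapse = ", ")))
  invisible(x)
}

#' Default interval grid from pooled event times
#'
#' Places the interior boundaries at the empirical quartiles of the
#' final-event times of a cohort, giving \code{L} intervals holding
#' roughly equal numbers of events.  For a constant exposure effect use
#' \code{L = 1}.
#'
#' @param cohort an \code{rsm_cohort} (or any data.frame with
#'   \code{t_final} and \code{event}).
#' @param L number of intervals.
#' @param tmax administrative horizon; defaults to the cohort scenario's.
#' @return an \code{\link{interval_grid}}.
#' @export
default_interval_grid <- function(cohort, L = 4L, tmax = NULL) {
  if (is.null(tmax)) {
    sc <- attr(cohort, "scenario")
    tmax <- if (!is.null(sc)) sc$tmax else max(cohort$t_final)
  }
  if (L == 1L) return(interval_grid(numeric(), tmax))
  ev <- cohort$t_final[cohort$event == 1L & cohort$t_final < tmax]
  if (length(ev) < 4L * L) stop("too few events to place ", L, " intervals")
  q <- unname(stats::quantile(ev, probs = seq_len(L - 1L) / L, type = 7))
  interval_grid(q, tmax)
}

interval_of <- function(t, grid) findInterval(t, c(grid$cuts, Inf)) + 1L

exposure_colnames <- function(L) paste0("e", seq_len(L))

#' Build the counting-process table of a paired dataset
#'
#' Turns matched pairs into start-stop rows for Cox model fitting.  Both
#' members of a pair enter the risk set at the pair formation time
#' (delayed entry); person-time outside any pair contributes no rows.
#' The exposed member carries exposure 1 from entry, the control 0.  An
#' imperfect control is censored within her pair at her own exposure time
#' (she may re-enter later as the exposed member of her own pair).  Under
#' the stratified (\code{"hp"}) construction, the pair is additionally
#' censored as a whole when either member exits, so both rows stop at the
#' earlier of the two exits; the marginal (\code{"lwa"}) construction
#' follows each member to her own exit.  Rows are half-open intervals
#' (start, stop] with events placed at stop; when an interval grid is
#' supplied, rows are split at the boundaries and the exposure column is
#' expanded into per-interval indicators \code{e1..eL}.
#'
#' @param paired an \code{rsm_pairs} with its source cohort attached (as
#'   produced by \code{\link{match_cohort}}).
#' @param model \code{"hp"} (pair-level censoring, for the stratified fit)
#'   or \code{"lwa"}.
#' @param grid optional \code{\link{interval_grid}}.
#' @param exposure_coding \code{"tdc"} (default) enters both members at
#'   the formation time with the exposed member's indicator switched on
#'   from entry; \code{"fixed"} treats the pair as known at \eqn{t = 0}
#'   (entry at 0, exposure constant over the row), the coding used when
#'   the a posteriori pairs are analysed as if formed at baseline.  For
#'   the stratified model on a posteriori pairs the two codings give
#'   identical estimates, because neither member can have an event before
#'   the formation time.
#' @return data.frame of class \code{"rsm_cptable"} with columns
#'   \code{subject_id}, \code{pair_id}, \code{start}, \code{stop},
#'   \code{event}, \code{exposure}, \code{z1}, \code{z2}, \code{z3} and,
#'   when split, \code{interval} and \code{e1..eL}.
#' @export
build_counting_process <- function(paired, model = c("lwa", "hp"),
                                   grid = NULL,
                                   exposure_coding = c("tdc", "fixed")) {
  model <- match.arg(model)
  exposure_coding <- match.arg(exposure_coding)
  cohort <- attr(paired, "cohort")
  if (is.null(cohort)) stop("paired dataset lacks its source cohort")
  if (nrow(paired) == 0L)
    stop("no pairs to analyse")
  er <- match(paired$exposed_id, cohort$id)
  cr <- match(paired$control_id, cohort$id)
  t0 <- paired$t_formation
  ## exposed member: at risk from formation (= her exposure time)
  stop_e <- cohort$t_final[er]
  ev_e <- cohort$event[er]
  ## control: censored at her own exposure if it comes first
  own_exp <- cohort$t_exposure[cr]
  stop_c <- pmin(cohort$t_final[cr], own_exp)
  ev_c <- ifelse(own_exp <= cohort$t_final[cr], 0L, cohort$event[cr])
  if (model == "hp") {
    pair_stop <- pmin(stop_e, stop_c)
    ev_e <- ifelse(stop_e <= pair_stop, ev_e, 0L)
    ev_c <- ifelse(stop_c <= pair_stop, ev_c, 0L)
    stop_e <- pair_stop
    stop_c <- pair_stop
  }
  entry <- if (exposure_coding == "fixed") rep_len(0, length(t0)) else t0
  tab <- data.frame(
    subject_id = c(paired$exposed_id, paired$control_id),
    pair_id = rep(paired$pair_id, 2L),
    start = rep(entry, 2L),
    stop = c(stop_e, stop_c),
    event = c(ev_e, ev_c),
    exposure = rep(c(1L, 0L), each = nrow(paired)),
    z1 = rep(paired$z1, 2L), z2 = rep(paired$z2, 2L),
    z3 = rep(paired$z3, 2L))
  zero <- tab$stop <= tab$start
  if (any(zero)) {
    warning(sum(zero), " pair member(s) with zero follow-up after formation dropped")
    tab <- tab[!zero, , drop = FALSE]
  }
  tab <- tab[order(tab$pair_id, -tab$exposure), ]
  rownames(tab) <- NULL
  if (!is.null(grid)) tab <- split_by_grid(tab, grid)
  structure(tab, model = model, grid = grid,
            class = c("rsm_cptable", "data.frame"))
}

#' Split a counting-process table at interval boundaries
#'
#' @param tab a counting-process table with \code{start}, \code{stop},
#'   \code{event}, \code{exposure} columns.
#' @param grid an \code{\link{interval_grid}}.
#' @return the split table with an \code{interval} column and exposure
#'   indicators \code{e1..eL} (\code{el = exposure} inside interval l,
#'   0 elsewhere).
#' @export
split_by_grid <- function(tab, grid) {
  stopifnot(inherits(grid, "rsm_grid"))
  if (max(tab$stop) > grid$tmax)
    stop("grid does not cover the data range")
  if (length(grid$cuts)) {
    tab <- survival::survSplit(Surv(start, stop, event) ~ .,
                               data = as.data.frame(tab), cut = grid$cuts,
                               episode = "interval")
  } else {
    tab$interval <- 1L
  }
  for (l in seq_len(grid$L))
    tab[[paste0("e", l)]] <- tab$exposure * as.integer(tab$interval == l)
  tab
}

#' Build the counting-process table of a whole cohort
#'
#' One or two start-stop rows per subject of the cohort itself (no
#' matching): (0, t_E] unexposed then (t_E, t_i] exposed for exposed
#' subjects, (0, t_i] for the others.  Used for the large-sample
#' empirical reference fits.
#'
#' @param cohort an \code{rsm_cohort}.
#' @param grid optional \code{\link{interval_grid}}.
#' @return data.frame with the same layout as
#'   \code{\link{build_counting_process}} (with \code{pair_id = 0}).
#' @export
cohort_counting_process <- function(cohort, grid = NULL) {
  expd <- cohort$exposed == 1L
  pre <- data.frame(subject_id = cohort$id, pair_id = 0L,
                    start = 0, stop = ifelse(expd, cohort$t_exposure,
                                             cohort$t_final),
                    event = ifelse(expd, 0L, cohort$event),
                    exposure = 0L,
                    z1 = cohort$z1, z2 = cohort$z2, z3 = cohort$z3)
  post <- data.frame(subject_id = cohort$id[expd], pair_id = 0L,
                     start = cohort$t_exposure[expd],
                     stop = cohort$t_final[expd],
                     event = cohort$event[expd], exposure = 1L,
                     z1 = cohort$z1[expd], z2 = cohort$z2[expd],
                     z3 = cohort$z3[expd])
  tab <- rbind(pre, post)
  tab <- tab[tab$stop > tab$start, , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(grid)) tab <- split_by_grid(tab, grid)
  structure(tab, model = "cohort", grid = grid,
            class = c("rsm_cptable", "data.frame"))
}

#' Write / read a counting-process table
#'
#' Plain CSV round-trip preserving all columns bit-exactly (times are
#' written with full precision).
#' @param tab an \code{rsm_cptable}.
#' @param file path.
#' @export
write_cptable <- function(tab, file) {
  df <- as.data.frame(tab)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_cptable
#' @export
read_cptable <- function(file) {
  tab <- utils::read.csv(file)
  structure(tab, class = c("rsm_cptable", "data.frame"))
}
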