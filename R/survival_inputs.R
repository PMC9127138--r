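# Conversion of published survival summaries into monthly transition
# probabilities: the closed-form median conversion, rate<->probability
# conversions, exponential fits to Kaplan-Meier points, and a consistency
# validator for a printed transition matrix against the closed form.

#' Survival summary for one arm
#'
#' @param median_pfs Median progression-free survival, months (> 0).
#' @param median_os Median overall survival, months (>= `median_pfs`).
#' @param arm Arm label.
#' @param population Population label, `"overall"` or `"pMMR"`.
#' @return An object of class `survival_summary`.
#' @export
survival_summary <- function(median_pfs, median_os, arm = "arm",
                             population = c("overall", "pMMR")) {
  population <- match.arg(population)
  if (median_pfs <= 0 || median_os <= 0) {
    stop("survival medians must be > 0", call. = FALSE)
  }
  if (median_os < median_pfs) {
    stop("median OS (", median_os, ") cannot be below median PFS (",
         median_pfs, ")", call. = FALSE)
  }
  structure(list(median_pfs = median_pfs, median_os = median_os,
                 arm = arm, population = population),
            class = "survival_summary")
}

#' Monthly event probability from a median time-to-event
#'
#' Assuming exponentially distributed event times, a median time to event of
#' `m` months implies a per-cycle event probability of
#' `1 - 0.5^(cycle / m)`.
#'
#' @param median Median time to event, months (> 0).
#' @param cycle Cycle length, months (default 1).
#' @return Event probability per cycle, in (0, 1).
#' @export
#' @examples
#' median_to_monthly_prob(7.2)   # 0.0917816
median_to_monthly_prob <- function(median, cycle = 1) {
  if (!is.numeric(median) || any(median <= 0)) {
    stop("median time to event must be > 0", call. = FALSE)
  }
  if (!is.numeric(cycle) || any(cycle <= 0)) {
    stop("cycle length must be > 0", call. = FALSE)
  }
  1 - 0.5^(cycle / median)
}

#' Convert a monthly event rate to a per-cycle probability
#'
#' `P = 1 - exp(-R * cycle)` for a constant hazard `R`.
#'
#' @param rate Events per month (>= 0).
#' @param cycle Cycle length in months.
#' @return Probability in \[0, 1).
#' @export
rate_to_prob <- function(rate, cycle = 1) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  1 - exp(-rate * cycle)
}

#' Convert a per-cycle probability to a monthly event rate
#'
#' `R = -log(1 - P) / cycle`; the inverse of [rate_to_prob()].
#'
#' @param prob Probability in \[0, 1).
#' @param cycle Cycle length in months.
#' @return Events per month.
#' @export
prob_to_rate <- function(prob, cycle = 1) {
  if (any(prob < 0) || any(prob > 1)) {
    stop("probability must be in [0, 1)", call. = FALSE)
  }
  if (any(prob == 1)) {
    stop("probability 1 implies an infinite event rate", call. = FALSE)
  }
  -log(1 - prob) / cycle
}

#' Fit an exponential survival model to Kaplan-Meier points
#'
#' Least-squares fit of the constant hazard through the origin on the
#' log-survival scale: the slope of `-log S(t)` against `t`. With a single
#' point `(t, 0.5)` this returns `log(2) / t` exactly. Points with survival 0
#' carry no information about the rate on this scale and are dropped.
#'
#' @param points Data frame with columns `time_months` (or `time`) and
#'   `survival`, e.g. from [km_from_ipd()] or [read_km_points()].
#' @return Fitted event rate, per month.
#' @export
fit_exponential <- function(points) {
  tm <- points[["time_months"]]
  if (is.null(tm)) tm <- points[["time"]]
  s <- points[["survival"]]
  if (is.null(tm) || is.null(s)) {
    stop("points must have columns time_months (or time) and survival",
         call. = FALSE)
  }
  keep <- tm > 0 & s > 0 & s <= 1
  tm <- tm[keep]; s <- s[keep]
  if (!any(s < 1)) {
    stop("exponential rate is not identifiable: no point has survival < 1",
         call. = FALSE)
  }
  y <- -log(s)
  sum(tm * y) / sum(tm^2)
}

# Median overall survival implied by a transition matrix: the (interpolated)
# cycle at which cumulative survival (1 - death occupancy) crosses 0.5.
simulated_median_os <- function(tm, max_cycles = 1200) {
  trace <- run_cohort(tm, n_cycles = max_cycles)
  surv <- 1 - trace$occupancy[, "Death"]
  below <- which(surv < 0.5)
  if (length(below) == 0L) return(Inf)
  i <- below[1L]                       # first cycle index (1-based, cycle i-1)
  s_hi <- surv[i - 1L]; s_lo <- surv[i]
  (i - 2L) + (s_hi - 0.5) / (s_hi - s_lo)
}

#' Derive a monthly transition matrix from survival medians
#'
#' Builds the three-state matrix from the closed-form median conversion:
#' the total probability of leaving the progression-free state comes from the
#' PFS median, the direct PFS-to-death probability from the OS median, and
#' their difference is the progression probability (floored at zero with a
#' warning if the OS median implies a faster exit than the PFS median). The
#' post-progression death probability is either supplied or calibrated by
#' root-finding so that the cohort model's simulated median overall survival
#' matches `median_os` (interpolating between cycles, tolerance 1e-6).
#'
#' @param summary A [survival_summary()].
#' @param pd_death_prob Monthly probability of death from the
#'   progressive-disease state, or `"calibrate"` (the default) to solve for it.
#' @param cycle Cycle length, months.
#' @return A [transition_matrix()].
#' @export
#' @examples
#' derive_transitions(survival_summary(7.2, 18.3, arm = "LP"))
derive_transitions <- function(summary, pd_death_prob = "calibrate",
                               cycle = 1) {
  stopifnot(inherits(summary, "survival_summary"))
  p_exit <- median_to_monthly_prob(summary$median_pfs, cycle)
  p_pfs_death <- median_to_monthly_prob(summary$median_os, cycle)
  if (p_pfs_death > p_exit) {
    warning("PFS->death probability exceeds total PFS-exit probability; ",
            "flooring the progression probability at 0")
    p_pfs_death <- p_exit
  }
  p_pfs_pd <- p_exit - p_pfs_death
  build <- function(p_pd_death) {
    transition_matrix(
      pfs_stay = 1 - p_exit, pfs_pd = p_pfs_pd, pfs_death = p_pfs_death,
      pd_stay = 1 - p_pd_death, pd_death = p_pd_death
    )
  }
  if (identical(pd_death_prob, "calibrate")) {
    target <- summary$median_os
    f <- function(p) simulated_median_os(build(p)) - target
    lo <- 1e-6; hi <- 1 - 1e-6
    f_lo <- f(lo); f_hi <- f(hi)
    if (is.infinite(f_lo)) f_lo <- .Machine$double.xmax
    if (!(f_lo > 0 && f_hi < 0)) {
      stop("calibration of the post-progression death probability failed to ",
           "bracket the target median OS of ", target, " months", call. = FALSE)
    }
    p <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
    return(build(p))
  }
  if (!is.numeric(pd_death_prob) || pd_death_prob < 0 || pd_death_prob > 1) {
    stop("pd_death_prob must be a probability or \"calibrate\"", call. = FALSE)
  }
  build(pd_death_prob)
}

#' Check a transition matrix against the closed-form median conversion
#'
#' Compares the matrix's total progression-free-exit probability with the
#' value implied by the PFS median, and its direct PFS-to-death probability
#' with the value implied by the OS median, flagging each against a
#' tolerance. Useful for auditing transition probabilities fitted elsewhere
#' (e.g. from digitized survival curves) against the published medians.
#'
#' @param matrix A [transition_matrix()].
#' @param summary A [survival_summary()].
#' @param tol Absolute tolerance for the pass flags (default 0.01).
#' @return A data.frame with one row per check: the matrix value, the
#'   closed-form expectation, their absolute difference and a pass flag.
#' @export
validate_transitions <- function(matrix, summary, tol = 0.01) {
  stopifnot(inherits(matrix, "transition_matrix"),
            inherits(summary, "survival_summary"))
  m <- unclass(matrix)
  pfs_exit <- m["PFS", "PD"] + m["PFS", "Death"]
  pfs_death <- m["PFS", "Death"]
  expect_exit <- median_to_monthly_prob(summary$median_pfs)
  expect_death <- median_to_monthly_prob(summary$median_os)
  out <- data.frame(
    check = c("PFS exit vs median PFS", "PFS->death vs median OS"),
    arm = summary$arm,
    population = summary$population,
    matrix_value = c(pfs_exit, pfs_death),
    closed_form = c(expect_exit, expect_death),
    abs_diff = abs(c(pfs_exit - expect_exit, pfs_death - expect_death)),
    stringsAsFactors = FALSE
  )
  out$pass <- out$abs_diff < tol
  out
}

#' Read / write Kaplan-Meier points as two-column CSV
#'
#' The CSV dialect has columns `time_months` and `survival`.
#'
#' @param path File path.
#' @return `read_km_points()` returns a data.frame with columns `time_months`
#'   and `survival`, checked for non-increasing survival in (0, 1\].
#' @export
read_km_points <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("time_months", "survival") %in% names(x))) {
    stop("KM points CSV must have columns time_months and survival",
         call. = FALSE)
  }
  x <- x[order(x$time_months), c("time_months", "survival")]
  if (any(diff(x$survival) > 1e-12)) {
    stop("survival must be non-increasing in time", call. = FALSE)
  }
  x
}

#' @rdname read_km_points
#' @param points Data frame with columns `time_months` and `survival`.
#' @export
write_km_points <- function(points, path) {
  utils::write.csv(points[, c("time_months", "survival")], path,
                   row.names = FALSE)
  invisible(path)
}
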