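# The three-state cohort engine: transition matrix over (PFS, PD, Death),
# cohort trace with per-cycle transition flows, discounted half-cycle
# corrected accumulation of costs and QALYs, and incremental comparison.

STATE_NAMES <- c("PFS", "PD", "Death")

#' Three-state monthly transition matrix
#'
#' Row-stochastic matrix over the ordered states progression-free (PFS),
#' progressive disease (PD) and Death. Backward transitions out of PD and out
#' of Death are structurally zero: Death is absorbing and progression is
#' irreversible. Rows must sum to 1 within 1e-6 (printed inputs carry 3
#' decimals); they are renormalised to sum exactly.
#'
#' @param pfs_stay,pfs_pd,pfs_death First-row probabilities.
#' @param pd_stay,pd_death Second-row probabilities.
#' @param m Alternatively, a full 3x3 numeric matrix (rows/cols PFS, PD,
#'   Death) to validate and wrap.
#' @return An object of class `transition_matrix` (a 3x3 matrix).
#' @export
#' @examples
#' transition_matrix(0.911, 0.052, 0.037, 0.951, 0.049)  # LP, overall
transition_matrix <- function(pfs_stay, pfs_pd, pfs_death,
                              pd_stay, pd_death, m = NULL) {
  if (is.null(m)) {
    m <- matrix(c(pfs_stay, pfs_pd, pfs_death,
                  0,        pd_stay, pd_death,
                  0,        0,       1),
                nrow = 3, byrow = TRUE,
                dimnames = list(STATE_NAMES, STATE_NAMES))
  } else {
    m <- as.matrix(m)
    if (!all(dim(m) == c(3L, 3L))) stop("m must be 3x3", call. = FALSE)
    dimnames(m) <- list(STATE_NAMES, STATE_NAMES)
  }
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  m[m < 0] <- 0; m[m > 1] <- 1
  if (m["PD", "PFS"] != 0) {
    stop("progression is irreversible: PD->PFS must be 0", call. = FALSE)
  }
  if (any(m["Death", ] != c(0, 0, 1))) {
    stop("Death must be absorbing: its row must be (0, 0, 1)", call. = FALSE)
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("transition matrix rows must sum to 1 (off by ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  m <- m / rs
  structure(m, class = "transition_matrix")
}

#' Run the Markov cohort
#'
#' Propagates the state-occupancy vector through `n_cycles` monthly cycles
#' and records the transition flows (the proportion of the cohort moving
#' between each pair of states at each cycle), which one-time transition
#' costs are charged against.
#'
#' @param matrix A [transition_matrix()].
#' @param n_cycles Number of cycles (the trace has `n_cycles + 1` rows,
#'   cycle 0 first).
#' @param initial Initial occupancy over (PFS, PD, Death); defaults to the
#'   whole cohort progression-free.
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   (`(n_cycles+1) x 3` matrix), `flows` (`n_cycles x 3 x 3` array;
#'   `flows[t, i, j]` is the proportion moving from state i to j during
#'   cycle t), and `n_cycles`.
#' @export
run_cohort <- function(matrix, n_cycles, initial = c(1, 0, 0)) {
  stopifnot(inherits(matrix, "transition_matrix"))
  if (length(initial) != 3L || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-8) {
    stop("initial occupancy must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  stopifnot(n_cycles >= 1L)
  occ <- base::matrix(0, n_cycles + 1L, 3L,
                      dimnames = list(NULL, STATE_NAMES))
  flows <- array(0, dim = c(n_cycles, 3L, 3L),
                 dimnames = list(NULL, STATE_NAMES, STATE_NAMES))
  occ[1L, ] <- initial
  m <- unclass(matrix)
  for (t in seq_len(n_cycles)) {
    flows[t, , ] <- occ[t, ] * m          # row i scaled by occupancy of i
    occ[t + 1L, ] <- occ[t, ] %*% m
  }
  structure(list(occupancy = occ, flows = flows, n_cycles = n_cycles),
            class = "cohort_trace")
}

#' State valuation: monthly costs, utilities and one-time costs
#'
#' @param state_costs Named numeric vector of monthly costs (USD) for PFS,
#'   PD and Death (Death is conventionally 0).
#' @param utilities Named numeric vector of utilities in \[0, 1\] for the
#'   three states; Death must be 0.
#' @param death_transition_cost One-time cost (USD) charged on each entry
#'   into Death (e.g. palliative care), attributed to the cost bucket of the
#'   state the patient dies from.
#' @param entry_cost One-time cost (USD) charged for the whole cohort at
#'   cycle 0, undiscounted (e.g. biomarker testing), attributed to the PFS
#'   bucket.
#' @return An object of class `state_valuation`.
#' @export
state_valuation <- function(state_costs = c(PFS = 0, PD = 0, Death = 0),
                            utilities = c(PFS = 1, PD = 1, Death = 0),
                            death_transition_cost = 0,
                            entry_cost = 0) {
  state_costs <- state_costs[STATE_NAMES]
  utilities <- utilities[STATE_NAMES]
  if (anyNA(state_costs) || anyNA(utilities)) {
    stop("state_costs and utilities must be named for PFS, PD and Death",
         call. = FALSE)
  }
  if (any(utilities < 0) || any(utilities > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (utilities[["Death"]] != 0) {
    stop("the utility of Death must be 0", call. = FALSE)
  }
  if (any(state_costs < 0) || death_transition_cost < 0 || entry_cost < 0) {
    stop("costs must be >= 0", call. = FALSE)
  }
  structure(list(state_costs = state_costs, utilities = utilities,
                 death_transition_cost = death_transition_cost,
                 entry_cost = entry_cost),
            class = "state_valuation")
}

#' Discounting specification
#'
#' @param annual_rate Annual discount rate (default 0.03).
#' @param cycle_length_months Cycle length in months (default 1).
#' @return An object of class `discount_spec`.
#' @export
discount_spec <- function(annual_rate = 0.03, cycle_length_months = 1) {
  if (annual_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (cycle_length_months <= 0) stop("cycle length must be > 0", call. = FALSE)
  structure(list(annual_rate = annual_rate,
                 cycle_length_months = cycle_length_months),
            class = "discount_spec")
}

#' Accumulate discounted, half-cycle-corrected costs and QALYs
#'
#' Per-cycle cost is occupancy times the monthly state cost; per-cycle QALY
#' is occupancy times utility times the cycle length in years. Both are
#' discounted with the monthly-compounded factor `(1 + annual)^(-t m / 12)`
#' (cycle length `m` months) and half-cycle corrected with trapezoidal
#' weights (half weight on cycle 0 and on the final cycle). One-time
#' transition costs are charged on each cycle's Death inflow (discounted,
#' full weight, attributed to the source state's bucket) and the entry cost
#' at cycle 0 undiscounted (PFS bucket); both are exempt from the half-cycle
#' weighting.
#'
#' @param trace A [run_cohort()] trace.
#' @param valuation A [state_valuation()].
#' @param discount A [discount_spec()].
#' @param half_cycle Apply the half-cycle correction? (default TRUE).
#' @return An object of class `arm_outcome`: discounted and undiscounted
#'   cost and QALY totals with per-state decompositions, plus the residual
#'   live occupancy at the end of the horizon.
#' @export
accumulate <- function(trace, valuation, discount = discount_spec(),
                       half_cycle = TRUE) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(valuation, "state_valuation"),
            inherits(discount, "discount_spec"))
  n <- trace$n_cycles
  occ <- trace$occupancy
  t_idx <- 0:n
  disc <- (1 + discount$annual_rate)^(-t_idx * discount$cycle_length_months / 12)
  w <- rep(1, n + 1L)
  if (half_cycle) w[c(1L, n + 1L)] <- 0.5

  # death inflow by source state at cycles 1..n (0 at cycle 0)
  inflow_pfs <- c(0, trace$flows[, "PFS", "Death"])
  inflow_pd <- c(0, trace$flows[, "PD", "Death"])

  cyc_years <- discount$cycle_length_months / 12
  per_state <- function(dfac) {
    occ_w <- w * dfac * occ
    cost <- colSums(occ_w) * valuation$state_costs
    cost[["PFS"]] <- cost[["PFS"]] +
      sum(dfac * inflow_pfs) * valuation$death_transition_cost +
      valuation$entry_cost
    cost[["PD"]] <- cost[["PD"]] +
      sum(dfac * inflow_pd) * valuation$death_transition_cost
    qaly <- colSums(occ_w) * valuation$utilities * cyc_years
    list(cost = cost, qaly = qaly)
  }
  d <- per_state(disc)
  u <- per_state(rep(1, n + 1L))

  live_end <- sum(occ[n + 1L, c("PFS", "PD")])
  if (live_end > 1e-4) {
    warning("horizon may be too short: ", format(live_end, digits = 3),
            " of the cohort is still alive at the end of the trace")
  }
  structure(list(
    cost_total = sum(d$cost), cost_by_state = d$cost,
    qaly_total = sum(d$qaly), qaly_by_state = d$qaly,
    cost_total_undiscounted = sum(u$cost), cost_by_state_undiscounted = u$cost,
    qaly_total_undiscounted = sum(u$qaly), qaly_by_state_undiscounted = u$qaly,
    live_occupancy_at_end = live_end,
    half_cycle = half_cycle, discount = discount
  ), class = "arm_outcome")
}

#' Incremental comparison of two arm outcomes
#'
#' @param a Intervention [accumulate()] outcome.
#' @param b Comparator outcome.
#' @param wtp Willingness-to-pay threshold, USD per QALY (default 100,000).
#' @return An object of class `incremental_result` with `delta_cost`,
#'   `delta_qaly`, `icer` (NA when the ratio is meaningless), `nmb`
#'   (`wtp * delta_qaly - delta_cost`), `wtp` and a `dominance` label:
#'   `"none"`, `"dominant"` (cheaper and more effective) or `"dominated"`.
#' @export
compare <- function(a, b, wtp = 1e5) {
  stopifnot(inherits(a, "arm_outcome"), inherits(b, "arm_outcome"))
  dc <- a$cost_total - b$cost_total
  dq <- a$qaly_total - b$qaly_total
  dominance <- "none"
  icer <- NA_real_
  if (dq > 0 && dc < 0) {
    dominance <- "dominant"
  } else if (dq < 0 && dc > 0) {
    dominance <- "dominated"
  } else if (dq != 0) {
    icer <- dc / dq
  }
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 nmb = wtp * dq - dc, wtp = wtp, dominance = dominance),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("Incremental cost:  $", formatC(round_currency(x$delta_cost),
                                      format = "f", digits = 2, big.mark = ","),
      "\n", sep = "")
  cat("Incremental QALYs: ", formatC(x$delta_qaly, format = "f", digits = 2),
      "\n", sep = "")
  if (x$dominance != "none") {
    cat("Dominance: intervention is ", x$dominance, "\n", sep = "")
  } else if (is.na(x$icer)) {
    cat("ICER: undefined (no QALY difference)\n")
  } else {
    cat("ICER: $", formatC(round_currency(x$icer), format = "f", digits = 2,
                           big.mark = ","), " per QALY\n", sep = "")
  }
  cat("NMB at $", formatC(x$wtp, format = "d", big.mark = ","), "/QALY: $",
      formatC(round_currency(x$nmb), format = "f", digits = 2,
              big.mark = ","), "\n", sep = "")
  invisible(x)
}
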