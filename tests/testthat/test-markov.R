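# Cohort engine: conservation, absorption, closed-form oracle equivalence,
# half-cycle bracketing, discounting, and incremental comparison.

lp_matrix <- transition_matrix(0.911, 0.052, 0.037, 0.951, 0.049)

test_that("transition matrices enforce structure", {
  expect_error(transition_matrix(0.8, 0.1, 0.2, 0.9, 0.1), "sum to 1")
  expect_error(transition_matrix(0.9, 0.2, -0.1, 0.9, 0.1), "\\[0, 1\\]")
  m <- matrix(c(0.9, 0.05, 0.05, 0.1, 0.8, 0.1, 0, 0, 1), 3, byrow = TRUE)
  expect_error(transition_matrix(m = m), "irreversible")
})

test_that("an identity matrix leaves occupancy constant", {
  tm <- transition_matrix(1, 0, 0, 1, 0)
  tr <- run_cohort(tm, 50, initial = c(0.6, 0.3, 0.1))
  expect_true(all(apply(tr$occupancy, 1, function(r) {
    isTRUE(all.equal(r, c(PFS = 0.6, PD = 0.3, Death = 0.1)))
  })))
})

test_that("cumulative state occupancy matches the geometric-series closed form", {
  # two-state reduction: PFS-stay 0.5, person-cycles = 1 / (1 - 0.5)
  tm <- transition_matrix(0.5, 0.25, 0.25, 0.9, 0.1)
  tr <- run_cohort(tm, 200)
  expect_equal(sum(tr$occupancy[, "PFS"]), 2.0, tolerance = 1e-6)
  # published first-row stay probability over the full horizon
  tr_lp <- run_cohort(lp_matrix, 600)
  expect_equal(sum(tr_lp$occupancy[, "PFS"]), 11.2359550562,
               tolerance = 1e-6)
})

test_that("traces conserve occupancy, keep flows consistent, and absorb into death", {
  tr <- run_cohort(lp_matrix, 600)
  expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
  death <- tr$occupancy[, "Death"]
  expect_true(all(diff(death) >= 0))
  expect_gt(death[601], 1 - 1e-4)
  expect_true(all(tr$flows >= 0))
  # occupancy steps are exactly the column sums of the flow matrices
  for (t in c(1, 7, 300)) {
    expect_equal(unname(colSums(tr$flows[t, , ])),
                 unname(tr$occupancy[t + 1, ]), tolerance = 1e-12)
  }
})

test_that("a single-state cohort accrues one QALY per undiscounted year", {
  tm <- transition_matrix(1, 0, 0, 1, 0)
  tr <- suppressWarnings(run_cohort(tm, 12))
  val <- state_valuation(utilities = c(PFS = 1, PD = 1, Death = 0))
  out <- suppressWarnings(
    accumulate(tr, val, discount_spec(annual_rate = 0)))
  expect_equal(out$qaly_total, 1.0)
})

test_that("zero discounting makes discounted and undiscounted totals equal", {
  tr <- run_cohort(lp_matrix, 600)
  val <- state_valuation(state_costs = c(PFS = 1000, PD = 500, Death = 0),
                         utilities = c(PFS = 0.8, PD = 0.6, Death = 0),
                         death_transition_cost = 2000, entry_cost = 100)
  out <- accumulate(tr, val, discount_spec(annual_rate = 0))
  expect_equal(out$cost_total, out$cost_total_undiscounted)
  expect_equal(out$qaly_total, out$qaly_total_undiscounted)
})

test_that("totals are non-increasing in the discount rate", {
  tr <- run_cohort(lp_matrix, 600)
  val <- state_valuation(state_costs = c(PFS = 1000, PD = 500, Death = 0),
                         utilities = c(PFS = 0.8, PD = 0.6, Death = 0),
                         death_transition_cost = 2000, entry_cost = 100)
  rates <- c(0, 0.01, 0.03, 0.05, 0.1)
  costs <- vapply(rates, function(r) {
    accumulate(tr, val, discount_spec(annual_rate = r))$cost_total
  }, numeric(1))
  qalys <- vapply(rates, function(r) {
    accumulate(tr, val, discount_spec(annual_rate = r))$qaly_total
  }, numeric(1))
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
  expect_lte(costs[3], costs[1])  # discounted <= undiscounted
})

test_that("the half-cycle-corrected total lies between cycle-start and cycle-end sums", {
  tr <- run_cohort(lp_matrix, 600)
  val <- state_valuation(utilities = c(PFS = 0.817, PD = 0.779, Death = 0))
  disc <- discount_spec(0.03)
  hc <- accumulate(tr, val, disc, half_cycle = TRUE)$qaly_total
  # independent start/end-weighted sums straight from the trace
  d <- (1.03)^(-(0:600) / 12)
  per_cycle <- (tr$occupancy %*% c(0.817, 0.779, 0)) * d / 12
  start_sum <- sum(per_cycle[1:600])
  end_sum <- sum(per_cycle[2:601])
  expect_gte(hc, min(start_sum, end_sum))
  expect_lte(hc, max(start_sum, end_sum))
})

test_that("state decompositions sum to the totals", {
  tr <- run_cohort(lp_matrix, 600)
  val <- state_valuation(state_costs = c(PFS = 36792.62, PD = 3266.78,
                                         Death = 0),
                         utilities = c(PFS = 0.817, PD = 0.779, Death = 0),
                         death_transition_cost = 11266.07,
                         entry_cost = 666.40)
  out <- accumulate(tr, val, discount_spec(0.03))
  expect_equal(sum(out$cost_by_state), out$cost_total, tolerance = 1e-8)
  expect_equal(sum(out$qaly_by_state), out$qaly_total, tolerance = 1e-8)
})

test_that("adding the same entry cost to both arms leaves the increment unchanged", {
  res0 <- run_scenario(base_scenario,
                       values = c("Testing for dMMR/MSI-H status-one set" = 0))
  res1 <- run_scenario(base_scenario,
                       values = c("Testing for dMMR/MSI-H status-one set" = 5000))
  expect_equal(res0$incremental$delta_cost, res1$incremental$delta_cost,
               tolerance = 1e-9)
  expect_equal(res0$incremental$icer, res1$incremental$icer, tolerance = 1e-9)
  # but each arm's own total does move
  expect_equal(res1$arms$LP$cost_total - res0$arms$LP$cost_total, 5000)
})

test_that("incremental comparison handles ties and dominance", {
  tr <- run_cohort(lp_matrix, 600)
  val <- state_valuation(state_costs = c(PFS = 100, PD = 50, Death = 0),
                         utilities = c(PFS = 0.8, PD = 0.6, Death = 0))
  a <- accumulate(tr, val)
  same <- compare(a, a, wtp = 1e5)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qaly, 0)
  expect_equal(same$nmb, 0)
  expect_true(is.na(same$icer))
  cheap_val <- state_valuation(state_costs = c(PFS = 10, PD = 5, Death = 0),
                               utilities = c(PFS = 0.9, PD = 0.7, Death = 0))
  cheaper_better <- accumulate(tr, cheap_val)
  expect_identical(compare(cheaper_better, a)$dominance, "dominant")
  expect_identical(compare(a, cheaper_better)$dominance, "dominated")
})
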