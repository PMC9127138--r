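# Per-state monthly cost arithmetic. The published state totals must be
# reproduced to the cent from the unit costs and event rates.

lp_ae <- list(adverse_event("Hypertension", 0.379, 7965.60),
              adverse_event("Diarrhea", 0.076, 7795.80))
chemo_ae <- list(adverse_event("Anemia", 0.147, 14314.20),
                 adverse_event("Neutropenia", 0.258, 14429.73),
                 adverse_event("Neutrophil count decreased", 0.212, 14429.73),
                 adverse_event("WBC decreased", 0.103, 7071.65))

test_that("adverse-event management cost reproduces the published monthly totals", {
  expect_identical(round_currency(ae_management_cost(lp_ae)), 3611.44)
  expect_identical(round_currency(ae_management_cost(chemo_ae)), 9614.54)
  expect_identical(ae_management_cost(list()), 0)
})

test_that("adverse-event cost is linear in the event rates", {
  double <- lapply(lp_ae, function(a) {
    adverse_event(a$name, min(1, 2 * a$rate), a$cost)
  })
  expect_equal(ae_management_cost(double), 2 * ae_management_cost(lp_ae))
})

test_that("invalid adverse-event items are rejected by name", {
  expect_error(adverse_event("Hypertension", -0.1, 100), "Hypertension")
  expect_error(adverse_event("Diarrhea", 1.2, 100), "Diarrhea")
  expect_error(adverse_event("Anemia", 0.5, -5), "Anemia")
})

test_that("crossover subsequent-therapy cost matches the published values", {
  expect_identical(
    round_currency(subsequent_therapy_cost(10740.27, 360.42, 0.280)), 2906.36)
  expect_identical(
    round_currency(subsequent_therapy_cost(36792.62, 360.42, 0.481)), 17523.89)
  expect_identical(subsequent_therapy_cost(5000, 300, 0), 0)
  expect_error(subsequent_therapy_cost(5000, 300, 1.1), "acceptance_rate")
})

test_that("subsequent-therapy cost is monotone in acceptance rate and the other arm's total", {
  rates <- seq(0, 1, by = 0.1)
  costs <- vapply(rates, function(r) subsequent_therapy_cost(10000, 300, r),
                  numeric(1))
  expect_true(all(diff(costs) > 0))
  totals <- seq(1000, 50000, length.out = 20)
  costs <- vapply(totals, function(x) subsequent_therapy_cost(x, 300, 0.4),
                  numeric(1))
  expect_true(all(diff(costs) > 0))
})

test_that("drug acquisition handles both the stated-monthly and component forms", {
  lenva <- drug_cost_spec("Lenvatinib", monthly_acquisition_cost = 16166.98)
  expect_identical(drug_acquisition_monthly(lenva), 16166.98)
  # component form: $2.00/mg x 13.8 mg/day x 30.44 days/month
  comp <- drug_cost_spec("generic", unit_price = 2.00, dose = 13.8,
                         administrations_per_month = 30.44)
  expect_identical(round_currency(drug_acquisition_monthly(comp)), 840.14)
  zero <- drug_cost_spec("free", unit_price = 0, dose = 13.8,
                         administrations_per_month = 30.44)
  expect_identical(drug_acquisition_monthly(zero), 0)
  expect_error(drug_cost_spec("broken", unit_price = 2.00), "broken")
})

test_that("per-m2 dosing scales with body surface area", {
  a <- drug_cost_spec("iv", unit_price = 10, dose = 60,
                      administrations_per_month = 1.45,
                      body_surface_area = 1.71, per_bsa = TRUE)
  b <- drug_cost_spec("iv", unit_price = 10, dose = 60 * 1.71,
                      administrations_per_month = 1.45)
  expect_equal(drug_acquisition_monthly(a), drug_acquisition_monthly(b))
})

test_that("state monthly totals reproduce the published state rows to the cent", {
  lp_pfs <- state_cost_spec(drug_acquisition = 32820.76,
                            ae_management = ae_management_cost(lp_ae),
                            disease_management = 360.42)
  expect_identical(round_currency(state_monthly_total(lp_pfs)), 36792.62)
  lp_pd <- state_cost_spec(
    disease_management = 360.42,
    subsequent_therapy = subsequent_therapy_cost(10740.27, 360.42, 0.280))
  expect_identical(round_currency(state_monthly_total(lp_pd)), 3266.78)
  expect_identical(state_monthly_total(state_cost_spec()), 0)
})

test_that("a state total equals the sum of its single-component totals", {
  spec <- state_cost_spec(drug_acquisition = 123.45, ae_management = 67.89,
                          disease_management = 11.11,
                          subsequent_therapy = 22.22)
  parts <- c(
    state_monthly_total(state_cost_spec(drug_acquisition = 123.45)),
    state_monthly_total(state_cost_spec(ae_management = 67.89)),
    state_monthly_total(state_cost_spec(disease_management = 11.11)),
    state_monthly_total(state_cost_spec(subsequent_therapy = 22.22))
  )
  expect_equal(state_monthly_total(spec), sum(parts))
  expect_error(state_cost_spec(drug_acquisition = -1), ">= 0")
})

test_that("currency rounding is half-up at 2 decimals", {
  expect_identical(round_currency(2906.358), 2906.36)
  expect_identical(round_currency(2.005), 2.01)   # base round() would give 2.00
  expect_identical(round_currency(-2.005), -2.01)
})
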