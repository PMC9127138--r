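# Median-to-probability conversion, rate<->probability, exponential fits to
# KM points, and transition derivation/validation from survival summaries.

test_that("median-to-monthly-probability matches the closed form", {
  expect_equal(median_to_monthly_prob(1), 0.5)
  expect_equal(median_to_monthly_prob(7.2), 0.0917816373056, tolerance = 1e-10)
  expect_equal(median_to_monthly_prob(11.4), 0.0589908203712, tolerance = 1e-10)
  # equals the rate route exactly: 1 - exp(-ln2/m)
  for (m in c(0.5, 3.8, 7.2, 18.3, 120)) {
    expect_equal(median_to_monthly_prob(m), rate_to_prob(log(2) / m))
  }
  expect_error(median_to_monthly_prob(0), "> 0")
  expect_error(median_to_monthly_prob(-3), "> 0")
})

test_that("median-to-probability is strictly decreasing in the median", {
  p <- median_to_monthly_prob(seq(1, 60, by = 0.5))
  expect_true(all(diff(p) < 0))
})

test_that("rate <-> probability conversions round-trip to machine precision", {
  expect_identical(rate_to_prob(0), 0)
  expect_equal(prob_to_rate(0.5), log(2))
  expect_equal(rate_to_prob(0.0963), 0.0918084822593, tolerance = 1e-10)
  r <- c(1e-6, 0.01, 0.0963, 0.5, 3)
  expect_equal(prob_to_rate(rate_to_prob(r)), r, tolerance = 1e-12)
  expect_error(prob_to_rate(1), "infinite")
})

test_that("exponential fit recovers the rate from noiseless KM points", {
  # single (median) point: exact closed form
  one <- data.frame(time_months = 7.2, survival = 0.5)
  expect_equal(fit_exponential(one), log(2) / 7.2, tolerance = 1e-12)
  # exact exponential curve
  t <- 1:24
  pts <- data.frame(time_months = t, survival = exp(-0.1 * t))
  expect_equal(fit_exponential(pts), 0.1, tolerance = 1e-10)
  expect_error(
    fit_exponential(data.frame(time_months = 1:3, survival = c(1, 1, 1))),
    "identifiable")
})

test_that("exponential fit recovers the rate from simulated cohorts", {
  ipd <- simulate_ipd(500, median_pfs = 7.2, median_os = 18.3, seed = 11)
  rate <- fit_exponential(km_from_ipd(ipd, "pfs"))
  expect_lt(abs(rate - log(2) / 7.2) / (log(2) / 7.2), 0.10)
})

test_that("derived transitions match the closed form and are row-stochastic", {
  lp <- derive_transitions(survival_summary(7.2, 18.3, arm = "LP"),
                           pd_death_prob = 0.049)
  expect_equal(lp["PFS", "Death"], 0.0371685371454, tolerance = 1e-9)
  expect_equal(lp["PFS", "PD"] + lp["PFS", "Death"], 0.0917816373056,
               tolerance = 1e-9)
  chemo_pmmr <- derive_transitions(
    survival_summary(3.8, 12.0, arm = "chemotherapy", population = "pMMR"),
    pd_death_prob = 0.096)
  expect_equal(chemo_pmmr["PFS", "Death"], 0.0561256873183, tolerance = 1e-9)
  expect_equal(rowSums(unclass(lp)), c(PFS = 1, PD = 1, Death = 1),
               tolerance = 1e-12)
  expect_equal(unname(unclass(lp)["Death", ]), c(0, 0, 1))
})

test_that("equal PFS and OS medians route the whole PFS exit to death", {
  expect_warning(
    tm <- derive_transitions(survival_summary(6, 6), pd_death_prob = 0.1),
    NA)
  expect_equal(tm["PFS", "PD"], 0)
  expect_equal(tm["PFS", "Death"], median_to_monthly_prob(6))
})

test_that("calibrating the post-progression death probability hits the OS median", {
  sm <- survival_summary(7.2, 18.3, arm = "LP")
  tm <- derive_transitions(sm, pd_death_prob = "calibrate")
  expect_equal(markovcea:::simulated_median_os(tm), 18.3, tolerance = 1e-4)
  # a self-built matrix validates with zero discrepancy on the PFS checks
  rep <- validate_transitions(tm, sm)
  expect_true(all(rep$abs_diff < 1e-9))
  expect_true(all(rep$pass))
})

test_that("published transition rows validate against the trial medians", {
  lp <- transition_matrix(0.911, 0.052, 0.037, 0.951, 0.049)
  rep <- validate_transitions(lp, survival_summary(7.2, 18.3, arm = "LP"),
                              tol = 0.01)
  exit <- rep[rep$check == "PFS exit vs median PFS", ]
  expect_lt(exit$abs_diff, 0.005)
  expect_true(exit$pass)
  chemo <- transition_matrix(0.814, 0.127, 0.059, 0.908, 0.092)
  rep2 <- validate_transitions(chemo,
                               survival_summary(3.8, 11.4, arm = "chemo"))
  expect_lt(rep2[rep2$check == "PFS->death vs median OS", "abs_diff"], 0.001)
})

test_that("KM points round-trip through the CSV dialect", {
  pts <- data.frame(time_months = c(1, 2.5, 4), survival = c(0.9, 0.6, 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_km_points(pts, path)
  expect_equal(read_km_points(path), pts)
  bad <- data.frame(time_months = c(1, 2), survival = c(0.5, 0.9))
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_km_points(path), "non-increasing")
})
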