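# Synthetic data: pseudo individual-patient survival data emulating the
# trial's Kaplan-Meier curves (progression and post-progression times both
# exponential, the latter calibrated so the marginal OS median matches),
# KM-point extraction standing in for curve digitization, and randomized
# full scenarios for property tests.

# Marginal OS CDF of Exp(a) progression + Exp(b) post-progression time.
hypoexp_cdf <- function(t, a, b) {
  if (abs(a - b) < 1e-12) {
    stats::pgamma(t, shape = 2, rate = a)
  } else {
    1 - (b * exp(-a * t) - a * exp(-b * t)) / (b - a)
  }
}

# Post-progression rate such that the marginal OS median equals median_os.
solve_post_progression_rate <- function(median_pfs, median_os) {
  a <- log(2) / median_pfs
  f <- function(b) hypoexp_cdf(median_os, a, b) - 0.5
  # b -> Inf gives OS -> PFS (median_pfs); b -> 0 gives median -> Inf
  lo <- 1e-8
  hi <- 1e4 / median_os
  if (f(lo) > 0 || f(hi) < 0) {
    stop("cannot calibrate post-progression survival for median PFS ",
         median_pfs, " and median OS ", median_os, call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate pseudo individual-patient survival data
#'
#' Progression times are exponential with rate `log(2) / median_pfs`;
#' overall-survival times add an independent exponential post-progression
#' time whose rate is solved numerically so the marginal OS median equals
#' `median_os` (which must therefore exceed `median_pfs`). Optional
#' independent exponential censoring. Deterministic given `seed`; the
#' caller's RNG state is restored on exit.
#'
#' @param n Number of patients.
#' @param median_pfs,median_os Target medians, months.
#' @param censoring_rate Censoring hazard per month (default 0, no
#'   censoring).
#' @param seed Integer seed.
#' @return data.frame with columns `patient_id`, `pfs_months`, `pfs_event`,
#'   `os_months`, `os_event` (times censored, event flags 0/1).
#' @export
simulate_ipd <- function(n, median_pfs, median_os, censoring_rate = 0,
                         seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (median_pfs <= 0 || median_os <= 0) {
    stop("medians must be > 0", call. = FALSE)
  }
  if (median_os <= median_pfs) {
    stop("median OS (", median_os, ") must exceed median PFS (", median_pfs,
         "): overall survival adds a positive post-progression time",
         call. = FALSE)
  }
  if (censoring_rate < 0) stop("censoring_rate must be >= 0", call. = FALSE)
  b <- solve_post_progression_rate(median_pfs, median_os)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  pfs <- stats::rexp(n, rate = log(2) / median_pfs)
  os <- pfs + stats::rexp(n, rate = b)
  cens <- if (censoring_rate > 0) stats::rexp(n, rate = censoring_rate) else
    rep(Inf, n)
  data.frame(
    patient_id = seq_len(n),
    pfs_months = pmin(pfs, cens),
    pfs_event = as.integer(pfs <= cens),
    os_months = pmin(os, cens),
    os_event = as.integer(os <= cens)
  )
}

#' Kaplan-Meier points from individual-patient data
#'
#' Product-limit survival estimates at each event time (via
#' [survival::survfit()]), in the two-column form consumed by
#' [fit_exponential()] and [read_km_points()]. Stands in for points
#' digitized off a published curve.
#'
#' @param ipd A [simulate_ipd()] data.frame (or any with the same columns).
#' @param endpoint `"pfs"` or `"os"`.
#' @return data.frame with columns `time_months` and `survival`, one row per
#'   distinct event time.
#' @export
km_from_ipd <- function(ipd, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  time <- ipd[[paste0(endpoint, "_months")]]
  event <- ipd[[paste0(endpoint, "_event")]]
  if (sum(event) == 0) {
    stop("no events: cannot estimate a survival curve", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time_months = fit$time[keep], survival = fit$surv[keep])
}

#' Random valid scenario for property testing
#'
#' Generates a fully valid two-arm scenario (row-stochastic transition
#' matrices with absorbing death and positive death probabilities,
#' non-negative costs with 95%-interval ranges, utilities in \[0, 1\]) that
#' runs end-to-end through the cohort model, tornado and PSA. Deterministic
#' given `seed`.
#'
#' @param seed Integer seed.
#' @return A `cea_scenario`.
#' @export
random_scenario <- function(seed = 1) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  rcost <- function(base) list(base = base, low = 0.75 * base,
                               high = 1.25 * base, distribution = "Gamma")
  u_pfs <- stats::runif(1, 0.55, 0.95)
  u_pd <- stats::runif(1, 0.3, u_pfs)
  utility <- function(u) list(base = u, low = max(0.01, 0.75 * u),
                              high = min(1, 1.25 * u), distribution = "Beta")
  params <- list(
    "Drug A1" = rcost(stats::runif(1, 1e3, 2e4)),
    "Drug A2" = rcost(stats::runif(1, 1e3, 2e4)),
    "Drug B1" = rcost(stats::runif(1, 50, 5e3)),
    "AE alpha" = rcost(stats::runif(1, 1e3, 2e4)),
    "AE beta" = rcost(stats::runif(1, 1e3, 2e4))
  )
  params[[ROLE_ADMIN]] <- rcost(stats::runif(1, 20, 100))
  params[[ROLE_DISEASE]] <- rcost(stats::runif(1, 100, 1e3))
  params[[ROLE_TESTING]] <- rcost(stats::runif(1, 100, 1e3))
  params[[ROLE_PALLIATIVE]] <- rcost(stats::runif(1, 2e3, 2e4))
  params[[ROLE_U_PFS]] <- utility(u_pfs)
  params[[ROLE_U_PD]] <- utility(u_pd)

  rtrans <- function() {
    exit <- stats::runif(1, 0.05, 0.4)
    death_share <- stats::runif(1, 0.1, 0.9)
    pd_death <- stats::runif(1, 0.02, 0.3)
    list(pfs_stay = 1 - exit,
         pfs_pd = exit * (1 - death_share),
         pfs_death = exit * death_share,
         pd_stay = 1 - pd_death, pd_death = pd_death)
  }
  arm <- function(name, drugs, ae_names) {
    ae <- as.list(stats::runif(length(ae_names), 0.01, 0.5))
    names(ae) <- ae_names
    list(name = name, drugs = drugs,
         administration_minutes_per_month = stats::runif(1, 0, 120),
         adverse_events = ae,
         subsequent_therapy_acceptance = stats::runif(1, 0, 0.9),
         transitions = rtrans())
  }
  new_scenario(list(
    label = paste("random scenario, seed", seed),
    population = "overall",
    settings = list(horizon_cycles = 400L,
                    annual_discount_rate = stats::runif(1, 0, 0.05),
                    wtp_per_qaly = 1e5, half_cycle_correction = TRUE,
                    cycle_length_months = 1),
    parameters = params,
    arms = list(
      arm("A", c("Drug A1", "Drug A2"), "AE alpha"),
      arm("B", "Drug B1", c("AE alpha", "AE beta"))
    )
  ))
}
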