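# Scenario configuration: a complete two-arm model parameterisation loaded
# from YAML (or built in code), validated at load, and composed into the
# per-state valuations the cohort engine consumes. Parameter rows carry the
# published base values and uncertainty ranges under their source-table row
# names, so sensitivity analyses can address them by name.

# Reserved parameter names with a structural role in the composition.
ROLE_ADMIN      <- "Costs of administration per 10 mins"
ROLE_DISEASE    <- "Costs of disease management"
ROLE_TESTING    <- "Testing for dMMR/MSI-H status-one set"
ROLE_PALLIATIVE <- "Costs of palliative care-one set"
ROLE_U_PFS      <- "Utility of PFS state"
ROLE_U_PD       <- "Utility of PD state"
ROLE_PARAMS <- c(ROLE_ADMIN, ROLE_DISEASE, ROLE_TESTING, ROLE_PALLIATIVE,
                 ROLE_U_PFS, ROLE_U_PD)

SCENARIO_KEYS <- c("label", "population", "settings", "parameters", "arms")
SETTINGS_KEYS <- c("horizon_cycles", "cycle_length_months",
                   "annual_discount_rate", "wtp_per_qaly",
                   "half_cycle_correction")
PARAM_KEYS <- c("base", "low", "high", "distribution")
ARM_KEYS <- c("name", "drugs", "administration_minutes_per_month",
              "adverse_events", "subsequent_therapy_acceptance",
              "transitions", "median_pfs", "median_os")
TRANSITION_KEYS <- c("pfs_stay", "pfs_pd", "pfs_death", "pd_stay", "pd_death")

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
}

validate_parameter <- function(p, name) {
  check_keys(p, PARAM_KEYS, paste0("parameter '", name, "'"))
  if (is.null(p$base) || !is.numeric(p$base)) {
    stop("parameter '", name, "' needs a numeric 'base' value", call. = FALSE)
  }
  p$distribution <- if (is.null(p$distribution)) "Fixed" else
    match.arg(p$distribution, c("Gamma", "Beta", "Fixed"))
  if (!is.null(p$low) && !is.null(p$high)) {
    if (!(p$low <= p$base && p$base <= p$high)) {
      stop("parameter '", name, "' violates low <= base <= high", call. = FALSE)
    }
  }
  if (p$distribution == "Beta" || name %in% c(ROLE_U_PFS, ROLE_U_PD)) {
    bounds <- c(p$base, p$low, p$high)
    if (any(bounds < 0 | bounds > 1)) {
      stop("parameter '", name, "' must lie in [0, 1] (got ",
           paste(bounds, collapse = ", "), ")", call. = FALSE)
    }
  } else if (p$base < 0) {
    stop("parameter '", name, "' must be >= 0", call. = FALSE)
  }
  p
}

validate_arm <- function(arm, params, i) {
  where <- paste0("arm ", i, if (!is.null(arm$name)) paste0(" ('", arm$name, "')"))
  check_keys(arm, ARM_KEYS, where)
  if (is.null(arm$name)) stop(where, " needs a name", call. = FALSE)
  arm$drugs <- as.character(arm$drugs %||% character())
  missing_drugs <- setdiff(arm$drugs, names(params))
  if (length(missing_drugs)) {
    stop(where, ": drug(s) not in parameters: ",
         paste(missing_drugs, collapse = ", "), call. = FALSE)
  }
  arm$administration_minutes_per_month <-
    arm$administration_minutes_per_month %||% 0
  if (arm$administration_minutes_per_month < 0) {
    stop(where, ": administration minutes must be >= 0", call. = FALSE)
  }
  ae <- arm$adverse_events %||% list()
  for (nm in names(ae)) {
    if (!nm %in% names(params)) {
      stop(where, ": adverse event '", nm,
           "' has no unit-cost parameter of that name", call. = FALSE)
    }
    if (ae[[nm]] < 0 || ae[[nm]] > 1) {
      stop(where, ": adverse event '", nm, "' rate must be in [0, 1]",
           call. = FALSE)
    }
  }
  arm$adverse_events <- ae
  acc <- arm$subsequent_therapy_acceptance %||% 0
  if (acc < 0 || acc > 1) {
    stop(where, ": subsequent_therapy_acceptance must be in [0, 1]",
         call. = FALSE)
  }
  arm$subsequent_therapy_acceptance <- acc
  tr <- arm$transitions
  if (is.null(tr)) stop(where, " needs transitions", call. = FALSE)
  check_keys(tr, TRANSITION_KEYS, paste0(where, " transitions"))
  if (!all(TRANSITION_KEYS %in% names(tr))) {
    stop(where, " transitions must give all of: ",
         paste(TRANSITION_KEYS, collapse = ", "), call. = FALSE)
  }
  # constructs and validates (row sums, ranges); keep the plain list in the
  # scenario so YAML round-trips are lossless
  transition_matrix(tr$pfs_stay, tr$pfs_pd, tr$pfs_death,
                    tr$pd_stay, tr$pd_death)
  arm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a scenario from a plain list
#'
#' Validates the full configuration (unknown keys rejected, all invariants
#' checked) and returns a `cea_scenario`. The list layout matches the YAML
#' schema of [load_scenario()].
#'
#' @param x Nested list: `label`, `population` (`"overall"` or `"pMMR"`),
#'   `settings` (horizon, cycle length, discount rate, WTP, half-cycle flag),
#'   `parameters` (named rows with `base`, optional `low`/`high`, and
#'   `distribution` in Gamma/Beta/Fixed), and `arms` (ordered list,
#'   intervention first; each with `name`, `drugs`, administration minutes,
#'   `adverse_events` rates keyed by unit-cost parameter name,
#'   `subsequent_therapy_acceptance`, `transitions`, and optional survival
#'   medians).
#' @return An object of class `cea_scenario`.
#' @export
new_scenario <- function(x) {
  check_keys(x, SCENARIO_KEYS, "scenario")
  x$label <- x$label %||% "unnamed scenario"
  x$population <- match.arg(x$population %||% "overall", c("overall", "pMMR"))
  s <- x$settings %||% list()
  check_keys(s, SETTINGS_KEYS, "settings")
  s$horizon_cycles <- as.integer(s$horizon_cycles %||% 600L)
  s$cycle_length_months <- s$cycle_length_months %||% 1
  s$annual_discount_rate <- s$annual_discount_rate %||% 0.03
  s$wtp_per_qaly <- s$wtp_per_qaly %||% 1e5
  s$half_cycle_correction <- isTRUE(s$half_cycle_correction %||% TRUE)
  if (s$horizon_cycles < 1L) stop("horizon_cycles must be >= 1", call. = FALSE)
  discount_spec(s$annual_discount_rate, s$cycle_length_months)  # validates
  x$settings <- s

  params <- x$parameters %||% list()
  missing_roles <- setdiff(ROLE_PARAMS, names(params))
  if (length(missing_roles)) {
    stop("parameters must include: ", paste(missing_roles, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(params)) {
    params[[nm]] <- validate_parameter(params[[nm]], nm)
  }
  x$parameters <- params

  arms <- x$arms
  if (length(arms) != 2L) {
    stop("a scenario compares exactly two arms (intervention first)",
         call. = FALSE)
  }
  arms <- lapply(seq_along(arms), function(i) validate_arm(arms[[i]], params, i))
  if (arms[[1]]$name == arms[[2]]$name) {
    stop("arm names must differ", call. = FALSE)
  }
  names(arms) <- vapply(arms, `[[`, "", "name")
  x$arms <- arms
  structure(x, class = "cea_scenario")
}

#' Load / save a scenario configuration (YAML)
#'
#' The YAML schema mirrors the published input table: a `parameters` section
#' whose keys are the table's row names (drug monthly costs, adverse-event
#' unit costs, "Costs of administration per 10 mins", "Costs of disease
#' management", "Testing for dMMR/MSI-H status-one set", "Costs of palliative
#' care-one set", "Utility of PFS state", "Utility of PD state"), each with
#' `base`, optional `low`/`high` range, and a `distribution` family
#' (Gamma/Beta/Fixed); an ordered two-entry `arms` section (intervention
#' first) wiring drugs, adverse-event rates, administration time, crossover
#' acceptance and the fixed monthly transition probabilities; and global
#' `settings`. Two fixtures ship with the package:
#' `keynote775_base.yaml` (overall population) and `keynote775_pmmr.yaml`
#' (mismatch-repair-proficient subgroup); see [keynote775_scenario()].
#'
#' @param path File path.
#' @return `load_scenario()` returns a validated `cea_scenario`.
#' @export
load_scenario <- function(path) {
  new_scenario(yaml::read_yaml(path))
}

#' @rdname load_scenario
#' @param scenario A `cea_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "cea_scenario"))
  yaml::write_yaml(unclass(scenario), path, precision = 15)
  invisible(path)
}

#' Packaged trial scenario
#'
#' Loads one of the two scenario fixtures shipped with the package: the
#' overall-population base case or the mismatch-repair-proficient (pMMR)
#' subgroup (identical costs and utilities, subgroup transition
#' probabilities).
#'
#' @param population `"overall"` or `"pMMR"`.
#' @return A `cea_scenario`.
#' @export
keynote775_scenario <- function(population = c("overall", "pMMR")) {
  population <- match.arg(population)
  file <- if (population == "overall") "keynote775_base.yaml" else
    "keynote775_pmmr.yaml"
  load_scenario(system.file("extdata", file, package = "markovcea",
                            mustWork = TRUE))
}

#' Base parameter values of a scenario
#'
#' @param scenario A `cea_scenario`.
#' @return Named numeric vector of every parameter's base value.
#' @export
scenario_values <- function(scenario) {
  stopifnot(inherits(scenario, "cea_scenario"))
  vapply(scenario$parameters, `[[`, numeric(1), "base")
}

#' Parameter table of a scenario
#'
#' @param scenario A `cea_scenario`.
#' @return data.frame with columns `name`, `base`, `low`, `high`,
#'   `distribution` (NA range where the source prints none).
#' @export
scenario_parameter_table <- function(scenario) {
  stopifnot(inherits(scenario, "cea_scenario"))
  p <- scenario$parameters
  data.frame(
    name = names(p),
    base = vapply(p, `[[`, numeric(1), "base"),
    low = vapply(p, function(q) q$low %||% NA_real_, numeric(1)),
    high = vapply(p, function(q) q$high %||% NA_real_, numeric(1)),
    distribution = vapply(p, `[[`, character(1), "distribution"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Compose per-arm monthly cost components from a parameter-value vector.
# The crossover linkage makes each arm's progressive-disease subsequent-
# therapy cost depend on the *other* arm's progression-free monthly total.
arm_cost_components <- function(scenario, values = NULL) {
  vals <- scenario_values(scenario)
  if (!is.null(values)) {
    unknown <- setdiff(names(values), names(vals))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    vals[names(values)] <- values
  }
  arms <- scenario$arms
  acq <- ae <- pfs <- numeric(length(arms))
  for (i in seq_along(arms)) {
    a <- arms[[i]]
    acq[i] <- sum(vals[a$drugs]) +
      a$administration_minutes_per_month / 10 * vals[[ROLE_ADMIN]]
    ae[i] <- if (length(a$adverse_events) == 0L) 0 else
      ae_management_cost(data.frame(
        name = names(a$adverse_events),
        rate = unlist(a$adverse_events, use.names = FALSE),
        cost = vals[names(a$adverse_events)]
      ))
    pfs[i] <- acq[i] + ae[i] + vals[[ROLE_DISEASE]]
  }
  out <- vector("list", length(arms))
  for (i in seq_along(arms)) {
    other <- if (i == 1L) 2L else 1L
    subseq <- subsequent_therapy_cost(pfs[other], vals[[ROLE_DISEASE]],
                                      arms[[i]]$subsequent_therapy_acceptance)
    out[[i]] <- list(
      drug_acquisition = acq[i], ae_management = ae[i],
      disease_management = vals[[ROLE_DISEASE]],
      pfs_monthly_total = pfs[i],
      subsequent_therapy = subseq,
      pd_monthly_total = vals[[ROLE_DISEASE]] + subseq
    )
  }
  names(out) <- names(arms)
  attr(out, "values") <- vals
  out
}

arm_transition_matrix <- function(arm) {
  tr <- arm$transitions
  transition_matrix(tr$pfs_stay, tr$pfs_pd, tr$pfs_death,
                    tr$pd_stay, tr$pd_death)
}

#' Run the full deterministic model for a scenario
#'
#' Composes each arm's per-state valuation from the parameter values (base
#' values unless overridden), runs the cohort trace, accumulates discounted
#' half-cycle-corrected costs and QALYs, and compares the arms
#' (intervention = first arm).
#'
#' @param scenario A `cea_scenario`.
#' @param values Optional named numeric vector overriding parameter base
#'   values (used by the sensitivity analyses).
#' @param traces Optional named list of precomputed [run_cohort()] traces per
#'   arm; transition probabilities do not depend on the parameter values, so
#'   sensitivity loops can reuse them.
#' @return An object of class `cea_result`: list with `arms` (named
#'   [accumulate()] outcomes), `incremental` ([compare()] result),
#'   `components` (the composed monthly cost components), `scenario` label
#'   and population.
#' @export
run_scenario <- function(scenario, values = NULL, traces = NULL) {
  stopifnot(inherits(scenario, "cea_scenario"))
  s <- scenario$settings
  comp <- arm_cost_components(scenario, values)
  vals <- attr(comp, "values")
  disc <- discount_spec(s$annual_discount_rate, s$cycle_length_months)
  if (is.null(traces)) traces <- scenario_traces(scenario)
  outcomes <- vector("list", length(scenario$arms))
  for (i in seq_along(scenario$arms)) {
    nm <- names(scenario$arms)[i]
    val <- state_valuation(
      state_costs = c(PFS = comp[[i]]$pfs_monthly_total,
                      PD = comp[[i]]$pd_monthly_total, Death = 0),
      utilities = c(PFS = min(1, max(0, vals[[ROLE_U_PFS]])),
                    PD = min(1, max(0, vals[[ROLE_U_PD]])), Death = 0),
      death_transition_cost = vals[[ROLE_PALLIATIVE]],
      entry_cost = vals[[ROLE_TESTING]]
    )
    outcomes[[i]] <- accumulate(traces[[nm]], val, disc,
                                half_cycle = s$half_cycle_correction)
  }
  names(outcomes) <- names(scenario$arms)
  structure(list(
    arms = outcomes,
    incremental = compare(outcomes[[1]], outcomes[[2]], wtp = s$wtp_per_qaly),
    components = comp,
    label = scenario$label,
    population = scenario$population
  ), class = "cea_result")
}

#' Cohort traces for every arm of a scenario
#'
#' @param scenario A `cea_scenario`.
#' @return Named list of [run_cohort()] traces.
#' @export
scenario_traces <- function(scenario) {
  stopifnot(inherits(scenario, "cea_scenario"))
  lapply(scenario$arms, function(a) {
    run_cohort(arm_transition_matrix(a), scenario$settings$horizon_cycles)
  })
}

#' Validate a scenario's transition probabilities against its medians
#'
#' Runs [validate_transitions()] for every arm that carries survival medians.
#'
#' @param scenario A `cea_scenario`.
#' @param tol Absolute tolerance for the pass flags.
#' @return data.frame of per-arm validation rows (empty if no arm has
#'   medians).
#' @export
validate_scenario_transitions <- function(scenario, tol = 0.01) {
  stopifnot(inherits(scenario, "cea_scenario"))
  rows <- list()
  for (a in scenario$arms) {
    if (is.null(a$median_pfs) || is.null(a$median_os)) next
    sm <- survival_summary(a$median_pfs, a$median_os, arm = a$name,
                           population = scenario$population)
    rows[[a$name]] <- validate_transitions(arm_transition_matrix(a), sm, tol)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.cea_scenario <- function(x, ...) {
  cat("Cost-effectiveness scenario:", x$label, "\n")
  cat("  population:", x$population,
      "| arms:", paste(names(x$arms), collapse = " vs "), "\n")
  s <- x$settings
  cat("  horizon:", s$horizon_cycles, "cycles of", s$cycle_length_months,
      "month(s); discount", paste0(100 * s$annual_discount_rate, "%/yr;"),
      "WTP $", formatC(s$wtp_per_qaly, format = "d", big.mark = ","),
      "/QALY\n")
  cat("  parameters:", length(x$parameters), "\n")
  invisible(x)
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Base-case results:", x$label, "(", x$population, "population )\n")
  print(cea_table(x), row.names = FALSE)
  invisible(x)
}
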