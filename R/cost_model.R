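# Per-state monthly cost arithmetic: drug acquisition, adverse-event
# management, crossover subsequent therapy, disease management, and the
# composed state totals. All arithmetic is full precision; currency is only
# rounded at presentation time (see round_currency()).

#' Round a dollar amount for presentation
#'
#' Rounds to 2 decimal places with half-up tie-breaking (the convention used
#' for currency), unlike [base::round()]'s round-half-even. Internal model
#' arithmetic is never rounded; use this only when printing or exporting.
#'
#' @param x Numeric vector of dollar amounts.
#' @return `x` rounded half-up to the cent.
#' @export
#' @examples
#' round_currency(2906.358)   # 2906.36
round_currency <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5) / 100
}

#' Adverse-event item
#'
#' One grade 3-4 adverse event attributed to a treatment arm: the proportion
#' of patients experiencing it and the unit management cost per event.
#'
#' @param name Event label (e.g. `"Hypertension"`).
#' @param rate Proportion of patients with the grade 3-4 event, in \[0, 1\].
#' @param cost Management cost per event, USD.
#' @return An object of class `ae_item`.
#' @export
adverse_event <- function(name, rate, cost) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1) {
    stop("adverse event '", name, "': rate must be a proportion in [0, 1], got ",
         format(rate), call. = FALSE)
  }
  if (!is.numeric(cost) || length(cost) != 1L || is.na(cost) || cost < 0) {
    stop("adverse event '", name, "': management cost must be >= 0, got ",
         format(cost), call. = FALSE)
  }
  structure(list(name = as.character(name), rate = rate, cost = cost),
            class = "ae_item")
}

#' Monthly adverse-event management cost
#'
#' Incidence-weighted sum of per-event management costs: each grade 3-4 event
#' contributes its rate times its unit cost, treated as a recurring monthly
#' cost while on treatment (i.e. in the progression-free state).
#'
#' @param items A list of [adverse_event()] objects (an empty list gives 0), or
#'   a data.frame with columns `name`, `rate`, `cost`.
#' @return Monthly cost in USD (unrounded).
#' @export
#' @examples
#' ae_management_cost(list(
#'   adverse_event("Hypertension", 0.379, 7965.60),
#'   adverse_event("Diarrhea", 0.076, 7795.80)
#' ))
ae_management_cost <- function(items) {
  if (is.data.frame(items)) {
    items <- mapply(adverse_event, items$name, items$rate, items$cost,
                    SIMPLIFY = FALSE)
  }
  if (length(items) == 0L) return(0)
  total <- 0
  for (it in items) {
    if (!inherits(it, "ae_item")) {
      it <- adverse_event(it$name, it$rate, it$cost)
    }
    total <- total + it$rate * it$cost
  }
  total
}

#' Monthly crossover subsequent-therapy cost
#'
#' Patients in the progressive-disease state are assumed to cross over to the
#' other arm's regimen; the monthly cost is the acceptance rate times the
#' other arm's progression-free monthly total net of disease management
#' (which is already charged in the progressive-disease state itself).
#'
#' @param other_arm_pfs_total Other arm's progression-free-state monthly total,
#'   USD/month.
#' @param disease_management Monthly disease-management cost, USD/month.
#' @param acceptance_rate Proportion of progressed patients accepting the
#'   subsequent therapy, in \[0, 1\].
#' @return Monthly cost in USD (unrounded).
#' @export
#' @examples
#' subsequent_therapy_cost(10740.27, 360.42, 0.280)  # LP arm: 2906.358
subsequent_therapy_cost <- function(other_arm_pfs_total, disease_management,
                                    acceptance_rate) {
  if (!is.numeric(acceptance_rate) || length(acceptance_rate) != 1L ||
      is.na(acceptance_rate) || acceptance_rate < 0 || acceptance_rate > 1) {
    stop("acceptance_rate must be a proportion in [0, 1], got ",
         format(acceptance_rate), call. = FALSE)
  }
  if (other_arm_pfs_total < disease_management) {
    stop("other arm's PFS monthly total (", format(other_arm_pfs_total),
         ") is below the disease-management cost (",
         format(disease_management), ")", call. = FALSE)
  }
  acceptance_rate * (other_arm_pfs_total - disease_management)
}

#' Drug acquisition cost specification
#'
#' Either a directly stated monthly acquisition cost, or a decomposition into
#' unit price x dose x administrations per month, optionally scaled by body
#' surface area (for per-m2 dosing) and with a bundled administration-time
#' component priced per 10 minutes.
#'
#' @param name Drug label.
#' @param monthly_acquisition_cost Monthly cost in USD; if given, the
#'   component fields are ignored.
#' @param unit_price USD per mg (or per administration when `dose` is per
#'   administration).
#' @param dose mg per day / per administration, as matching `administrations_per_month`.
#' @param administrations_per_month Number of dosing occasions per month
#'   (e.g. 30.44 days for daily oral dosing).
#' @param body_surface_area m2; multiplies the dose when `per_bsa = TRUE`.
#' @param per_bsa Logical; is the dose expressed per m2 of body surface area?
#' @param admin_minutes_per_administration Administration chair time, minutes.
#' @param admin_cost_per_10min USD per 10 minutes of administration time.
#' @return An object of class `drug_cost_spec`.
#' @export
drug_cost_spec <- function(name,
                           monthly_acquisition_cost = NULL,
                           unit_price = NULL, dose = NULL,
                           administrations_per_month = NULL,
                           body_surface_area = 1, per_bsa = FALSE,
                           admin_minutes_per_administration = 0,
                           admin_cost_per_10min = 0) {
  has_monthly <- !is.null(monthly_acquisition_cost)
  has_components <- !is.null(unit_price) && !is.null(dose) &&
    !is.null(administrations_per_month)
  if (!has_monthly && !has_components) {
    stop("drug '", name, "': give either monthly_acquisition_cost or all of ",
         "unit_price, dose and administrations_per_month", call. = FALSE)
  }
  vals <- c(monthly_acquisition_cost, unit_price, dose,
            administrations_per_month, body_surface_area,
            admin_minutes_per_administration, admin_cost_per_10min)
  if (any(vals < 0)) {
    stop("drug '", name, "': all cost components must be >= 0", call. = FALSE)
  }
  structure(list(
    name = as.character(name),
    monthly_acquisition_cost = monthly_acquisition_cost,
    unit_price = unit_price, dose = dose,
    administrations_per_month = administrations_per_month,
    body_surface_area = body_surface_area, per_bsa = per_bsa,
    admin_minutes_per_administration = admin_minutes_per_administration,
    admin_cost_per_10min = admin_cost_per_10min
  ), class = "drug_cost_spec")
}

#' Monthly drug acquisition cost
#'
#' @param spec A [drug_cost_spec()].
#' @return Monthly acquisition cost in USD (unrounded). A stated monthly cost
#'   is returned unchanged; otherwise the component product
#'   `unit_price * dose * administrations_per_month` (times body surface area
#'   for per-m2 dosing) plus any bundled administration-time cost.
#' @export
drug_acquisition_monthly <- function(spec) {
  stopifnot(inherits(spec, "drug_cost_spec"))
  if (!is.null(spec$monthly_acquisition_cost)) {
    return(spec$monthly_acquisition_cost)
  }
  bsa <- if (spec$per_bsa) spec$body_surface_area else 1
  drug <- spec$unit_price * spec$dose * bsa * spec$administrations_per_month
  admin <- spec$admin_minutes_per_administration / 10 *
    spec$admin_cost_per_10min * spec$administrations_per_month
  drug + admin
}

#' Per-state cost specification
#'
#' The monthly cost components charged while occupying a health state, plus
#' one-time costs charged at model entry and on transition into another state
#' (these are excluded from the monthly total).
#'
#' @param drug_acquisition,ae_management,disease_management,subsequent_therapy
#'   Monthly components, USD/month.
#' @param one_time_entry Named numeric vector of one-time costs applied at
#'   model entry (e.g. `c("Testing for dMMR/MSI-H status" = 666.40)`).
#' @param transition_costs Named numeric vector of one-time costs applied on
#'   transition, named by target state (e.g. `c(Death = 11266.07)` for
#'   palliative care).
#' @return An object of class `state_cost_spec`.
#' @export
state_cost_spec <- function(drug_acquisition = 0, ae_management = 0,
                            disease_management = 0, subsequent_therapy = 0,
                            one_time_entry = numeric(),
                            transition_costs = numeric()) {
  comp <- c(drug_acquisition = drug_acquisition,
            ae_management = ae_management,
            disease_management = disease_management,
            subsequent_therapy = subsequent_therapy)
  if (any(comp < 0) || any(one_time_entry < 0) || any(transition_costs < 0)) {
    stop("all cost components must be >= 0", call. = FALSE)
  }
  structure(list(
    drug_acquisition = drug_acquisition,
    ae_management = ae_management,
    disease_management = disease_management,
    subsequent_therapy = subsequent_therapy,
    one_time_entry = one_time_entry,
    transition_costs = transition_costs
  ), class = "state_cost_spec")
}

#' Total monthly cost of a state
#'
#' Sum of the recurring monthly components of a [state_cost_spec()]; one-time
#' entry and transition costs are excluded (they are charged by the cohort
#' accumulator when the corresponding event occurs).
#'
#' @param spec A [state_cost_spec()].
#' @return Monthly total in USD (unrounded).
#' @export
state_monthly_total <- function(spec) {
  stopifnot(inherits(spec, "state_cost_spec"))
  spec$drug_acquisition + spec$ae_management +
    spec$disease_management + spec$subsequent_therapy
}
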