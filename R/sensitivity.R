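# One-way (tornado) and probabilistic sensitivity analysis. Transition
# probabilities are fixed inputs, so every deterministic rerun and every PSA
# draw reuses the base cohort traces and only recomposes the valuations.

#' Fit a sampling distribution to a (base, low, high) parameter row
#'
#' The published range is interpreted as a symmetric `range_z`-SD interval:
#' `sd = (high - low) / (2 * range_z)`, by default a 95% interval
#' (`range_z = 1.96`); the distribution is then fitted by the method of
#' moments with mean equal to the base value. Gamma:
#' `shape = mean^2 / var`, `scale = var / mean`. Beta: moment equations on
#' \[0, 1\], with the variance clipped below `mean * (1 - mean)` when the
#' stated range is too wide for the support. `Fixed` (or a degenerate range)
#' always returns the base value. Setting `range_z = 1` reads the range as
#' mean +/- 1 SD, which reproduces the spread of the published Monte-Carlo
#' summaries (see the methods vignette).
#'
#' @param name Parameter label.
#' @param base Base (mean) value.
#' @param low,high Range endpoints (`low <= base <= high`); may be NULL for
#'   Fixed.
#' @param family `"Gamma"`, `"Beta"` or `"Fixed"`.
#' @param range_z Number of standard deviations each side of the mean the
#'   (low, high) range spans (default 1.96).
#' @return An object of class `param_distribution`.
#' @export
#' @examples
#' fit_distribution("example cost", 100, 75, 125, "Gamma")
fit_distribution <- function(name, base, low = NULL, high = NULL,
                             family = c("Gamma", "Beta", "Fixed"),
                             range_z = 1.96) {
  family <- match.arg(family)
  out <- list(name = name, base = base, low = low, high = high,
              family = family)
  if (family != "Fixed") {
    if (is.null(low) || is.null(high)) {
      stop("parameter '", name, "': a ", family,
           " distribution needs a (low, high) range", call. = FALSE)
    }
    if (!(low <= base && base <= high)) {
      stop("parameter '", name, "' violates low <= base <= high",
           call. = FALSE)
    }
    sd <- (high - low) / (2 * range_z)
    if (sd == 0 || base == 0) {
      out$family <- "Fixed"
    } else if (family == "Gamma") {
      if (base < 0) {
        stop("parameter '", name, "': Gamma requires base >= 0", call. = FALSE)
      }
      out$shape <- base^2 / sd^2
      out$scale <- sd^2 / base
    } else {                              # Beta
      if (base <= 0 || base >= 1) {
        stop("parameter '", name, "': Beta requires base in (0, 1)",
             call. = FALSE)
      }
      v <- min(sd^2, 0.95 * base * (1 - base))
      k <- base * (1 - base) / v - 1
      out$shape1 <- base * k
      out$shape2 <- (1 - base) * k
    }
  }
  structure(out, class = "param_distribution")
}

#' Sample from a fitted parameter distribution
#'
#' @param dist A [fit_distribution()] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n` (all equal to base for Fixed).
#' @export
sample_distribution <- function(dist, n) {
  stopifnot(inherits(dist, "param_distribution"))
  switch(dist$family,
    Fixed = rep(dist$base, n),
    Gamma = stats::rgamma(n, shape = dist$shape, scale = dist$scale),
    Beta = stats::rbeta(n, shape1 = dist$shape1, shape2 = dist$shape2)
  )
}

# Default deterministic-sensitivity parameter set: each arm's drug rows are
# varied jointly as one "drug acquisition" block (the influential combination
# regimen is reported as a single factor), every other non-Fixed parameter is
# varied alone. Ranges default to base * (1 -/+ span) where none is printed.
default_tornado_groups <- function(scenario, span) {
  params <- scenario$parameters
  drug_names <- unlist(lapply(scenario$arms, `[[`, "drugs"), use.names = FALSE)
  groups <- list()
  for (a in scenario$arms) {
    if (length(a$drugs) == 0L) next
    groups[[paste0("Costs of drug acquisition (", a$name, ")")]] <- a$drugs
  }
  for (nm in names(params)) {
    p <- params[[nm]]
    if (p$distribution == "Fixed" || nm %in% drug_names) next
    groups[[nm]] <- nm
  }
  groups
}

param_bounds <- function(p, span) {
  list(low = p$low %||% (p$base * (1 - span)),
       high = p$high %||% (p$base * (1 + span)))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the full deterministic model with each parameter (or named group
#' of parameters) set to its low and high value, holding everything else at
#' base, and reports the ICER swing per parameter, sorted descending. A
#' parameter's range is its published (low, high) where one exists and
#' `base * (1 -/+ span)` otherwise. By default each arm's drug-cost rows are
#' varied jointly as a single drug-acquisition parameter and every other
#' non-Fixed parameter is varied alone; pass `parameters` (a character
#' vector of parameter names, or a named list of name groups) to control the
#' set.
#'
#' @param scenario A `cea_scenario`.
#' @param parameters Optional parameter set (see above).
#' @param span Relative half-range used where no range is printed
#'   (default 0.25).
#' @return data.frame of class `tornado_result`: `parameter`, `icer_low`,
#'   `icer_high` (ICER at the parameter's low / high value), `swing`
#'   (`|icer_high - icer_low|`), sorted by descending swing.
#' @export
one_way_tornado <- function(scenario, parameters = NULL, span = 0.25) {
  stopifnot(inherits(scenario, "cea_scenario"))
  if (is.null(parameters)) {
    groups <- default_tornado_groups(scenario, span)
  } else {
    if (is.character(parameters)) {
      groups <- as.list(parameters)
      names(groups) <- parameters
    } else {
      groups <- parameters
    }
    missing <- setdiff(unlist(groups), names(scenario$parameters))
    if (length(missing)) {
      stop("unknown parameter(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  traces <- scenario_traces(scenario)
  icer_at <- function(members, side) {
    vals <- vapply(members, function(nm) {
      param_bounds(scenario$parameters[[nm]], span)[[side]]
    }, numeric(1))
    names(vals) <- members
    run_scenario(scenario, values = vals, traces = traces)$incremental$icer
  }
  rows <- lapply(names(groups), function(g) {
    lo <- icer_at(groups[[g]], "low")
    hi <- icer_at(groups[[g]], "high")
    data.frame(parameter = g, icer_low = lo, icer_high = hi,
               swing = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte-Carlo: each draw samples every non-Fixed parameter
#' independently from its fitted distribution (Gamma for costs, Beta for
#' utilities; transition probabilities are fixed inputs and are never
#' sampled), recomposes the per-state valuations, reruns both arms through
#' the cohort model and records per-draw discounted costs and QALYs.
#' Deterministic given `seed` (the caller's RNG state is restored on exit).
#'
#' @param scenario A `cea_scenario`.
#' @param distributions Optional named list of [fit_distribution()] objects;
#'   defaults to fitting every scenario parameter from its published
#'   base/range/family.
#' @param n Number of draws (default 10,000).
#' @param seed Integer seed (default 20220510).
#' @param range_z How many SDs the published (low, high) ranges span each
#'   side of the mean when fitting the default distributions; see
#'   [fit_distribution()].
#' @return An object of class `psa_samples`: `draws` (data.frame with
#'   per-arm `cost_*` and `qaly_*` plus `delta_cost` and `delta_qaly`,
#'   intervention minus comparator), `params` (n x p matrix of sampled
#'   values), `n`, `seed`, `wtp`, `arm_names`, and `clipped` (count of
#'   utility draws clipped into \[0, 1\]).
#' @export
run_psa <- function(scenario, distributions = NULL, n = 10000,
                    seed = 20220510, range_z = 1.96) {
  stopifnot(inherits(scenario, "cea_scenario"))
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (is.null(distributions)) {
    distributions <- lapply(names(scenario$parameters), function(nm) {
      p <- scenario$parameters[[nm]]
      if (p$distribution == "Fixed") {
        fit_distribution(nm, p$base, family = "Fixed")
      } else {
        b <- param_bounds(p, 0.25)
        fit_distribution(nm, p$base, b$low, b$high, p$distribution,
                         range_z = range_z)
      }
    })
    names(distributions) <- names(scenario$parameters)
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  p <- length(distributions)
  samples <- matrix(NA_real_, n, p,
                    dimnames = list(NULL, names(distributions)))
  for (j in seq_len(p)) {
    samples[, j] <- sample_distribution(distributions[[j]], n)
  }
  # utilities must stay on [0, 1]
  clipped <- 0L
  for (nm in intersect(c(ROLE_U_PFS, ROLE_U_PD), colnames(samples))) {
    bad <- samples[, nm] < 0 | samples[, nm] > 1
    clipped <- clipped + sum(bad)
    samples[, nm] <- pmin(1, pmax(0, samples[, nm]))
  }
  if (clipped > 0L) {
    message(clipped, " sampled utility value(s) clipped into [0, 1]")
  }

  traces <- scenario_traces(scenario)
  arm_names <- names(scenario$arms)
  cost <- matrix(NA_real_, n, 2L); qaly <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    res <- run_scenario(scenario, values = samples[i, ], traces = traces)
    cost[i, ] <- vapply(res$arms, `[[`, numeric(1), "cost_total")
    qaly[i, ] <- vapply(res$arms, `[[`, numeric(1), "qaly_total")
  }
  draws <- data.frame(cost[, 1], qaly[, 1], cost[, 2], qaly[, 2],
                      cost[, 1] - cost[, 2], qaly[, 1] - qaly[, 2])
  names(draws) <- c(paste0(c("cost_", "qaly_"), arm_names[1]),
                    paste0(c("cost_", "qaly_"), arm_names[2]),
                    "delta_cost", "delta_qaly")
  structure(list(draws = draws, params = samples, n = n, seed = seed,
                 wtp = scenario$settings$wtp_per_qaly,
                 arm_names = arm_names, clipped = clipped),
            class = "psa_samples")
}

#' @export
summary.psa_samples <- function(object, ...) {
  d <- object$draws
  nm <- object$arm_names
  out <- data.frame(
    arm = nm,
    mean_cost = c(mean(d[[paste0("cost_", nm[1])]]),
                  mean(d[[paste0("cost_", nm[2])]])),
    sd_cost = c(stats::sd(d[[paste0("cost_", nm[1])]]),
                stats::sd(d[[paste0("cost_", nm[2])]])),
    mean_qaly = c(mean(d[[paste0("qaly_", nm[1])]]),
                  mean(d[[paste0("qaly_", nm[2])]])),
    sd_qaly = c(stats::sd(d[[paste0("qaly_", nm[1])]]),
                stats::sd(d[[paste0("qaly_", nm[2])]])),
    stringsAsFactors = FALSE
  )
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the intervention
#' is cost-effective is the fraction of PSA draws with positive incremental
#' net monetary benefit (`wtp * delta_qaly - delta_cost > 0`).
#'
#' @param samples A [run_psa()] result.
#' @param wtp_grid Numeric vector of willingness-to-pay values, USD/QALY.
#' @return data.frame with columns `wtp` and `probability` (empty for an
#'   empty grid).
#' @export
ceac <- function(samples, wtp_grid) {
  stopifnot(inherits(samples, "psa_samples"))
  if (length(wtp_grid) == 0L) {
    return(data.frame(wtp = numeric(), probability = numeric()))
  }
  dc <- samples$draws$delta_cost
  dq <- samples$draws$delta_qaly
  prob <- vapply(wtp_grid, function(w) mean(w * dq - dc > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}
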