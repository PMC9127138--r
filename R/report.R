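# Publication-style rendering of results: the cost-effectiveness table with
# the standard row labels, CSV/JSON export, and formatting conventions
# (currency and QALYs to 2 decimals, probabilities to 3).

#' Cost-effectiveness results table
#'
#' Assembles the standard base-case table (per-state and total costs,
#' per-state and total effectiveness, incremental cost, incremental
#' effectiveness, cost/effectiveness ratios, ICER), optionally followed by
#' the Monte-Carlo summary block when a PSA result is supplied.
#'
#' @param result A [run_scenario()] `cea_result`.
#' @param psa Optional [run_psa()] `psa_samples` for the simulation block.
#' @return data.frame with columns `row` and one column per arm, holding
#'   unrounded numbers (NA in cells the published layout leaves blank).
#' @export
cea_table <- function(result, psa = NULL) {
  stopifnot(inherits(result, "cea_result"))
  arms <- result$arms
  nm <- names(arms)
  inc <- result$incremental
  get <- function(field, state = NULL) {
    vapply(arms, function(a) {
      if (is.null(state)) a[[field]] else a[[field]][[state]]
    }, numeric(1))
  }
  ce <- get("cost_total") / get("qaly_total")
  rows <- list(
    list("Costs for PFS state", get("cost_by_state", "PFS")),
    list("Costs for PD state", get("cost_by_state", "PD")),
    list("Total costs", get("cost_total")),
    list("Incremental costs", c(inc$delta_cost, NA_real_)),
    list("Effectiveness for PFS state", get("qaly_by_state", "PFS")),
    list("Effectiveness for PD state", get("qaly_by_state", "PD")),
    list("Total effectiveness", get("qaly_total")),
    list("Incremental effectiveness", c(inc$delta_qaly, NA_real_)),
    list("Cost/Effectiveness", ce),
    list("ICER ($ per QALY)", c(inc$icer, NA_real_))
  )
  if (!is.null(psa)) {
    stopifnot(inherits(psa, "psa_samples"))
    s <- summary(psa)
    rows <- c(rows, list(
      list("Mean costs ($)", s$mean_cost),
      list("SD of costs ($)", s$sd_cost),
      list("Mean effectiveness (QALYs)", s$mean_qaly),
      list("SD of effectiveness (QALYs)", s$sd_qaly)
    ))
  }
  out <- data.frame(
    row = vapply(rows, function(r) r[[1]], ""),
    a = vapply(rows, function(r) r[[2]][1], numeric(1)),
    b = vapply(rows, function(r) r[[2]][2], numeric(1)),
    stringsAsFactors = FALSE
  )
  names(out) <- c("row", nm)
  out
}

#' Format a results table for display
#'
#' Currency and QALY cells are rendered to 2 decimals (half-up currency
#' rounding), blank where the layout leaves them empty.
#'
#' @param table A [cea_table()] data.frame.
#' @return Character matrix of aligned cells.
#' @export
format_cea_table <- function(table) {
  cells <- vapply(names(table)[-1], function(col) {
    x <- table[[col]]
    is_qaly <- grepl("ffectiveness", table$row) &
      !grepl("Cost/", table$row)
    out <- character(length(x))
    out[is_qaly] <- ifelse(is.na(x[is_qaly]), "",
                           formatC(x[is_qaly], format = "f", digits = 2))
    out[!is_qaly] <- ifelse(is.na(x[!is_qaly]), "",
                            formatC(round_currency(x[!is_qaly]),
                                    format = "f", digits = 2,
                                    big.mark = ","))
    out
  }, character(nrow(table)))
  cbind(row = format(table$row), cells)
}

#' Export results as CSV / JSON
#'
#' `write_cea_csv()` writes any results data.frame ([cea_table()],
#' [one_way_tornado()], [ceac()], PSA draws) as CSV; `write_cea_json()`
#' writes a list or data.frame as JSON (numbers unrounded).
#'
#' @param x A data.frame (CSV) or any jsonlite-serialisable object (JSON).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cea_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cea_csv
#' @export
write_cea_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
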