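#' Incremental cost-effectiveness ratio over a scope
#'
#' Sums incremental costs and effects over a year or cumulatively (the
#' comparator is the status quo with zero incremental cost and effect) and
#' returns the cost per DALY averted and per death averted. A scope with
#' positive cost but no effect yields a typed "undefined (no effect)"
#' record — never an infinity.
#'
#' @param cost_stream [compute_cost_stream()] output.
#' @param impact [aggregate_impact()] output.
#' @param scope A year index, or `"cumulative"`.
#' @return One-row tibble of class `icer_record`: `scope`,
#'   `incremental_cost`, `dalys_averted`, `deaths_averted`,
#'   `cost_per_daly`, `cost_per_death`, `status`.
#' @export
icer <- function(cost_stream, impact, scope = "cumulative") {
  if (identical(scope, "cumulative")) {
    cost <- sum(cost_stream$usd_2014)
    by <- impact$by_year
  } else {
    stopifnot(is.numeric(scope), length(scope) == 1)
    cost <- sum(cost_stream$usd_2014[cost_stream$year == scope])
    by <- impact$by_year[impact$by_year$year == scope, ]
  }
  mask <- if (impact$params$include_stillbirths) rep(TRUE, nrow(by)) else by$outcome != "stillbirth"
  dalys <- sum(by$dalys[mask])
  deaths <- sum(by$deaths_averted)
  defined <- dalys > 0
  rec <- tibble::tibble(
    scope = as.character(scope)[1],
    incremental_cost = cost,
    dalys_averted = dalys,
    deaths_averted = deaths,
    cost_per_daly = if (defined) cost / dalys else NA_real_,
    cost_per_death = if (deaths > 0) cost / deaths else NA_real_,
    status = if (defined) "defined" else "undefined (no effect)"
  )
  structure(rec, class = c("icer_record", class(rec)))
}

#' Per-year and cumulative ICER table
#'
#' @param cost_stream,impact As for [icer()].
#' @param horizon_years Years to tabulate.
#' @return Tibble of ICER records, one per year plus a cumulative row.
#' @export
icer_table <- function(cost_stream, impact,
                       horizon_years = attr(cost_stream, "horizon_years")) {
  rows <- lapply(c(as.list(seq_len(horizon_years)), "cumulative"),
                 function(s) icer(cost_stream, impact, s))
  out <- do.call(rbind, rows)
  tibble::as_tibble(out)
}

#' Classify an ICER against GDP-multiple thresholds
#'
#' Below 1x per-capita income per DALY averted: highly cost-effective;
#' below 3x: cost-effective; otherwise not cost-effective. Exact multiples
#' fall into the weaker class.
#'
#' @param icer_value Cost per DALY averted (USD, > 0).
#' @param per_capita_income Per-capita GDP/GNI (USD, > 0).
#' @return Object of class `threshold_verdict`: `threshold_basis`,
#'   `icer_value`, `verdict`.
#' @export
classify_icer <- function(icer_value, per_capita_income) {
  stopifnot(icer_value > 0, per_capita_income > 0)
  verdict <- if (icer_value < per_capita_income) {
    "highly cost-effective"
  } else if (icer_value < 3 * per_capita_income) {
    "cost-effective"
  } else {
    "not cost-effective"
  }
  structure(list(threshold_basis = per_capita_income,
                 icer_value = icer_value, verdict = verdict),
            class = "threshold_verdict")
}

#' @export
print.threshold_verdict <- function(x, ...) {
  cat(sprintf("ICER %.2f vs per-capita income %.0f: %s\n",
              x$icer_value, x$threshold_basis, x$verdict))
  invisible(x)
}

#' Program cost as a share of the district primary-care budget
#'
#' Contextualizes an annual per-district program cost against the share of
#' the national health budget directed to primary care, split evenly across
#' districts: `annual_cost / (budget * fraction / n_districts) * 100`.
#'
#' @param annual_cost_per_district USD per district per year.
#' @param national_budget National health budget (USD).
#' @param primary_care_fraction Fraction of the budget for primary care.
#' @param n_districts Number of districts sharing it.
#' @return Percent of the per-district primary-care budget.
#' @export
budget_share <- function(annual_cost_per_district, national_budget,
                         primary_care_fraction, n_districts) {
  stopifnot(annual_cost_per_district >= 0, national_budget > 0,
            primary_care_fraction > 0, n_districts > 0)
  annual_cost_per_district /
    (national_budget * primary_care_fraction / n_districts) * 100
}
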