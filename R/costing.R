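#' Convert a raw expenditure into 2014 USD
#'
#' Applies the month-appropriate market exchange rate, then re-expresses the
#' dollar amount in 2014 terms with the consumer price index
#' (`cpi[2014] / cpi[year]`). Missing months or years are explicit lookup
#' failures, never interpolated.
#'
#' @param raw_amount Amount in the source currency.
#' @param month Calendar month `"YYYY-MM"` the cost was incurred.
#' @param fx Tibble with columns `month`, `rate` (local currency per USD).
#' @param cpi Tibble with columns `year`, `index`; must contain 2014.
#' @param currency `"local"` (apply fx) or `"USD"` (skip fx).
#' @return Amount in 2014 USD.
#' @export
adjust_to_base_year <- function(raw_amount, month, fx = synthetic_fx_table(),
                                cpi = synthetic_cpi_table(),
                                currency = c("local", "USD")) {
  currency <- match.arg(currency)
  stopifnot(raw_amount >= 0)
  year <- as.integer(substr(month, 1, 4))
  if (!2014 %in% cpi$year) stop("CPI table must contain the 2014 base year", call. = FALSE)
  if (!year %in% cpi$year) {
    stop(sprintf("CPI table has no entry for year %d", year), call. = FALSE)
  }
  usd <- raw_amount
  if (currency == "local") {
    i <- match(month, fx$month)
    if (is.na(i)) stop(sprintf("FX table has no entry for month %s", month), call. = FALSE)
    usd <- raw_amount / fx$rate[i]
  }
  usd * cpi$index[cpi$year == 2014] / cpi$index[cpi$year == year]
}

#' Equivalent annual cost of a capital outlay
#'
#' Spreads `amount` over `lifespan_years` with the standard annuity factor
#' at discount rate `r`: `amount * r / (1 - (1 + r)^-lifespan)`. The zero-
#' discount limit is straight-line, `amount / lifespan`.
#'
#' @param amount Capital amount.
#' @param lifespan_years Useful life in years (>= 1).
#' @param r Annual discount rate (fraction, >= 0; default 3%).
#' @return Cost per year.
#' @export
annualize <- function(amount, lifespan_years, r = 0.03) {
  stopifnot(lifespan_years >= 1, r >= 0)
  if (r == 0) return(amount / lifespan_years)
  amount * r / (1 - (1 + r)^(-lifespan_years))
}

#' Assign concrete districts to the rollout plan
#'
#' Expands per-region, per-period new-district counts into a schedule of
#' (district, start period) pairs, taking districts from the registry in
#' registry order within each region. Periods are half-years 1..6; the
#' district's start calendar year is `ceiling(period / 2)`.
#'
#' @param plan Tibble `region`, `period`, `new_districts`
#'   (see [reference_rollout_plan()]).
#' @param registry District registry from [generate_districts()].
#' @return Tibble `district_id`, `region`, `start_period`, `start_year`.
#' @export
expand_rollout <- function(plan, registry) {
  need <- vapply(split(plan$new_districts, plan$region), sum, numeric(1))
  have <- table(registry$region)
  short <- need[need > 0 & need > as.numeric(have[names(need)]) |
                  (need > 0 & !(names(need) %in% names(have)))]
  if (length(short) > 0) {
    stop("rollout plan exceeds available districts in region(s): ",
         paste(names(short), collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (reg in unique(plan$region)) {
    rows <- plan[plan$region == reg & plan$new_districts > 0, ]
    if (nrow(rows) == 0) next
    pool <- registry$district_id[registry$region == reg]
    used <- 0L
    for (i in seq_len(nrow(rows))) {
      k <- rows$new_districts[i]
      ids <- pool[(used + 1L):(used + k)]
      used <- used + k
      out[[length(out) + 1L]] <- tibble::tibble(
        district_id = ids, region = reg,
        start_period = rows$period[i],
        start_year = ceiling(rows$period[i] / 2))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(district_id = character(), region = character(),
                          start_period = integer(), start_year = numeric()))
  }
  sched <- do.call(rbind, out)
  if (anyDuplicated(sched$district_id)) {
    stop("a district may enter the rollout at most once", call. = FALSE)
  }
  sched
}

#' Cumulative active-district counts per rollout period
#'
#' @param plan Rollout plan tibble (`region`, `period`, `new_districts`).
#' @return Integer vector, one cumulative count per period.
#' @export
rollout_cumulative <- function(plan = reference_rollout_plan()) {
  per_period <- vapply(split(plan$new_districts, plan$period), sum, numeric(1))
  as.integer(cumsum(per_period[order(as.integer(names(per_period)))]))
}

#' Unit-cost basis implied by the reference rollout
#'
#' Aggregated 10-year item amounts resolve to per-district rates by dividing
#' by the number of participating districts (development and start-up: one-
#' time, 6 months each) and by the total implementation district-years
#' (implementation: recurrent). Under the reference plan these denominators
#' are 170 districts and 1,347 district-years (45 districts x 9 years +
#' 67 x 8 + 58 x 7 for the three annual cohorts over a 10-year horizon).
#'
#' @param plan Rollout plan tibble.
#' @param horizon_years Analytic horizon.
#' @return List with `n_districts` and `district_years`.
#' @export
reference_unit_basis <- function(plan = reference_rollout_plan(),
                                 horizon_years = 10) {
  per_year <- vapply(split(plan$new_districts, ceiling(plan$period / 2)),
                     sum, numeric(1))
  yrs <- as.integer(names(per_year))
  impl_years <- pmax(horizon_years - yrs, 0)
  list(n_districts = as.integer(sum(per_year)),
       district_years = as.integer(sum(per_year * impl_years)))
}

# Driver weight of a district relative to the anchor profile.
driver_weight <- function(driver, registry, anchor) {
  switch(driver,
    lump_total = ,
    per_district = rep(1, nrow(registry)),
    per_facility = (registry$n_chps + registry$n_health_centers) /
      (anchor$n_chps + anchor$n_health_centers),
    per_nurse = registry$n_nurses / anchor$n_nurses,
    per_enrollee_year = registry$population / anchor$population,
    stop(sprintf("unresolvable cost driver '%s'", driver), call. = FALSE)
  )
}

#' Build the district-by-year cost stream
#'
#' Resolves each ingredient to a fixed per-district (development, start-up)
#' or per-district-year (implementation) unit rate on the reference basis,
#' scales it by the district's driver weight relative to the anchor profile
#' (facility counts, nurse counts, or population), and lays it onto the
#' schedule: development and start-up fall in a district's first active
#' year (the first and second 6 months respectively), implementation in
#' every following year up to the horizon.
#'
#' @param items Cost-ingredient tibble (see [reference_cost_items()]).
#' @param schedule Rollout schedule from [expand_rollout()].
#' @param registry District registry covering every scheduled district.
#' @param horizon_years Analytic horizon (default 10).
#' @param anchor Anchor district profile for variable-cost scaling.
#' @param unit_basis Denominators resolving aggregated amounts to unit
#'   rates; default the reference basis (170 districts, 1,347
#'   district-years).
#' @param discount_rate Annual discount rate carried as an attribute.
#' @return Tibble `district_id`, `year`, `phase`, `usd_2014` of class
#'   `cost_stream`, with attributes `discount_rate` and `horizon_years`.
#' @export
compute_cost_stream <- function(items, schedule, registry,
                                horizon_years = 10,
                                anchor = gomoa_west_anchor(),
                                unit_basis = reference_unit_basis(horizon_years = horizon_years),
                                discount_rate = 0.03) {
  stopifnot(all(c("activity", "phase", "amount_2014usd", "driver") %in% names(items)))
  empty <- tibble::tibble(district_id = character(), year = integer(),
                          phase = character(), usd_2014 = numeric())
  if (nrow(schedule) == 0) {
    return(structure(empty, class = c("cost_stream", class(empty)),
                     discount_rate = discount_rate, horizon_years = horizon_years))
  }
  if (!all(schedule$district_id %in% registry$district_id)) {
    stop("schedule refers to districts missing from the registry", call. = FALSE)
  }
  reg <- registry[match(schedule$district_id, registry$district_id), ]
  if (any(items$amount_2014usd < 0)) stop("cost amounts must be >= 0", call. = FALSE)

  phase_amount <- function(ph) {
    sub <- items[items$phase == ph, ]
    if (nrow(sub) == 0) return(rep(0, nrow(schedule)))
    w <- vapply(sub$driver, driver_weight, numeric(nrow(schedule)),
                registry = reg, anchor = anchor)
    if (is.null(dim(w))) w <- matrix(w, nrow = nrow(schedule))
    denom <- if (ph == "implementation") unit_basis$district_years else unit_basis$n_districts
    as.numeric(w %*% (sub$amount_2014usd / denom))
  }

  rows <- list(
    tibble::tibble(district_id = schedule$district_id,
                   year = as.integer(schedule$start_year),
                   phase = "development", usd_2014 = phase_amount("development")),
    tibble::tibble(district_id = schedule$district_id,
                   year = as.integer(schedule$start_year),
                   phase = "start-up", usd_2014 = phase_amount("start-up"))
  )
  impl_rate <- phase_amount("implementation")
  for (i in seq_len(nrow(schedule))) {
    yrs <- seq_len(horizon_years)
    yrs <- yrs[yrs > schedule$start_year[i]]
    if (length(yrs) > 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        district_id = schedule$district_id[i], year = as.integer(yrs),
        phase = "implementation", usd_2014 = impl_rate[i])
    }
  }
  stream <- do.call(rbind, rows)
  stream <- stream[stream$usd_2014 > 0 | stream$phase == "implementation", ]
  stream <- stream[order(stream$district_id, stream$year, stream$phase), ]
  structure(stream, class = c("cost_stream", class(empty)),
            discount_rate = discount_rate, horizon_years = horizon_years)
}

#' Phase and activity cost shares
#'
#' Each activity's share of its phase subtotal, from the ingredient table.
#'
#' @param items Cost-ingredient tibble.
#' @return Tibble `phase`, `activity`, `amount_2014usd`, `phase_subtotal`,
#'   `share` (fraction of the phase subtotal).
#' @export
phase_shares <- function(items) {
  subtotal <- vapply(split(items$amount_2014usd, items$phase), sum, numeric(1))
  if (any(subtotal == 0)) {
    stop("phase subtotal is zero for: ",
         paste(names(subtotal)[subtotal == 0], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    phase = items$phase,
    activity = items$activity,
    amount_2014usd = items$amount_2014usd,
    phase_subtotal = unname(subtotal[items$phase]),
    share = unname(items$amount_2014usd / subtotal[items$phase])
  )
}

#' Per-district per-year phase subtotals on the reference basis
#'
#' Development and start-up subtotals divide by the participating-district
#' count; the implementation subtotal divides by total implementation
#' district-years. Their sum is the total annualized cost per district per
#' year.
#'
#' @param items Cost-ingredient tibble.
#' @param unit_basis See [reference_unit_basis()].
#' @return Named numeric: `development`, `start-up`, `implementation`,
#'   `total`.
#' @export
per_district_annual_cost <- function(items, unit_basis = reference_unit_basis()) {
  subtotal <- vapply(split(items$amount_2014usd, items$phase), sum, numeric(1))
  out <- c(
    "development" = unname(subtotal["development"] / unit_basis$n_districts),
    "start-up" = unname(subtotal["start-up"] / unit_basis$n_districts),
    "implementation" = unname(subtotal["implementation"] / unit_basis$district_years)
  )
  c(out, total = sum(out))
}
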