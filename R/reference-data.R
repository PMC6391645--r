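#' The ten regions used by the national rollout plan
#'
#' Region names in the order they appear in the reference rollout plan.
#'
#' @return Character vector of length 10.
#' @export
ghana_regions <- function() {
  c("Western", "Central", "Greater Accra", "Volta", "Eastern",
    "Ashanti", "Brong-Ahafo", "Northern", "Upper East", "Upper West")
}

#' Gomoa West anchor district profile
#'
#' The district whose field data anchor the whole forecast: a semirural
#' coastal district of the Central Region with 135,139 residents served by
#' 17 CHPS facilities (1 per 7,949 population), 4 health centers
#' (1 per 33,785 population) and 1 district hospital. Variable program
#' costs scale against this profile, and the synthetic district generator
#' draws registries around its facility-to-population ratios.
#'
#' The nurse count and crude birth rate are not published at district level;
#' the defaults here (3 nurses per CHPS + 8 per health center; 30 births per
#' 1,000 population per year) are field-typical and configurable.
#'
#' @param n_nurses Nurse count for the anchor district.
#' @param crude_birth_rate Births per 1,000 population per year.
#' @return A one-row tibble with the district registry columns.
#' @export
gomoa_west_anchor <- function(n_nurses = 83, crude_birth_rate = 30) {
  tibble::tibble(
    district_id = "gomoa_west",
    region = "Central",
    population = 135139,
    n_chps = 17L,
    n_health_centers = 4L,
    n_hospitals = 1L,
    n_nurses = as.integer(n_nurses),
    crude_birth_rate = crude_birth_rate
  )
}

#' Reference program cost ingredients
#'
#' The ingredients-based cost table for the national scale-up: one row per
#' activity, grouped into the three program phases (development and start-up,
#' 6 months each per district and treated as one-time capital investments;
#' implementation, recurrent). Amounts are aggregated 10-year totals in 2014
#' USD for the 170-district reference rollout.
#'
#' The development-phase line items sum to 674,142 while the phase subtotal
#' is 698,647; the 24,505 residual is carried as an explicit "Unallocated
#' balance" row so that phase totals reconcile.
#'
#' `driver` marks how an item scales across districts: `per_district` (flat),
#' `per_facility` (proportional to CHPS + health-center counts relative to
#' the anchor district), `per_nurse`, `per_enrollee_year` (proportional to
#' population), or `lump_total` (central lump spread evenly over
#' participating districts).
#'
#' @return Tibble with columns `activity`, `phase`, `level`,
#'   `amount_2014usd`, `driver`, `capital`, `lifespan_years`.
#' @export
reference_cost_items <- function() {
  tribble_row <- function(activity, phase, level, amount, driver,
                          capital = FALSE, lifespan = NA_real_) {
    tibble::tibble(activity = activity, phase = phase, level = level,
                   amount_2014usd = amount, driver = driver,
                   capital = capital, lifespan_years = lifespan)
  }
  dev <- rbind(
    tribble_row("Program design", "development", "central", 36800, "lump_total", TRUE, 10),
    tribble_row("Telecommunications", "development", "central", 23480, "lump_total", TRUE, 10),
    tribble_row("Technology", "development", "central", 16907, "lump_total", TRUE, 10),
    tribble_row("Personnel", "development", "central", 596955, "lump_total", TRUE, 10),
    tribble_row("Unallocated balance", "development", "central", 24505, "lump_total", TRUE, 10)
  )
  su <- rbind(
    tribble_row("District profiling", "start-up", "district", 150919, "per_district", TRUE, 10),
    tribble_row("Content localization", "start-up", "central", 30690, "lump_total", TRUE, 10),
    tribble_row("Equipment", "start-up", "district", 2471799, "per_facility", TRUE, 10),
    tribble_row("Customer support", "start-up", "central", 249746, "lump_total", TRUE, 10),
    tribble_row("Training", "start-up", "district", 2406578, "per_facility", TRUE, 10),
    tribble_row("Community mobilization", "start-up", "district", 627638, "per_district", TRUE, 10),
    tribble_row("Partnership building", "start-up", "regional", 10449, "per_district", TRUE, 10),
    tribble_row("Vehicle maintenance", "start-up", "district", 172082, "per_district", TRUE, 10),
    tribble_row("Office maintenance", "start-up", "central", 86277, "lump_total", TRUE, 10),
    tribble_row("Telecommunications", "start-up", "district", 77166, "per_enrollee_year", TRUE, 10),
    tribble_row("Technology", "start-up", "central", 26318, "lump_total", TRUE, 10),
    tribble_row("Personnel & benefits", "start-up", "district", 1193847, "per_district", TRUE, 10)
  )
  impl <- rbind(
    tribble_row("Technical groups", "implementation", "district", 17810, "per_district"),
    tribble_row("Monitoring and evaluation", "implementation", "district", 1700567, "per_district"),
    tribble_row("Continued training", "implementation", "district", 2140605, "per_facility"),
    tribble_row("Equipment & materials", "implementation", "district", 4928480, "per_facility", TRUE, 3),
    tribble_row("Vehicle maintenance", "implementation", "district", 1078131, "per_district"),
    tribble_row("Field office maintenance", "implementation", "district", 209521, "per_district"),
    tribble_row("Office maintenance", "implementation", "central", 257036, "lump_total"),
    tribble_row("Telecommunications", "implementation", "district", 2343275, "per_enrollee_year"),
    tribble_row("Technology maintenance", "implementation", "central", 241582, "lump_total"),
    tribble_row("Personnel & benefits", "implementation", "district", 11218454, "per_district")
  )
  tibble::as_tibble(rbind(dev, su, impl))
}

#' Reference three-year rollout plan
#'
#' New districts starting the program per region and half-year period
#' (periods 1..6 over three calendar years). Column sums give 15, 30, 39,
#' 28, 31 and 27 new districts per period; the cumulative active counts are
#' 15, 45, 84, 112, 143 and 170.
#'
#' @return Tibble with columns `region`, `period` (1..6), `new_districts`.
#' @export
reference_rollout_plan <- function() {
  counts <- rbind(
    Western          = c(5, 5, 7, 0, 0, 0),
    Central          = c(5, 5, 7, 0, 0, 0),
    `Greater Accra`  = c(5, 5, 0, 0, 0, 0),
    Volta            = c(0, 5, 5, 8, 0, 0),
    Eastern          = c(0, 5, 5, 5, 6, 0),
    Ashanti          = c(0, 5, 5, 5, 5, 7),
    `Brong-Ahafo`    = c(0, 0, 5, 5, 5, 7),
    Northern         = c(0, 0, 5, 5, 5, 5),
    `Upper East`     = c(0, 0, 0, 0, 5, 4),
    `Upper West`     = c(0, 0, 0, 0, 5, 4)
  )
  tibble::tibble(
    region = rep(rownames(counts), each = ncol(counts)),
    period = rep(seq_len(ncol(counts)), times = nrow(counts)),
    new_districts = as.integer(t(counts))
  )
}

#' Headline effect anchors for the reference configuration
#'
#' Ten-year deaths-averted totals per outcome (used as calibration anchors
#' for the lives-saved engine) and the Year-2 per-outcome components, as
#' carried in the reference configuration.
#'
#' @return List with `total_averted` (named numeric: maternal, child,
#'   stillbirth) and `year2_averted` (named numeric).
#' @export
reference_headline_effects <- function() {
  list(
    total_averted = c(maternal = 6298, child = 33797, stillbirth = 19811),
    year2_averted = c(maternal = 43, child = 288, stillbirth = 152)
  )
}

#' Reference coverage-effect inputs
#'
#' Program-attributable coverage-point increases per intervention (endline
#' effect over the comparison arm) used by the reference configuration.
#'
#' @return Named numeric vector of percentage points.
#' @export
reference_effects <- function() {
  c(sba = 11, facility_delivery = 10, measles = 6)
}

#' Synthetic monthly exchange-rate fixture (GHS per USD), 2012-2014
#'
#' The costing stage converts local-currency expenditures with
#' month-appropriate market exchange rates. The sources are cited but the
#' rates are not printed, so this synthetic fixture carries a plausible
#' monotone depreciation path for the Ghana cedi over 2012-2014.
#'
#' @return Tibble with columns `month` ("YYYY-MM") and `rate` (> 0).
#' @export
synthetic_fx_table <- function() {
  months <- sprintf("%d-%02d", rep(2012:2014, each = 12), rep(1:12, 3))
  rate <- round(seq(1.65, 3.20, length.out = length(months)), 3)
  tibble::tibble(month = months, rate = rate)
}

#' Synthetic annual CPI fixture with 2014 base, 2012-2014
#'
#' Consumer price index used to express all costs in 2014 USD; the 2014
#' entry defines the base (ratio 1 for 2014). Index levels are synthetic
#' (the study cites the CPI source without printing values).
#'
#' @return Tibble with columns `year` and `index` (> 0).
#' @export
synthetic_cpi_table <- function() {
  tibble::tibble(year = 2012:2014, index = c(87.6, 97.8, 113.2))
}
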