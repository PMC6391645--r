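#' Step-rate factor for the coverage breakpoints
#'
#' Coverage gains attenuate as coverage saturates: the annual increment
#' applies in full while start-of-year coverage is at or below 75%, at half
#' rate once coverage has surpassed 75%, and at quarter rate from 90%
#' upward; no intervention's coverage may exceed 99%.
#'
#' @param coverage Start-of-year coverage percent.
#' @return 1, 0.5 or 0.25.
#' @keywords internal
attenuation_factor <- function(coverage) {
  ifelse(coverage <= 75, 1, ifelse(coverage < 90, 0.5, 0.25))
}

# One-year-at-a-time stepping with per-year increments.
step_coverage <- function(baseline, increments) {
  cov <- baseline
  out <- numeric(length(increments))
  for (i in seq_along(increments)) {
    cov <- min(99, cov + increments[i] * attenuation_factor(cov))
    out[i] <- cov
  }
  out
}

#' Project an intervention's coverage trajectory
#'
#' Steps coverage forward one program year at a time from `baseline`,
#' applying a constant annual increment attenuated at the 75% and 90%
#' breakpoints (keyed to start-of-year coverage) and capped at 99%.
#'
#' @param baseline Baseline coverage percent in `[0, 100]`.
#' @param increment Annual increase in percentage points (>= 0; coverage
#'   decline is not modelled).
#' @param years Number of program years to project.
#' @param intervention Optional label.
#' @return Object of class `coverage_trajectory`: `intervention`,
#'   `baseline`, `annual_increment`, `values` (percent per program year).
#' @export
project_coverage <- function(baseline, increment, years,
                             intervention = NA_character_) {
  if (baseline < 0 || baseline > 100) {
    stop("`baseline` must lie in [0, 100]", call. = FALSE)
  }
  if (increment < 0) stop("negative increments are not modelled", call. = FALSE)
  stopifnot(years >= 1)
  structure(
    list(intervention = intervention, baseline = baseline,
         annual_increment = increment,
         values = step_coverage(min(baseline, 99), rep(increment, years))),
    class = "coverage_trajectory"
  )
}

#' @export
print.coverage_trajectory <- function(x, ...) {
  cat(sprintf("Coverage trajectory%s: baseline %.1f%%, +%.2f pp/yr\n",
              if (is.na(x$intervention)) "" else paste0(" [", x$intervention, "]"),
              x$baseline, x$annual_increment))
  print(round(x$values, 2))
  invisible(x)
}

#' District-by-year coverage table under the rollout
#'
#' Builds per-district trajectories for every intervention. A district's
#' coverage stays at baseline through its first active year (gains lag the
#' development/start-up period; no lives are saved in a district's first
#' year) and then ramps: the program-attributable effect is spread linearly
#' over `ramp_years` years of increments, each passed through the
#' breakpoint attenuation and 99% cap.
#'
#' @param schedule Rollout schedule from [expand_rollout()].
#' @param baselines Named baseline coverage percents per intervention.
#' @param effects Named total coverage-point effects per intervention
#'   (e.g. `c(sba = 11, facility_delivery = 10, measles = 6)`).
#' @param horizon_years Analytic horizon.
#' @param ramp_years Years over which each effect is spread (default 2).
#' @return Tibble `district_id`, `year`, `intervention`, `percent`.
#' @export
coverage_table <- function(schedule, baselines, effects, horizon_years = 10,
                           ramp_years = 2) {
  stopifnot(all(names(effects) %in% names(baselines)), ramp_years >= 1)
  if (any(effects < 0)) stop("negative effects are not modelled", call. = FALSE)
  start_years <- sort(unique(schedule$start_year))
  out <- list()
  for (iv in names(effects)) {
    base <- baselines[[iv]]
    per_start <- lapply(start_years, function(s) {
      inc <- numeric(horizon_years)
      ramp <- seq.int(s + 1, length.out = ramp_years)
      ramp <- ramp[ramp <= horizon_years]
      inc[ramp] <- effects[[iv]] / ramp_years
      step_coverage(min(base, 99), inc)
    })
    names(per_start) <- start_years
    for (i in seq_len(nrow(schedule))) {
      out[[length(out) + 1L]] <- tibble::tibble(
        district_id = schedule$district_id[i],
        year = seq_len(horizon_years),
        intervention = iv,
        percent = per_start[[as.character(schedule$start_year[i])]])
    }
  }
  do.call(rbind, out)
}
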