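test_that("no coverage gain averts no deaths", {
  reg <- anchor_registry(2)
  env <- mortality_envelope(reg, horizon_years = 3)
  sched <- tibble::tibble(district_id = reg$district_id, region = reg$region,
                          start_period = 1L, start_year = 1)
  cv <- coverage_table(sched, c(sba = 70, facility_delivery = 57, measles = 85),
                       c(sba = 0, facility_delivery = 0, measles = 0),
                       horizon_years = 3)
  av <- deaths_averted(env, default_effectiveness(), cv,
                       c(sba = 70, facility_delivery = 57, measles = 85))
  expect_equal(sum(av$averted), 0)
  imp <- aggregate_impact(av)
  expect_equal(imp$total_dalys, 0) # no deaths averted, no DALYs
})

test_that("the attributable-risk formula matches hand arithmetic", {
  # 1000 deaths, efficacy 0.5, affected 0.8, coverage 20 -> 40:
  # 1000 * 0.8 * 0.5 * 0.20 / (1 - 0.5*0.20) = 88.9
  reg <- anchor_registry(1)
  env <- tibble::tibble(district_id = "D001", year = 1, live_births = 0,
                        maternal = 1000, child = 0, stillbirth = 0)
  eff <- tibble::tibble(intervention = "sba", outcome = "maternal",
                        efficacy = 0.5, affected_fraction = 0.8, scale = 1)
  cv <- tibble::tibble(district_id = "D001", year = 1, intervention = "sba",
                       percent = 40)
  av <- deaths_averted(env, eff, cv, c(sba = 20))
  expect_equal(av$averted, 88.9, tolerance = 1e-3)

  # full-protection limit: efficacy 1, affected 1, coverage 0 -> 100
  eff2 <- eff
  eff2$efficacy <- 1
  eff2$affected_fraction <- 1
  cv2 <- cv
  cv2$percent <- 100
  expect_equal(deaths_averted(env, eff2, cv2, c(sba = 0))$averted, 1000)

  # degenerate denominator rejected
  expect_error(deaths_averted(env, eff2, cv2, c(sba = 100)), ">= 100")
})

test_that("discounted years of life lost follow the closed form", {
  expect_equal(yll(10, 40, 0), 400) # undiscounted limit
  expect_equal(yll(1, 65.5, 0.03), 28.66, tolerance = 0.01 / 28.66)
  expect_equal(yll(0, 65.5, 0.03), 0)
  expect_equal(yll(7, 65.5, 0.03), 7 * yll(1, 65.5, 0.03))
})

test_that("impact aggregation is additive across districts", {
  reg <- anchor_registry(3)
  env <- mortality_envelope(reg, horizon_years = 4)
  sched <- tibble::tibble(district_id = reg$district_id, region = reg$region,
                          start_period = 1L, start_year = 1)
  bl <- c(sba = 70, facility_delivery = 57, measles = 85)
  cv <- coverage_table(sched, bl, reference_effects(), horizon_years = 4)
  av <- deaths_averted(env, default_effectiveness(), cv, bl)
  nat <- aggregate_impact(av)
  one <- aggregate_impact(av[av$district_id == "D001", ])
  # identical districts: national = 3x single district
  expect_equal(nat$total_deaths, 3 * one$total_deaths)
  expect_equal(nat$total_dalys, 3 * one$total_dalys)
  # a single district, single year aggregates to itself
  a1 <- av[av$district_id == "D001" & av$year == 2, ]
  expect_equal(aggregate_impact(a1)$total_deaths, sum(a1$averted))
})

test_that("deaths averted are monotone in efficacy", {
  reg <- anchor_registry(2)
  env <- mortality_envelope(reg, horizon_years = 3)
  sched <- tibble::tibble(district_id = reg$district_id, region = reg$region,
                          start_period = 1L, start_year = 1)
  bl <- c(sba = 70, facility_delivery = 57, measles = 85)
  cv <- coverage_table(sched, bl, reference_effects(), horizon_years = 3)
  eff <- default_effectiveness()
  base_total <- sum(deaths_averted(env, eff, cv, bl)$averted)
  for (k in seq_len(nrow(eff))) {
    up <- eff
    up$efficacy[k] <- min(1, up$efficacy[k] + 0.1)
    expect_gte(sum(deaths_averted(env, up, cv, bl)$averted), base_total)
  }
})

test_that("calibration aligns 10-year totals with the anchors exactly", {
  run <- reference_run()
  expect_equal(unname(run$impact$totals[c("maternal", "child", "stillbirth")]),
               unname(reference_headline_effects()$total_averted
                      [c("maternal", "child", "stillbirth")]))
  # fractions stay within [0,1]; any anchor excess sits in the scale column
  expect_true(all(run$effectiveness$affected_fraction <= 1))
  expect_true(all(run$effectiveness$affected_fraction >= 0))
  expect_true(all(run$effectiveness$scale >= 1))
})

test_that("DALYs per averted death sit in the expected bracket", {
  run <- reference_run()
  per_death <- run$impact$total_dalys / run$impact$total_deaths
  expect_gt(per_death, 22)
  expect_lt(per_death, 29)
  # child/stillbirth YLL per death is 28.66; maternal lower (shorter L)
  by <- run$impact$by_year
  m <- by[by$outcome == "maternal" & by$deaths_averted > 0, ]
  expect_equal(m$dalys / m$deaths_averted,
               rep(yll(1, 36.5, 0.03), nrow(m)))
})
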