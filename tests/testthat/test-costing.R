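test_that("currency conversion and CPI adjustment follow the stated rule", {
  fx <- tibble::tibble(month = c("2013-06", "2014-06"), rate = c(2.0, 3.0))
  cpi <- tibble::tibble(year = 2013:2014, index = c(100, 110))
  # USD in the base year is unchanged
  expect_equal(adjust_to_base_year(250, "2014-06", fx, cpi, currency = "USD"), 250)
  # 100 local / 2.0 fx * 1.10 cpi ratio = 55
  expect_equal(adjust_to_base_year(100, "2013-06", fx, cpi), 55)
  expect_error(adjust_to_base_year(100, "2013-07", fx, cpi), "no entry for month")
  expect_error(adjust_to_base_year(100, "2011-06", fx, cpi), "no entry for year")
})

test_that("annualization reproduces the annuity factor and its limits", {
  expect_equal(annualize(1000, 10, 0), 100)
  expect_equal(annualize(1000, 10, 0.03), 117.23, tolerance = 0.01 / 117.23)
  # one-year lifespan: amount * r / (1 - (1+r)^-1) = amount * (1+r)
  expect_equal(annualize(500, 1, 0.03), 500 * 1.03)
})

test_that("the reference plan expands to the printed cumulative counts", {
  expect_identical(rollout_cumulative(), c(15L, 45L, 84L, 112L, 143L, 170L))
  reg <- generate_districts(216, seed = 1)
  sched <- expand_rollout(reference_rollout_plan(), reg)
  expect_equal(nrow(sched), 170)
  expect_false(anyDuplicated(sched$district_id) > 0)
  active <- vapply(1:6, function(p) sum(sched$start_period <= p), integer(1))
  expect_identical(active, c(15L, 45L, 84L, 112L, 143L, 170L))
  # the three annual cohorts imply 45*9 + 67*8 + 58*7 implementation years
  expect_identical(reference_unit_basis()$district_years, 1347L)
})

test_that("an empty plan gives an empty schedule; an oversized plan errors", {
  empty <- reference_rollout_plan()
  empty$new_districts <- 0L
  reg <- anchor_registry(10)
  expect_equal(nrow(expand_rollout(empty, reg)), 0)
  small <- anchor_registry(3, regions = rep("Western", 3))
  expect_error(expand_rollout(reference_rollout_plan(), small), "exceeds")
})

test_that("the cost stream conserves totals under the reference schedule", {
  reg <- anchor_registry(216) # every district equals the anchor: weights 1
  sched <- expand_rollout(reference_rollout_plan(), reg)
  cs <- compute_cost_stream(reference_cost_items(), sched, reg)
  expect_equal(sum(cs$usd_2014), sum(reference_cost_items()$amount_2014usd),
               tolerance = 1 / 32e6)
  # development/start-up only in a district's first active year
  first <- cs[cs$phase != "implementation", ]
  starts <- sched$start_year[match(first$district_id, sched$district_id)]
  expect_true(all(first$year == starts))
  # implementation strictly after the first year
  impl <- cs[cs$phase == "implementation", ]
  starts_i <- sched$start_year[match(impl$district_id, sched$district_id)]
  expect_true(all(impl$year > starts_i))
})

test_that("the cost stream is monotone in the schedule and scale-equivariant", {
  reg <- anchor_registry(8, regions = rep("Western", 8))
  plan <- tibble::tibble(region = "Western", period = c(1, 3),
                         new_districts = c(2L, 1L))
  sched <- expand_rollout(plan, reg)
  cs <- compute_cost_stream(toy_items(), sched, reg)

  plan2 <- tibble::tibble(region = "Western", period = c(1, 3),
                          new_districts = c(2L, 2L))
  cs2 <- compute_cost_stream(toy_items(), expand_rollout(plan2, reg), reg)
  y1 <- vapply(1:10, function(y) sum(cs$usd_2014[cs$year == y]), numeric(1))
  y2 <- vapply(1:10, function(y) sum(cs2$usd_2014[cs2$year == y]), numeric(1))
  expect_true(all(y2 >= y1))

  doubled <- toy_items()
  doubled$amount_2014usd <- doubled$amount_2014usd * 2
  cs_d <- compute_cost_stream(doubled, sched, reg)
  expect_equal(cs_d$usd_2014, cs$usd_2014 * 2)

  empty_sched <- expand_rollout(plan[0, ], reg)
  cs_e <- compute_cost_stream(toy_items(), empty_sched, reg)
  expect_equal(sum(cs_e$usd_2014), 0)
})

test_that("variable items scale with facility counts relative to the anchor", {
  reg <- anchor_registry(2, regions = rep("Western", 2))
  reg$n_chps[2] <- 34L
  reg$n_health_centers[2] <- 8L # doubled facilities -> weight 2
  plan <- tibble::tibble(region = "Western", period = 1, new_districts = 2L)
  sched <- expand_rollout(plan, reg)
  cs <- compute_cost_stream(toy_items(), sched, reg)
  su <- cs[cs$phase == "start-up", ]
  expect_equal(su$usd_2014[su$district_id == "D002"],
               2 * su$usd_2014[su$district_id == "D001"])
})

test_that("phase and activity shares reproduce the printed cost drivers", {
  shares <- phase_shares(reference_cost_items())
  pick <- function(ph, act) shares$share[shares$phase == ph & shares$activity == act]
  expect_equal(pick("implementation", "Personnel & benefits"),
               11218454 / 24135461)
  expect_equal(round(100 * pick("development", "Personnel")), 85)
  expect_equal(round(100 * pick("implementation", "Equipment & materials")), 20)
  # single-item phase is 100% of itself
  one <- tibble::tibble(activity = "X", phase = "implementation", level = "d",
                        amount_2014usd = 5, driver = "per_district",
                        capital = FALSE, lifespan_years = NA)
  expect_equal(phase_shares(one)$share, 1)
  one$amount_2014usd <- 0
  expect_error(phase_shares(one), "zero")
})

test_that("per-district annual subtotals divide by the reference basis", {
  pd <- per_district_annual_cost(reference_cost_items())
  expect_equal(round(pd[["development"]]), 4110)
  expect_equal(round(pd[["start-up"]]), 44138)
  expect_equal(round(pd[["implementation"]]), 17918)
  expect_equal(round(pd[["total"]]), 66166)
})
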