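toy_model <- function() {
  items <- toy_items()
  impact <- structure(list(
    by_year = tibble::tibble(year = 1, outcome = c("child", "maternal"),
                             deaths_averted = c(100, 10),
                             dalys = c(100 * yll(1, 65.5, 0.03),
                                       10 * yll(1, 36.5, 0.03))),
    totals = c(child = 100, maternal = 10),
    total_deaths = 110,
    total_dalys = 100 * yll(1, 65.5, 0.03) + 10 * yll(1, 36.5, 0.03),
    params = list(r = 0.03, life_expectancy = 65.5, maternal_remaining = 36.5,
                  include_stillbirths = TRUE)), class = "impact_result")
  make_reference_model(items, impact)
}

test_that("the reduced-form model reproduces its deterministic inputs", {
  m <- toy_model()
  v <- m()
  expect_equal(unname(v["cost"]), sum(toy_items()$amount_2014usd))
  expect_equal(unname(v["dalys"]),
               100 * yll(1, 65.5, 0.03) + 10 * yll(1, 36.5, 0.03))
  expect_equal(unname(v["deaths"]), 110)
})

test_that("tornado entries rank by span with deterministic tie-breaks", {
  m <- toy_model()
  specs <- default_parameter_specs(m)
  # a parameter the model ignores spans zero and ranks last
  specs2 <- rbind(specs, parameter_spec("zzz ignored", 0, "fixed",
                                        low = 0, high = 0))
  t <- one_way(m, specs2)
  expect_equal(t$name[nrow(t)], "zzz ignored")
  expect_equal(t$span[nrow(t)], 0)
  expect_true(all(diff(t$span) <= 1e-12))
  # ordering is invariant to the listing order of the specs
  t2 <- one_way(m, specs2[rev(seq_len(nrow(specs2))), ])
  expect_equal(t$name, t2$name)
  # two parameters with identical spans order alphabetically
  s <- rbind(parameter_spec("b dup", 1700, low = 1360, high = 2040),
             parameter_spec("a dup", 1700, low = 1360, high = 2040))
  td <- one_way(m, s)
  expect_equal(td$name, c("a dup", "b dup"))
})

test_that("health-effect parameters dominate the reference tornado", {
  run <- reference_run()
  t <- run$tornado
  cost_rows <- grep("^cost:", t$name)
  # the largest lives-saved drivers sit at the top ...
  expect_true(all(c("lives saved: child", "lives saved: stillbirth") %in%
                    t$name[1:3]))
  # ... and implementation personnel is the highest-ranked cost parameter
  expect_equal(t$name[min(cost_rows)],
               "cost: implementation/Personnel & benefits")
  expect_lte(min(cost_rows), 4)
})

test_that("an all-fixed PSA reproduces the deterministic run exactly", {
  m <- toy_model()
  pars <- attr(m, "parameters")
  specs <- do.call(rbind, lapply(seq_len(nrow(pars)), function(i) {
    parameter_spec(pars$name[i], pars$base[i], "fixed")
  }))
  psa <- run_psa(m, specs, n_iter = 20, seed = 3)
  det <- m()
  expect_true(all(psa$draws$incremental_cost == det[["cost"]]))
  expect_true(all(psa$draws$dalys_averted == det[["dalys"]]))
  expect_equal(psa$icer_mean, det[["cost"]] / det[["dalys"]])
})

test_that("PSA draws are reproducible under a fixed seed", {
  m <- toy_model()
  specs <- default_parameter_specs(m)
  a <- run_psa(m, specs, n_iter = 100, seed = 7)
  b <- run_psa(m, specs, n_iter = 100, seed = 7)
  expect_identical(a$draws, b$draws)
  c <- run_psa(m, specs, n_iter = 100, seed = 8)
  expect_false(identical(a$draws, c$draws))
})

test_that("PSA mean cost converges to the deterministic cost", {
  m <- toy_model()
  pars <- attr(m, "parameters")
  # symmetric +/-10% normals on the cost items only
  specs <- do.call(rbind, lapply(seq_len(nrow(pars)), function(i) {
    if (pars$kind[i] == "cost") {
      parameter_spec(pars$name[i], pars$base[i], "normal",
                     sd = 0.1 * pars$base[i])
    } else {
      parameter_spec(pars$name[i], pars$base[i], "fixed")
    }
  }))
  det_cost <- m()[["cost"]]
  for (s in 1:20) {
    psa <- run_psa(m, specs, n_iter = 1000, seed = s)
    expect_lt(abs(psa$mean_cost - det_cost) / det_cost, 0.01)
  }
})

test_that("the CEAC counts net-monetary-benefit wins and is monotone", {
  draws <- tibble::tibble(
    iteration = 1:5,
    incremental_cost = c(10, 10, 30, 5, 50),
    dalys_averted = c(1, 2, 1, 1, 1),
    deaths_averted = 1)
  # brute-force NMB count at lambda = 10: draws 1, 2, 4 win -> 3/5
  cc <- ceac(draws, c(0, 10, 1e6))
  expect_equal(cc$probability[cc$wtp == 10], 0.6)
  expect_equal(cc$probability[cc$wtp == 0], 0) # all-positive costs
  expect_equal(cc$probability[cc$wtp == 1e6], 1) # large-lambda limit
  expect_true(all(diff(cc$probability) >= 0))
  expect_error(ceac(draws, numeric(0)), "empty")
})

test_that("the CE plane buckets draws into signed quadrants", {
  draws <- tibble::tibble(iteration = 1:3,
                          incremental_cost = c(5, -2, 3),
                          dalys_averted = c(1, 2, -1),
                          deaths_averted = 0)
  q <- ce_plane(draws)
  expect_equal(q$n[q$quadrant == "NE"], 1L)
  expect_equal(q$n[q$quadrant == "SE"], 1L) # negative cost, positive effect
  expect_equal(q$n[q$quadrant == "NW"], 1L)

  set.seed(99)
  sym <- tibble::tibble(iteration = 1:10000,
                        incremental_cost = rnorm(10000),
                        dalys_averted = rnorm(10000),
                        deaths_averted = 0)
  qs <- ce_plane(sym)
  expect_true(all(abs(qs$fraction - 0.25) < 0.02)) # binomial check at n = 10,000
})
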