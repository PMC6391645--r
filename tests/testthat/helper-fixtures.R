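# Shared fixtures, built in code.

# Registry of n districts identical to the anchor profile (driver weights 1).
anchor_registry <- function(n, regions = NULL) {
  a <- gomoa_west_anchor()
  out <- a[rep(1, n), ]
  out$district_id <- sprintf("D%03d", seq_len(n))
  out$region <- if (is.null(regions)) {
    # regional quotas of the reference plan first, any surplus cycling
    plan <- reference_rollout_plan()
    need <- vapply(split(plan$new_districts, plan$region), sum, numeric(1))
    need <- need[ghana_regions()]
    base <- rep(names(need), times = pmin(need, n))
    c(base, rep(ghana_regions(), length.out = max(0, n - length(base))))[seq_len(n)]
  } else {
    regions
  }
  out
}

# A tiny two-phase item table for structural costing tests.
toy_items <- function() {
  tibble::tibble(
    activity = c("Design", "Kit", "Ops"),
    phase = c("development", "start-up", "implementation"),
    level = c("central", "district", "district"),
    amount_2014usd = c(1700, 3400, 13470),
    driver = c("lump_total", "per_facility", "per_district"),
    capital = c(TRUE, TRUE, FALSE),
    lifespan_years = c(10, 10, NA)
  )
}

# Reference pipeline run, computed once per test session.
.ref_cache <- new.env(parent = emptyenv())
reference_run <- function() {
  if (is.null(.ref_cache$run)) {
    .ref_cache$run <- run_pipeline(default_config(),
                                   out_dir = file.path(tempdir(), "refrun"))
  }
  .ref_cache$run
}
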