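#' Generate a synthetic district registry
#'
#' Draws `n` districts whose facility counts match, in expectation, the
#' anchor district's population-per-CHPS and population-per-health-center
#' ratios. Populations are drawn log-normally around the anchor mean
#' (district size distributions are right-skewed and must stay positive);
#' facility counts are Poisson with mean population/ratio, with at least one
#' CHPS facility per district (a district cannot enter the rollout without
#' one). With `pop_sdlog = 0` the generator is degenerate and every district
#' reproduces the anchor profile exactly.
#'
#' Regions are assigned deterministically, with district counts allocated
#' across the ten regions proportionally to the reference rollout plan's
#' regional totals (largest-remainder rounding), so that any plan scaled
#' within those totals is feasible.
#'
#' @param n Number of districts (>= 1).
#' @param seed Integer seed; the registry is reproduced bit-for-bit for the
#'   same seed and parameters.
#' @param anchor One-row district profile supplying the mean ratios; see
#'   [gomoa_west_anchor()].
#' @param pop_sdlog Log-scale standard deviation of district populations.
#' @return Tibble of districts (`district_id`, `region`, `population`,
#'   `n_chps`, `n_health_centers`, `n_hospitals`, `n_nurses`,
#'   `crude_birth_rate`).
#' @export
generate_districts <- function(n, seed = 1, anchor = gomoa_west_anchor(),
                               pop_sdlog = 0.5) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a single positive count", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(anchor$population > 0, anchor$n_chps >= 1)
  set.seed(seed)

  ratio_chps <- anchor$population / anchor$n_chps
  ratio_hc <- anchor$population / anchor$n_health_centers
  ratio_hosp <- anchor$population / max(anchor$n_hospitals, 1L)
  nurses_per_facility <- anchor$n_nurses / (anchor$n_chps + anchor$n_health_centers)

  if (pop_sdlog == 0) {
    population <- rep(anchor$population, n)
    n_chps <- rep(as.integer(round(anchor$population / ratio_chps)), n)
    n_hc <- rep(as.integer(round(anchor$population / ratio_hc)), n)
    n_hosp <- rep(anchor$n_hospitals, n)
    n_nurses <- rep(anchor$n_nurses, n)
  } else {
    meanlog <- log(anchor$population) - pop_sdlog^2 / 2
    population <- round(stats::rlnorm(n, meanlog = meanlog, sdlog = pop_sdlog))
    population <- pmax(population, 1000)
    n_chps <- pmax(1L, stats::rpois(n, population / ratio_chps))
    n_hc <- stats::rpois(n, population / ratio_hc)
    n_hosp <- stats::rpois(n, population / ratio_hosp)
    n_nurses <- stats::rpois(n, nurses_per_facility * (n_chps + n_hc))
  }

  tibble::tibble(
    district_id = sprintf("D%03d", seq_len(n)),
    region = assign_regions(n),
    population = as.numeric(population),
    n_chps = as.integer(n_chps),
    n_health_centers = as.integer(n_hc),
    n_hospitals = as.integer(n_hosp),
    n_nurses = as.integer(n_nurses),
    crude_birth_rate = anchor$crude_birth_rate
  )
}

# Largest-remainder allocation of n districts across the 10 regions,
# proportional to the reference plan's regional totals.
assign_regions <- function(n) {
  plan <- reference_rollout_plan()
  totals <- vapply(split(plan$new_districts, plan$region), sum, numeric(1))
  totals <- totals[ghana_regions()] # keep plan order
  quota <- n * totals / sum(totals)
  alloc <- floor(quota)
  rem <- n - sum(alloc)
  if (rem > 0) {
    extra <- order(quota - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  rep(ghana_regions(), times = alloc)
}

#' Generate synthetic exit-interview records with an embedded treatment effect
#'
#' Stands in for the field evaluation's endline exit interviews. Five
#' covariates (education, employment, marital status, age, income) enter a
#' shared linear index that drives both treatment assignment and baseline
#' outcome probabilities, so the data are confounded by construction and the
#' naive treated-minus-control gap does not equal the average treatment
#' effect on the treated. Conditional on covariates, the treated arm's
#' outcome probability exceeds control by exactly `true_effects` (clipped to
#' (0,1)), so the embedded ATT equals `true_effects`.
#'
#' @param n_per_arm Records per arm (treated and control each).
#' @param true_effects Named probability-point increases for `sba`,
#'   `facility_delivery`, `measles`.
#' @param seed Integer seed; byte-identical output for the same seed.
#' @param baselines Named baseline outcome probabilities (control arm at the
#'   index midpoint).
#' @param confounding Named vector: `treatment` is the index coefficient in
#'   the assignment logit, `outcome` the coefficient in the outcome logits.
#'   Set both to 0 for an unconfounded design.
#' @return Tibble of records (`record_id`, `treated`, covariates, one
#'   `outcome_*` column per intervention).
#' @export
generate_exit_interviews <- function(n_per_arm,
                                     true_effects = c(sba = 0.11,
                                                      facility_delivery = 0.10,
                                                      measles = 0.06),
                                     seed = 1,
                                     baselines = c(sba = 0.70,
                                                   facility_delivery = 0.57,
                                                   measles = 0.85),
                                     confounding = c(treatment = 0.8,
                                                     outcome = 0.5)) {
  if (n_per_arm < 1) stop("`n_per_arm` must be positive", call. = FALSE)
  interventions <- names(true_effects)
  if (is.null(interventions) || !all(interventions %in% names(baselines))) {
    stop("`true_effects` and `baselines` must share intervention names",
         call. = FALSE)
  }
  if (any(baselines < 0 | baselines > 1) ||
      any(baselines + true_effects < 0 | baselines + true_effects > 1)) {
    stop("baseline and baseline + effect probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  set.seed(seed)

  draw_chunk <- function(m) {
    education <- sample(0:3, m, replace = TRUE, prob = c(0.25, 0.35, 0.25, 0.15))
    employment <- stats::rbinom(m, 1, 0.5)
    marital_status <- sample(c("single", "married", "other"), m,
                             replace = TRUE, prob = c(0.3, 0.6, 0.1))
    age <- sample(15:49, m, replace = TRUE)
    income <- sample(1:5, m, replace = TRUE)
    z <- 0.45 * (education - 1.3) + 0.5 * employment +
      0.5 * (marital_status == "married") - 0.3 * (marital_status == "other") -
      0.02 * (age - 30) + 0.25 * (income - 3)
    treated <- stats::rbinom(m, 1, stats::plogis(confounding[["treatment"]] * z))
    tibble::tibble(education, employment, marital_status, age, income, z, treated)
  }

  # draw in chunks until both arms are filled, then truncate deterministically
  pool <- draw_chunk(4L * n_per_arm)
  while (sum(pool$treated == 1) < n_per_arm || sum(pool$treated == 0) < n_per_arm) {
    pool <- rbind(pool, draw_chunk(2L * n_per_arm))
  }
  keep <- c(which(pool$treated == 1)[seq_len(n_per_arm)],
            which(pool$treated == 0)[seq_len(n_per_arm)])
  pool <- pool[sort(keep), ]

  out <- tibble::tibble(
    record_id = sprintf("R%06d", seq_len(nrow(pool))),
    treated = pool$treated,
    education = pool$education,
    employment = pool$employment,
    marital_status = pool$marital_status,
    age = pool$age,
    income = pool$income
  )
  for (iv in interventions) {
    p <- stats::plogis(stats::qlogis(baselines[[iv]]) +
                         confounding[["outcome"]] * pool$z) +
      true_effects[[iv]] * pool$treated
    p <- pmin(pmax(p, 1e-3), 1 - 1e-3)
    out[[paste0("outcome_", iv)]] <- stats::rbinom(nrow(pool), 1, p)
  }
  out
}

#' Write all synthetic pipeline inputs to disk
#'
#' Writes `districts.csv`, `exit_interviews.csv`, `fx.csv` and `cpi.csv`
#' plus a `manifest.json` sidecar recording every generator parameter and
#' the seed.
#'
#' @param dir Output directory (created if missing).
#' @param n_districts,n_per_arm Sizes for the two generators.
#' @param seed Integer seed shared by both generators (offset internally so
#'   the streams are distinct).
#' @param ... Passed through to [generate_exit_interviews()].
#' @return Invisibly, the paths written.
#' @export
write_synthetic_inputs <- function(dir, n_districts = 216, n_per_arm = 5000,
                                   seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  districts <- generate_districts(n_districts, seed = seed)
  records <- generate_exit_interviews(n_per_arm, seed = seed + 1L, ...)
  paths <- c(
    districts = file.path(dir, "districts.csv"),
    exit_interviews = file.path(dir, "exit_interviews.csv"),
    fx = file.path(dir, "fx.csv"),
    cpi = file.path(dir, "cpi.csv"),
    manifest = file.path(dir, "synthesis_manifest.json")
  )
  utils::write.csv(districts, paths[["districts"]], row.names = FALSE)
  utils::write.csv(records, paths[["exit_interviews"]], row.names = FALSE)
  utils::write.csv(synthetic_fx_table(), paths[["fx"]], row.names = FALSE)
  utils::write.csv(synthetic_cpi_table(), paths[["cpi"]], row.names = FALSE)
  jsonlite::write_json(
    list(n_districts = n_districts, n_per_arm = n_per_arm, seed = seed,
         generator = "mhealthcea", extra = list(...)),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
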