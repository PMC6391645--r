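utils::globalVariables(c("dalys_averted", "incremental_cost", "wtp",
                         "probability", "name", "icer_low", "icer_high",
                         "averted"))

#' Default run configuration
#'
#' All tunable settings of the end-to-end pipeline, schema-validated by
#' [validate_config()]. Defaults reproduce the reference scale-up: 216
#' districts generated, 170 rolled out over 3 years, a 10-year horizon at a
#' 3% discount rate, coverage effects +11/+10/+6 percentage points spread
#' over 2 years, lives-saved anchors from the headline per-outcome totals,
#' and a 1,000-iteration probabilistic analysis.
#'
#' @param ... Overrides for any top-level key.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 42L,
    n_districts = 216L,
    pop_sdlog = 0.5,
    n_per_arm = 5000L,
    horizon_years = 10L,
    discount_rate = 0.03,
    ramp_years = 2L,
    baselines = c(sba = 70, facility_delivery = 57, measles = 85),
    effects = reference_effects(),
    use_estimated_effects = FALSE,
    caliper = Inf,
    n_boot = 500L,
    rates = list(mmr = 380, u5mr = 49, stillbirth_rate = 20),
    life_expectancy = 65.5,
    maternal_remaining = 36.5,
    include_stillbirths = TRUE,
    calibration_anchors = reference_headline_effects()$total_averted,
    per_capita_income = 1480,
    budget = list(national = 264.5e6, primary_care_fraction = 0.72),
    wtp_grid = c(0, 50, 100, 200, 400, 800, 1480, 4440),
    psa_iterations = 1000L,
    cost_cv = 0.2,
    effect_span = 0.4,
    stages = c(synthesis = TRUE, effects = TRUE, costs = TRUE,
               coverage = TRUE, impact = TRUE, cea = TRUE,
               uncertainty = TRUE)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Rejects unknown keys and out-of-domain values before any stage runs.
#'
#' @param cfg List or `run_config`.
#' @return The validated config (invisibly classed `run_config`).
#' @export
validate_config <- function(cfg) {
  ref <- unclass(default_config())
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(names(ref), names(cfg))
  if (length(missing) > 0) {
    stop("missing config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(cfg$n_districts >= 1, cfg$horizon_years >= 1,
            cfg$discount_rate >= 0, cfg$ramp_years >= 1,
            all(cfg$effects >= 0),
            all(cfg$baselines >= 0 & cfg$baselines <= 100),
            cfg$psa_iterations >= 1)
  invisible(structure(cfg, class = "run_config"))
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`; top-level keys
#'   override the defaults.
#' @return Validated `run_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- unclass(default_config())
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(raw)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && !is.list(raw[[k]])) as.list(raw[[k]]) else raw[[k]]
  }
  # named vectors survive YAML as lists; coerce back
  for (k in c("baselines", "effects", "calibration_anchors", "stages")) {
    if (is.list(cfg[[k]])) cfg[[k]] <- unlist(cfg[[k]])
  }
  validate_config(cfg)
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full forecasting pipeline
#'
#' Executes the stages in order — synthesis, effect estimation, costing,
#' coverage projection, impact, cost-effectiveness, uncertainty — writing
#' each stage's outputs as CSV/JSON under `out_dir` and a `manifest.json`
#' recording the config hash, seed, package version and per-file MD5
#' checksums. A stage failure halts the run with the failing stage named;
#' outputs of completed stages are retained. Stages toggled off in
#' `config$stages` are skipped (downstream stages then consume configured
#' values instead of estimated ones).
#'
#' @param config A `run_config` (see [default_config()], [read_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("cea_run_")) {
  cfg <- validate_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(config = cfg, out_dir = out_dir)
  written <- character()
  put_csv <- function(x, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(x, path, row.names = FALSE)
    written <<- c(written, path)
  }
  put_json <- function(x, file) {
    path <- file.path(out_dir, file)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE)
    written <<- c(written, path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- synthesis -----------------------------------------------------------
  results$districts <- stage("synthesis", {
    d <- generate_districts(cfg$n_districts, seed = cfg$seed,
                            pop_sdlog = cfg$pop_sdlog)
    if (cfg$stages[["synthesis"]]) put_csv(d, "districts.csv")
    d
  })
  if (cfg$stages[["synthesis"]]) {
    put_csv(synthetic_fx_table(), "fx.csv")
    put_csv(synthetic_cpi_table(), "cpi.csv")
  }

  # --- effect estimation ---------------------------------------------------
  effects_pp <- cfg$effects
  if (cfg$stages[["effects"]]) {
    results$exit_interviews <- stage("effects", {
      generate_exit_interviews(cfg$n_per_arm, true_effects = cfg$effects / 100,
                               seed = cfg$seed + 1L)
    })
    results$att <- stage("effects", {
      est <- estimate_effects(results$exit_interviews, caliper = cfg$caliper,
                              n_boot = cfg$n_boot, boot_seed = cfg$seed + 2L,
                              path = file.path(out_dir, "effects.json"))
      written <- c(written, file.path(out_dir, "effects.json"))
      put_csv(results$exit_interviews, "exit_interviews.csv")
      est
    })
    if (isTRUE(cfg$use_estimated_effects)) {
      effects_pp <- stats::setNames(results$att$att * 100, results$att$outcome)
      effects_pp <- pmax(effects_pp, 0)
    }
  }

  # --- costing -------------------------------------------------------------
  results$items <- reference_cost_items()
  results$schedule <- stage("costs", {
    expand_rollout(reference_rollout_plan(), results$districts)
  })
  results$cost_stream <- stage("costs", {
    cs <- compute_cost_stream(results$items, results$schedule,
                              results$districts,
                              horizon_years = cfg$horizon_years,
                              discount_rate = cfg$discount_rate)
    if (cfg$stages[["costs"]]) {
      put_csv(cs, "cost_stream.csv")
      put_json(as.list(per_district_annual_cost(results$items)),
               "phase_summary.json")
    }
    cs
  })

  # --- coverage ------------------------------------------------------------
  results$coverage <- stage("coverage", {
    cv <- coverage_table(results$schedule, cfg$baselines, effects_pp,
                         horizon_years = cfg$horizon_years,
                         ramp_years = cfg$ramp_years)
    if (cfg$stages[["coverage"]]) put_csv(cv, "coverage.csv")
    cv
  })

  # --- impact --------------------------------------------------------------
  results$impact <- stage("impact", {
    env <- mortality_envelope(
      results$districts[results$districts$district_id %in%
                          results$schedule$district_id, ],
      horizon_years = cfg$horizon_years,
      mmr = cfg$rates$mmr, u5mr = cfg$rates$u5mr,
      stillbirth_rate = cfg$rates$stillbirth_rate)
    eff <- default_effectiveness()
    if (!is.null(cfg$calibration_anchors)) {
      eff <- calibrate_effectiveness(eff, env, results$coverage,
                                     cfg$baselines, cfg$calibration_anchors)
    }
    results$effectiveness <- eff
    av <- deaths_averted(env, eff, results$coverage, cfg$baselines)
    imp <- aggregate_impact(av, r = cfg$discount_rate,
                            life_expectancy = cfg$life_expectancy,
                            maternal_remaining = cfg$maternal_remaining,
                            include_stillbirths = cfg$include_stillbirths)
    if (cfg$stages[["impact"]]) {
      put_csv(imp$by_year, "impact.csv")
      put_json(list(total_deaths_averted = imp$total_deaths,
                    deaths_by_outcome = as.list(imp$totals),
                    total_dalys = imp$total_dalys),
               "impact_summary.json")
    }
    imp
  })

  # --- cea -----------------------------------------------------------------
  results$icers <- stage("cea", {
    tab <- icer_table(results$cost_stream, results$impact,
                      horizon_years = cfg$horizon_years)
    tab$verdict <- vapply(tab$cost_per_daly, function(v) {
      if (is.na(v) || v <= 0) return(NA_character_)
      classify_icer(v, cfg$per_capita_income)$verdict
    }, character(1))
    if (cfg$stages[["cea"]]) put_csv(tab, "icers.csv")
    tab
  })

  # --- uncertainty ---------------------------------------------------------
  if (cfg$stages[["uncertainty"]]) {
    results$model <- make_reference_model(results$items, results$impact)
    results$specs <- default_parameter_specs(results$model,
                                             cost_cv = cfg$cost_cv,
                                             effect_span = cfg$effect_span)
    results$tornado <- stage("uncertainty", {
      t <- one_way(results$model, results$specs)
      put_csv(t, "tornado.csv")
      t
    })
    results$psa <- stage("uncertainty", {
      p <- run_psa(results$model, results$specs,
                   n_iter = cfg$psa_iterations, seed = cfg$seed + 3L)
      put_csv(p$draws, "psa_draws.csv")
      p
    })
    results$ceac <- stage("uncertainty", {
      cc <- ceac(results$psa, cfg$wtp_grid)
      put_csv(cc, "ceac.csv")
      cc
    })
  }

  # --- manifest ------------------------------------------------------------
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "mhealthcea",
    version = as.character(utils::packageVersion("mhealthcea")),
    seed = cfg$seed,
    config_md5 = md5_of(cfg[setdiff(names(cfg), "stages")]),
    stages_run = names(cfg$stages)[cfg$stages],
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
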