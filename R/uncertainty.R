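#' Parameter specification table for sensitivity analyses
#'
#' One row per uncertain parameter: its base value, sampling distribution
#' for the probabilistic analysis and low/high bounds for the one-way
#' analysis. Families: `gamma` (costs; mean = base, SD = `cost_cv` x base),
#' `normal` (effects; truncated to `[0, Inf)`, SD chosen so the 95%
#' interval spans +/- `effect_span` of the base), `beta`, `triangular`,
#' `fixed`.
#'
#' @param name,base Parameter name and base value.
#' @param distribution Family name.
#' @param sd Standard deviation (gamma/normal).
#' @param low,high One-way bounds (default +/-20% of base).
#' @return One-row tibble (`parameter_spec` rows bind into a spec table).
#' @export
parameter_spec <- function(name, base, distribution = "fixed",
                           sd = NA_real_, low = 0.8 * base, high = 1.2 * base) {
  stopifnot(distribution %in% c("gamma", "normal", "beta", "triangular", "fixed"))
  tibble::tibble(name = name, base = base, distribution = distribution,
                 sd = sd, low = low, high = high)
}

#' Default parameter specifications for the reference model
#'
#' Gamma distributions (SD 20% of base) for every cost item, and truncated
#' normals for the three per-outcome lives-saved totals (SD set so the 95%
#' interval spans +/-40% of the base). All spreads are conventions exposed
#' here, not measured quantities.
#'
#' @param model A [make_reference_model()] closure (its parameter table
#'   supplies names and bases).
#' @param cost_cv Coefficient of variation for cost items.
#' @param effect_span Half-width of the effects' 95% interval, as a
#'   fraction of base.
#' @return Spec tibble.
#' @export
default_parameter_specs <- function(model, cost_cv = 0.2, effect_span = 0.4) {
  pars <- attr(model, "parameters")
  specs <- lapply(seq_len(nrow(pars)), function(i) {
    if (pars$kind[i] == "cost") {
      parameter_spec(pars$name[i], pars$base[i], "gamma",
                     sd = cost_cv * pars$base[i])
    } else {
      parameter_spec(pars$name[i], pars$base[i], "normal",
                     sd = effect_span * pars$base[i] / stats::qnorm(0.975))
    }
  })
  do.call(rbind, specs)
}

#' Reduced-form deterministic model closure for sensitivity analyses
#'
#' Wraps a solved reference run into a fast closure mapping parameter
#' values to `(incremental_cost, dalys_averted, deaths_averted)`:
#' incremental cost is the sum of the resolved cost items, DALYs the sum of
#' per-outcome deaths averted times the per-death discounted YLL. The
#' closure's parameters are the cost items (named `cost: <phase>/<activity>`)
#' and the per-outcome lives-saved totals (`lives saved: <outcome>`), so
#' both analyses perturb the quantities the full pipeline computes.
#'
#' @param items Cost-ingredient tibble (resolved 10-year totals).
#' @param impact An [aggregate_impact()] result supplying per-outcome
#'   deaths averted and YLL parameters.
#' @return Function `f(params)` (named numeric, defaults = base values)
#'   returning a named numeric `c(cost, dalys, deaths)`; the parameter
#'   table is in `attr(, "parameters")`.
#' @export
make_reference_model <- function(items, impact) {
  cost_names <- sprintf("cost: %s/%s", items$phase, items$activity)
  effect_names <- sprintf("lives saved: %s", names(impact$totals))
  p <- impact$params
  yll_per_death <- vapply(names(impact$totals), function(oc) {
    L <- if (oc == "maternal") p$maternal_remaining else p$life_expectancy
    yll(1, L, p$r)
  }, numeric(1))
  daly_weight <- yll_per_death
  if (!p$include_stillbirths) daly_weight[names(daly_weight) == "stillbirth"] <- 0
  base <- c(stats::setNames(items$amount_2014usd, cost_names),
            stats::setNames(as.numeric(impact$totals), effect_names))
  kind <- c(rep("cost", length(cost_names)), rep("effect", length(effect_names)))
  f <- function(params = base) {
    full <- base
    keep <- intersect(names(params), names(base)) # unknown parameters ignored
    full[keep] <- params[keep]
    cost <- sum(full[kind == "cost"])
    deaths <- full[kind == "effect"]
    c(cost = cost,
      dalys = sum(deaths * daly_weight),
      deaths = sum(deaths))
  }
  attr(f, "parameters") <- tibble::tibble(name = names(base), base = unname(base),
                                          kind = kind)
  f
}

model_icer <- function(model, params) {
  v <- model(params)
  if (v[["dalys"]] <= 0) return(NA_real_)
  v[["cost"]] / v[["dalys"]]
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic model at each parameter's low and high bound,
#' all others held at base, and ranks parameters by the span of the
#' resulting cost-per-DALY. Equal spans order alphabetically; a model
#' failure at a bound is recorded for that parameter, not fatal.
#'
#' @param model Model closure (see [make_reference_model()]).
#' @param specs Spec tibble with `low`/`high` per parameter.
#' @return Tibble `name`, `icer_low`, `icer_high`, `span`, sorted by
#'   descending span.
#' @export
one_way <- function(model, specs) {
  stopifnot(all(c("name", "low", "high") %in% names(specs)))
  eval_at <- function(name, value) {
    tryCatch(model_icer(model, stats::setNames(value, name)),
             error = function(e) NA_real_)
  }
  lo <- unname(mapply(eval_at, specs$name, specs$low))
  hi <- unname(mapply(eval_at, specs$name, specs$high))
  span <- abs(hi - lo)
  out <- tibble::tibble(name = specs$name, icer_low = lo, icer_high = hi,
                        span = span)
  out[order(-out$span, out$name), ]
}

sample_spec <- function(spec, n) {
  base <- spec$base
  switch(spec$distribution,
    fixed = rep(base, n),
    gamma = {
      shape <- (base / spec$sd)^2
      stats::rgamma(n, shape = shape, rate = shape / base)
    },
    normal = {
      x <- stats::rnorm(n, base, spec$sd)
      while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), base, spec$sd)
      x
    },
    beta = {
      # mean = base, sd given; method-of-moments on [0,1]
      v <- spec$sd^2
      k <- base * (1 - base) / v - 1
      stats::rbeta(n, base * k, (1 - base) * k)
    },
    triangular = {
      u <- stats::runif(n)
      a <- spec$low; b <- spec$high; cpk <- base
      fc <- (cpk - a) / (b - a)
      ifelse(u < fc, a + sqrt(u * (b - a) * (cpk - a)),
             b - sqrt((1 - u) * (b - a) * (b - cpk)))
    },
    stop(sprintf("unknown distribution '%s'", spec$distribution), call. = FALSE)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_iter` joint parameter realizations and re-evaluates the model
#' for each, recording incremental cost, DALYs averted and deaths averted.
#' Draws with a non-positive effect denominator are resampled (counted;
#' more than 1% resampling aborts). The summary point estimate is mean
#' cost divided by mean effect, with a percentile 95% CI over the per-draw
#' ratios.
#'
#' @param model Model closure.
#' @param specs Spec tibble.
#' @param n_iter Iterations (default 1000).
#' @param seed Seed for the single random stream.
#' @return Object of class `psa_result`: `draws` tibble (`iteration`,
#'   `incremental_cost`, `dalys_averted`, `deaths_averted`), `mean_cost`,
#'   `mean_dalys`, `icer_mean` (mean cost / mean DALYs), `icer_ci`
#'   (percentile 95% CI of per-draw ratios), `cost_per_death_mean`,
#'   `n_resampled`.
#' @export
run_psa <- function(model, specs, n_iter = 1000, seed = 1) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  draw_matrix <- function(m) {
    vapply(seq_len(nrow(specs)), function(i) sample_spec(specs[i, ], m),
           numeric(m))
  }
  draws <- draw_matrix(n_iter)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n_iter)
  colnames(draws) <- specs$name
  evaluate <- function(x) model(stats::setNames(x, specs$name))
  res <- t(apply(draws, 1, evaluate))
  n_resampled <- 0L
  while (any(bad <- res[, "dalys"] <= 0)) {
    n_resampled <- n_resampled + sum(bad)
    if (n_resampled > 0.01 * n_iter) {
      stop("more than 1% of PSA draws invalid; check distributions", call. = FALSE)
    }
    redraw <- draw_matrix(sum(bad))
    if (is.null(dim(redraw))) redraw <- matrix(redraw, nrow = sum(bad))
    res[bad, ] <- t(apply(redraw, 1, evaluate))
  }
  out <- tibble::tibble(
    iteration = seq_len(n_iter),
    incremental_cost = res[, "cost"],
    dalys_averted = res[, "dalys"],
    deaths_averted = res[, "deaths"]
  )
  ratios <- out$incremental_cost / out$dalys_averted
  structure(
    list(draws = out,
         mean_cost = mean(out$incremental_cost),
         mean_dalys = mean(out$dalys_averted),
         icer_mean = mean(out$incremental_cost) / mean(out$dalys_averted),
         icer_ci = stats::quantile(ratios, c(0.025, 0.975), names = FALSE),
         cost_per_death_mean = mean(out$incremental_cost) / mean(out$deaths_averted),
         n_resampled = n_resampled, seed = seed),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "PSA (%d draws): cost/DALY %.2f (95%% CI %.2f-%.2f), cost/death %.2f\n",
    nrow(x$draws), x$icer_mean, x$icer_ci[1], x$icer_ci[2],
    x$cost_per_death_mean))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws with a
#' non-negative net monetary benefit (`wtp * dalys - cost >= 0`).
#'
#' @param psa `psa_result` or its draws tibble.
#' @param wtp_grid Willingness-to-pay grid (USD per DALY averted); the
#'   default includes the quoted $50 and $400 thresholds and the 1x/3x
#'   income multiples 1,480 and 4,440.
#' @return Tibble `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = c(0, 50, 100, 200, 400, 800, 1480, 4440)) {
  draws <- if (inherits(psa, "psa_result")) psa$draws else psa
  if (nrow(draws) == 0) stop("no PSA draws", call. = FALSE)
  if (length(wtp_grid) == 0) stop("empty willingness-to-pay grid", call. = FALSE)
  prob <- vapply(wtp_grid, function(l) {
    mean(l * draws$dalys_averted - draws$incremental_cost >= 0)
  }, numeric(1))
  tibble::tibble(wtp = wtp_grid, probability = prob)
}

#' Cost-effectiveness plane quadrant counts
#'
#' Counts draws by the sign of incremental effect (east: DALYs averted > 0)
#' and incremental cost (north: cost > 0); zeros count with the
#' positive side.
#'
#' @param psa `psa_result` or its draws tibble.
#' @return Tibble `quadrant`, `n`, `fraction` with quadrants NE/NW/SE/SW.
#' @export
ce_plane <- function(psa) {
  draws <- if (inherits(psa, "psa_result")) psa$draws else psa
  if (nrow(draws) == 0) stop("no PSA draws", call. = FALSE)
  east <- draws$dalys_averted >= 0
  north <- draws$incremental_cost >= 0
  quadrant <- ifelse(north & east, "NE",
                     ifelse(north & !east, "NW",
                            ifelse(!north & east, "SE", "SW")))
  counts <- table(factor(quadrant, levels = c("NE", "NW", "SE", "SW")))
  tibble::tibble(quadrant = names(counts), n = as.integer(counts),
                 fraction = as.numeric(counts) / nrow(draws))
}
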