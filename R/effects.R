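#' Fit a propensity-score model on exit-interview records
#'
#' Maximum-likelihood logistic regression of the treatment flag on the five
#' exit-interview covariates (education, employment, marital status, age,
#' income). Fitted probabilities are clipped to `[1e-6, 1 - 1e-6]`; fitted
#' values at the clip boundary (or a non-converged fit) raise a separation
#' diagnostic but never abort, matching how degenerate survey strata are
#' handled in practice.
#'
#' @param records Tibble from [generate_exit_interviews()] (or same schema).
#' @return Object of class `propensity_fit`: `coefficients`, `scores`
#'   (named by `record_id`), `separation` flag.
#' @export
fit_propensity <- function(records) {
  stopifnot(all(c("record_id", "treated", "education", "employment",
                  "marital_status", "age", "income") %in% names(records)))
  if (sum(records$treated == 1) < 2 || sum(records$treated == 0) < 2) {
    stop("need at least 2 records per arm", call. = FALSE)
  }
  dat <- as.data.frame(records)
  dat$marital_status <- factor(dat$marital_status)
  # constant covariates carry no information and would break the factor
  # contrasts; drop them so degenerate strata fall back to the intercept
  covs <- c("education", "employment", "marital_status", "age", "income")
  keep <- covs[vapply(covs, function(v) length(unique(dat[[v]])) > 1, logical(1))]
  rhs <- if (length(keep) > 0) paste(keep, collapse = " + ") else "1"
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::as.formula(paste("treated ~", rhs)),
               family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  scores <- pmin(pmax(stats::fitted(fit), 1e-6), 1 - 1e-6)
  if (any(stats::fitted(fit) <= 1e-6 | stats::fitted(fit) >= 1 - 1e-6)) {
    separation <- TRUE
  }
  names(scores) <- records$record_id
  structure(
    list(coefficients = stats::coef(fit), scores = scores,
         separation = separation),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Propensity-score fit on", length(x$scores), "records\n")
  if (x$separation) cat("  [!] separation diagnostic raised\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

# Nearest control (by absolute score distance) for each treated record,
# with replacement; equidistant candidates break ties on lowest record_id.
match_nearest <- function(treated_scores, control_scores, control_ids) {
  ord <- order(control_scores, control_ids)
  cs <- control_scores[ord]
  cid <- control_ids[ord]
  pos <- findInterval(treated_scores, cs)
  n <- length(cs)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, n)
  d_lo <- abs(treated_scores - cs[lo])
  d_hi <- abs(treated_scores - cs[hi])
  tol <- 1e-12
  pick <- ifelse(d_lo <= d_hi + tol & (d_lo < d_hi - tol | cid[lo] <= cid[hi]),
                 lo, hi)
  list(index = ord[pick], distance = pmin(d_lo, d_hi))
}

#' Estimate the average treatment effect on the treated by nearest-neighbour
#' matching
#'
#' Each treated record is matched, with replacement, to the control record
#' with minimal absolute propensity-score distance (ties broken by lowest
#' `record_id`); treated records with no control within `caliper` are
#' dropped and counted. The ATT is the mean of treated-minus-matched-control
#' outcome differences; the standard error comes from a seeded nonparametric
#' bootstrap over treated records (matches held fixed).
#'
#' @param records Exit-interview tibble.
#' @param fit A [fit_propensity()] result covering all records.
#' @param outcome Intervention name, e.g. `"sba"` (column `outcome_sba`).
#' @param caliper Maximum score distance for an acceptable match
#'   (default `Inf`, i.e. no caliper).
#' @param n_boot Bootstrap resamples for the SE.
#' @param boot_seed Seed for the bootstrap stream.
#' @return Object of class `att_estimate`: `outcome`, `att`, `se`,
#'   `n_matched_pairs`, `n_discarded`.
#' @export
estimate_att <- function(records, fit, outcome, caliper = Inf,
                         n_boot = 500, boot_seed = 1) {
  col <- paste0("outcome_", outcome)
  stopifnot(col %in% names(records))
  scores <- fit$scores[records$record_id]
  if (anyNA(scores)) stop("propensity fit does not cover all records", call. = FALSE)

  is_t <- records$treated == 1
  y <- records[[col]]
  m <- match_nearest(scores[is_t], scores[!is_t], records$record_id[!is_t])
  within <- m$distance <= caliper
  n_discarded <- sum(!within)
  diffs <- y[is_t][within] - y[!is_t][m$index[within]]
  n_pairs <- length(diffs)
  if (n_pairs == 0) stop("no treated record has a control within the caliper",
                         call. = FALSE)
  att <- mean(diffs)
  se <- NA_real_
  if (n_boot > 0 && n_pairs > 1) {
    set.seed(boot_seed)
    boot <- replicate(n_boot, mean(diffs[sample.int(n_pairs, replace = TRUE)]))
    se <- stats::sd(boot)
  }
  structure(
    list(outcome = outcome, att = att, se = se,
         n_matched_pairs = n_pairs, n_discarded = n_discarded),
    class = "att_estimate"
  )
}

#' @export
print.att_estimate <- function(x, ...) {
  cat(sprintf("ATT[%s] = %+.4f (SE %.4f, %d matched pairs, %d discarded)\n",
              x$outcome, x$att, x$se, x$n_matched_pairs, x$n_discarded))
  invisible(x)
}

#' Estimate ATTs for every outcome column and write effects to JSON
#'
#' @param records Exit-interview tibble.
#' @param outcomes Intervention names; default every `outcome_*` column.
#' @param caliper,n_boot,boot_seed Passed to [estimate_att()].
#' @param path Optional path for an `effects.json` file
#'   (`{outcome: {att, se, n_matched_pairs}}`).
#' @return Tibble of ATT estimates (one row per outcome).
#' @export
estimate_effects <- function(records, outcomes = NULL, caliper = Inf,
                             n_boot = 500, boot_seed = 1, path = NULL) {
  if (is.null(outcomes)) {
    outcomes <- sub("^outcome_", "", grep("^outcome_", names(records), value = TRUE))
  }
  fit <- fit_propensity(records)
  ests <- lapply(outcomes, function(o) {
    estimate_att(records, fit, o, caliper = caliper,
                 n_boot = n_boot, boot_seed = boot_seed)
  })
  out <- tibble::tibble(
    outcome = outcomes,
    att = vapply(ests, `[[`, numeric(1), "att"),
    se = vapply(ests, `[[`, numeric(1), "se"),
    n_matched_pairs = vapply(ests, `[[`, integer(1), "n_matched_pairs"),
    n_discarded = vapply(ests, `[[`, integer(1), "n_discarded")
  )
  if (!is.null(path)) {
    payload <- stats::setNames(lapply(seq_len(nrow(out)), function(i) {
      list(att = out$att[i], se = out$se[i],
           n_matched_pairs = out$n_matched_pairs[i])
    }), out$outcome)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  out
}
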