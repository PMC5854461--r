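# Pre-2012 expectation analysis: refit on the dataset truncated at the
# cutoff, compare full-data estimates with counterfactual projections in
# the years where data were removed, and express the comparison as an
# attainment probability.

#' Truncate a dataset at a cutoff year
#'
#' Removes every survey and service-statistic observation whose start
#' date is strictly greater than the cutoff (an observation starting
#' exactly in the cutoff year is retained); metadata and populations are
#' untouched. Idempotent.
#'
#' @param d an [fpem_dataset].
#' @param cutoff_year decimal cutoff (default 2012).
#' @return an [fpem_dataset].
#' @export
truncate_dataset <- function(d, cutoff_year = 2012) {
  fpem_dataset(
    surveys = d$surveys[d$surveys$period_start <= cutoff_year, ],
    meta = d$meta,
    populations = d$populations,
    service_stats =
      d$service_stats[d$service_stats$year <= cutoff_year, ],
    check = FALSE
  )
}

#' Attainment probability
#'
#' The probability, under the counterfactual (truncated-data) posterior,
#' of an outcome equal to or greater than the full-data estimate: the
#' fraction of counterfactual draws at or above the estimate. A 10%
#' attainment probability means there was a 10% chance of attaining the
#' observed level under pre-cutoff expectations.
#'
#' @param cf_draws counterfactual posterior draws of the indicator at the
#'   evaluation year.
#' @param estimate full-data point estimate (posterior median).
#' @return probability in \[0, 1\].
#' @export
attainment_probability <- function(cf_draws, estimate) {
  if (length(cf_draws) == 0) stop_fpem("no counterfactual draws")
  mean(cf_draws >= estimate)
}

#' Attainment probability group
#'
#' `LE25` when the probability (in percent) is at most 25, `GE75` when at
#' least 75, otherwise `MID`.
#'
#' @param p probability in \[0, 1\].
#' @return `"LE25"`, `"MID"` or `"GE75"`.
#' @export
classify_attainment <- function(p) {
  stopifnot(p >= 0, p <= 1)
  pct <- 100 * p
  if (pct <= 25) "LE25" else if (pct >= 75) "GE75" else "MID"
}

#' Two-criterion progress assessment
#'
#' Positive progress requires an increase of the estimate over the
#' expectation (`gap_pp > 0`) and a low attainment probability
#' (strictly below 50%).
#'
#' @param gap_pp estimated-minus-expected mCPR, percentage points.
#' @param attainment_prob probability in \[0, 1\].
#' @return logical.
#' @export
progress_assessment <- function(gap_pp, attainment_prob) {
  gap_pp > 0 & attainment_prob < 0.5
}

#' Counterfactual analysis of mCPR against pre-cutoff expectations
#'
#' Truncates the dataset at the cutoff, refits (unless counterfactual
#' draws are supplied), and for every country with data after the cutoff
#' compares the full-data posterior median mCPR at its most recent
#' observation year with the counterfactual projection for that year:
#' median gap in percentage points, the same gap in users, the attainment
#' probability, its group, and the two-criterion progress flag.
#'
#' @param data the full [fpem_dataset].
#' @param full_fit the fit on the full dataset (`fpem_fit` or
#'   `fpem_draws`).
#' @param model_cfg,fit_cfg configuration for the counterfactual refit.
#' @param cutoff_year decimal cutoff (default 2012).
#' @param cf_fit optional precomputed counterfactual fit, e.g. to reuse a
#'   fit when the cutoff removes nothing.
#' @return tibble sorted by increasing attainment probability:
#'   `country_code`, `eval_year`, `gap_pp`, `gap_users`,
#'   `attainment_prob`, `group`, `commitment`, `progress_positive`.
#' @export
counterfactual_analysis <- function(data, full_fit,
                                    model_cfg = fpem_config(),
                                    fit_cfg = fit_config(),
                                    cutoff_year = 2012, cf_fit = NULL) {
  if (inherits(full_fit, "fpem_fit")) full_fit <- full_fit$draws
  if (is.null(cf_fit)) {
    cf_fit <- fit_fpem(truncate_dataset(data, cutoff_year), model_cfg,
                       fit_cfg)
  }
  if (inherits(cf_fit, "fpem_fit")) cf_fit <- cf_fit$draws

  s <- data$surveys
  e <- data$service_stats
  post <- union(
    unique(s$country_code[s$period_start > cutoff_year]),
    unique(e$country_code[e$year > cutoff_year])
  )
  post <- intersect(data$meta$country_code, post)

  rows <- lapply(post, function(cc) {
    latest <- max(c(s$period_end[s$country_code == cc],
                    e$year[e$country_code == cc]))
    eval_year <- min(floor(latest), max(full_fit$years))
    full_med <- stats::median(draws_at(full_fit, cc, eval_year,
                                       "modern_cpr"))
    cf <- draws_at(cf_fit, cc, eval_year, "modern_cpr")
    cf_med <- stats::median(cf)
    prob <- attainment_probability(cf, full_med)
    mwra <- data$populations$mwra[
      data$populations$country_code == cc &
        data$populations$year == eval_year
    ]
    gap <- full_med - cf_med
    tibble::tibble(
      country_code = cc,
      eval_year = eval_year,
      gap_pp = 100 * gap,
      gap_users = if (length(mwra) == 1) mwra * gap else NA_real_,
      attainment_prob = prob,
      group = classify_attainment(prob),
      commitment = data$meta$fp2020_commitment[
        match(cc, data$meta$country_code)
      ],
      progress_positive = progress_assessment(100 * gap, prob)
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(
      country_code = character(), eval_year = numeric(),
      gap_pp = numeric(), gap_users = numeric(),
      attainment_prob = numeric(), group = character(),
      commitment = logical(), progress_positive = logical()
    ))
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$attainment_prob, out$country_code), ]
}
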