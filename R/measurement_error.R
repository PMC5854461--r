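# Observation-scale transforms and total-error assembly: survey proportions
# are modelled on the logit scale; proportion-scale sampling SEs map to
# logit-scale variances by the delta method, and each source type adds an
# estimated non-sampling variance on top.

#' Logit transform of a survey observation with delta-method variance
#'
#' Maps a proportion-scale observation and its sampling SE to the
#' modelling scale: `z = logit(value)` and
#' `v_sampling = se^2 / (value (1 - value))^2`.
#'
#' @param value observed proportion, strictly inside (0,1).
#' @param sampling_se proportion-scale sampling standard error (> 0).
#' @return list with `z` and `v_sampling` (logit scale).
#' @export
#' @examples
#' transform_observation(0.5, 0.01)  # z = 0, v = 0.0016
transform_observation <- function(value, sampling_se) {
  if (!is.finite(value) || value <= 0 || value >= 1)
    stop_fpem("value must lie strictly in (0,1), got ", value)
  if (!is.finite(sampling_se) || sampling_se <= 0)
    stop_fpem("sampling_se must be > 0, got ", sampling_se)
  list(
    z = logit(value),
    v_sampling = sampling_se^2 / (value * (1 - value))^2
  )
}

#' Impute a missing sampling standard error
#'
#' Observations whose source did not yield a computed sampling SE receive
#' the median of the observed SEs in the pool (same indicator, and same
#' source type when available); an empty pool falls back to the configured
#' default. Always positive; the caller flags the observation as imputed.
#'
#' @param pool numeric vector of observed proportion-scale SEs (may be
#'   empty; `NA`s are dropped).
#' @param default_se fallback SE when the pool is empty.
#' @return a single positive SE.
#' @export
impute_sampling_se <- function(pool, default_se = 0.015) {
  pool <- pool[is.finite(pool) & pool > 0]
  if (length(pool) == 0) {
    if (!is.finite(default_se) || default_se <= 0)
      stop_fpem("default_se must be > 0")
    return(default_se)
  }
  stats::median(pool)
}

#' Total logit-scale error variance
#'
#' Sampling variance plus the squared non-sampling SD of the observation's
#' source type.
#'
#' @param v_sampling logit-scale sampling variance (> 0).
#' @param source_type one of [fpem_source_types].
#' @param nonsampling_sd named numeric vector of logit-scale non-sampling
#'   SDs by source type (missing sources count as 0).
#' @return total variance.
#' @export
total_variance <- function(v_sampling, source_type, nonsampling_sd) {
  if (!is.finite(v_sampling) || v_sampling <= 0)
    stop_fpem("v_sampling must be > 0, got ", v_sampling)
  ns <- nonsampling_sd[[source_type]] %||% 0
  if (ns < 0) stop_fpem("nonsampling_sd must be >= 0")
  v_sampling + ns^2
}

#' Prepare survey observations for modelling
#'
#' Imputes missing sampling SEs (median of observed SEs for the same
#' indicator and source type; same indicator across sources if that pool
#' is empty; the configured default otherwise), then applies the logit
#' transform with delta-method variances.
#'
#' @param surveys the `surveys` table of an [fpem_dataset].
#' @param cfg an [fpem_config()].
#' @return the surveys tibble with added columns `sampling_se_filled`,
#'   `imputed` (logical), `z`, `v_sampling`.
#' @export
prepare_observations <- function(surveys, cfg = fpem_config()) {
  s <- tibble::as_tibble(surveys)
  s$imputed <- is.na(s$sampling_se)
  s$sampling_se_filled <- s$sampling_se
  for (i in which(s$imputed)) {
    pool <- s$sampling_se[s$indicator == s$indicator[i] &
                            s$source_type == s$source_type[i]]
    if (all(is.na(pool)))
      pool <- s$sampling_se[s$indicator == s$indicator[i]]
    s$sampling_se_filled[i] <-
      impute_sampling_se(pool[!is.na(pool)], cfg$error$default_se)
  }
  tr <- Map(transform_observation, s$value, s$sampling_se_filled)
  s$z <- vapply(tr, `[[`, numeric(1), "z")
  s$v_sampling <- vapply(tr, `[[`, numeric(1), "v_sampling")
  s
}
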