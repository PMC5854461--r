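#' Model configuration
#'
#' Assemble the model configuration: estimation grid, prior hyperparameters
#' for the hierarchical logistic trend, AR(1) distortion priors, the
#' measurement-error settings and the service-statistic (EMU) variance.
#' All values can be overridden, either here or from a YAML file via
#' [load_config()].
#'
#' Priors (all declared defaults, on the modelling scale):
#' * `logit_ptilde`: world mean N(0.5, 1^2) for the logit asymptote of total
#'   prevalence, truncated so the asymptote lies in (0.1, 0.95);
#' * `log_omega`: world mean N(log 0.1, 0.5^2) for the log growth rate per
#'   year;
#' * `midpoint`: world mean N(2000, 10^2) for the logistic midpoint year;
#' * `logit_rtilde` / `log_psi` / `share_midpoint`: the analogous prior for
#'   the modern-share logistic curve;
#' * `alpha`: N(-0.5, 1^2) country intercept (logit unmet need among
#'   non-users at eta = 0);
#' * hierarchy-level standard deviations: half-normal with scale
#'   `level_sd_scale` at each of the region, subregion and country levels;
#' * AR distortions: rho ~ Uniform(0, `rho_max`), tau ~ half-normal with
#'   scale `tau_scale` (one pair for prevalence rate-of-change distortions,
#'   one for unmet-need level distortions);
#' * source biases (logit scale, DHS fixed at 0): N(0, `bias_sd`^2);
#' * non-sampling SDs per source: half-normal with scale
#'   `error$nonsampling_prior_scale`.
#'
#' @param ... named overrides merged recursively into the defaults, e.g.
#'   `grid = list(year_min = 1980)`.
#' @return a nested list of class `fpem_config`.
#' @export
#' @examples
#' cfg <- fpem_config(grid = list(year_min = 1980, year_max = 2025))
#' cfg$grid$year_max
fpem_config <- function(...) {
  cfg <- list(
    grid = list(year_min = 1970, year_max = 2030),
    priors = list(
      logit_ptilde = list(mean = 0.5, sd = 1,
                          lower = logit(0.1), upper = logit(0.95)),
      log_omega = list(mean = log(0.1), sd = 0.5),
      midpoint = list(mean = 2000, sd = 10),
      logit_rtilde = list(mean = 0.5, sd = 1,
                          lower = logit(0.1), upper = logit(0.95)),
      log_psi = list(mean = log(0.1), sd = 0.5),
      share_midpoint = list(mean = 2000, sd = 10),
      alpha = list(mean = -0.5, sd = 1),
      beta_sd = 1,
      level_sd_scale = 0.5,
      rho_max = 0.95,
      tau_scale = 0.1,
      bias_sd = 0.2
    ),
    error = list(default_se = 0.015, nonsampling_prior_scale = 0.2),
    emu = list(variance = 0.01),
    outlier_screen = TRUE
  )
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(cfg))
    if (length(bad)) stop_fpem("unknown config keys: ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, override)
  }
  structure(cfg, class = c("fpem_config", "list"))
}

#' Read configuration overrides from a YAML file
#'
#' The YAML file contains any subset of the [fpem_config()] keys; values it
#' supplies replace the defaults, everything else keeps its default. An
#' optional `fit:` block is returned alongside for [fit_config()].
#'
#' @param path YAML file.
#' @return list with elements `model` (an `fpem_config`) and `fit` (a list
#'   of fit overrides, possibly empty).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  fit <- raw$fit %||% list()
  raw$fit <- NULL
  model <- do.call(fpem_config, raw)
  list(model = model, fit = fit)
}

#' Sampler configuration
#'
#' @param n_chains number of MCMC chains (>= 2 for convergence checks).
#' @param n_warmup adaptation + burn-in iterations per chain.
#' @param n_samples retained iterations per chain.
#' @param seed master integer seed; every chain derives its own stream.
#' @param thin thinning interval.
#' @return list of class `fpem_fit_config`.
#' @export
fit_config <- function(n_chains = 4, n_warmup = 1000, n_samples = 1000,
                       seed = 1, thin = 1) {
  stopifnot(n_chains >= 1, n_warmup > 0, n_samples > 0, thin >= 1)
  structure(
    list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
         n_samples = as.integer(n_samples), seed = as.integer(seed),
         thin = as.integer(thin)),
    class = c("fpem_fit_config", "list")
  )
}
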