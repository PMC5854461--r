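# Synthetic-data generator: a generative mirror of the model. Trend and
# distortion parameters are drawn from the declared priors down the
# region/subregion/country hierarchy; surveys are sampled sparsely with
# heterogeneous sources, reference periods, biases and noise; EMU series
# carry a country-level offset that only their differences survive.

#' Named scenario configurations
#'
#' * `tiny`: 1 region, 1 subregion, 3 countries, ~4 surveys each --
#'   smoke-test scale.
#' * `small`: 2 regions x 2 subregions x 4 countries = 16 countries,
#'   ~5 surveys each -- calibration-study scale.
#' * `fp2020_like`: 2 regions x 2 subregions x 17 countries = 68
#'   countries with ~5.4 surveys each (each survey reports total and
#'   modern prevalence, so ~730 prevalence rows), unmet need on ~63% of
#'   surveys, and 13 countries carrying ~6.5 EMU points each --
#'   proportioned to the multi-country database the model was built for
#'   (733 prevalence, 462 unmet-need and 85 service-statistic
#'   observations).
#'
#' @param name scenario name.
#' @return list of class `fpem_scenario` with generator settings.
#' @export
make_scenario <- function(name = c("tiny", "small", "fp2020_like")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    n_regions = 2, n_subregions_per_region = 2,
    n_countries_per_subregion = 4,
    surveys_per_country = 5,
    p_unmet = 0.63,
    p_period_two = 0.3,
    source_mix = c(DHS = 0.5, MICS = 0.2, PMA = 0.1, RHS = 0.05,
                   NATIONAL = 0.1, OTHER = 0.05),
    bias = c(DHS = 0, MICS = -0.05, PMA = 0.05, RHS = 0,
             NATIONAL = 0.1, OTHER = -0.1),
    nonsampling_sd = c(DHS = 0.05, MICS = 0.07, PMA = 0.07, RHS = 0.07,
                       NATIONAL = 0.1, OTHER = 0.12),
    n_eff_range = c(2000, 15000),
    p_se_missing = 0.5,
    n_emu_countries = 3,
    emu_points = 6,
    emu_offset_sd = 0.15,
    obs_window = c(1985, 2017),
    pop_meanlog = log(2e6), pop_sdlog = 0.7, pop_growth = 0.015,
    p_commitment = 0.6
  )
  over <- switch(name,
    tiny = list(n_regions = 1, n_subregions_per_region = 1,
                n_countries_per_subregion = 3, surveys_per_country = 4,
                n_emu_countries = 1),
    small = list(),
    fp2020_like = list(n_countries_per_subregion = 17,
                       surveys_per_country = 5.4,
                       n_emu_countries = 13, emu_points = 6.5)
  )
  structure(utils::modifyList(base, over), class = c("fpem_scenario", "list"))
}

scenario_meta <- function(cfg, seed) {
  set.seed(sub_seed(seed, 900))
  n_sub <- cfg$n_regions * cfg$n_subregions_per_region
  n_ctry <- n_sub * cfg$n_countries_per_subregion
  sub_reg <- rep(seq_len(cfg$n_regions), each = cfg$n_subregions_per_region)
  ctry_sub <- rep(seq_len(n_sub), each = cfg$n_countries_per_subregion)
  tibble::tibble(
    country_code = sprintf("C%02d", seq_len(n_ctry)),
    name = sprintf("Country %02d", seq_len(n_ctry)),
    subregion = sprintf("S%02d", ctry_sub),
    region = sprintf("R%d", sub_reg[ctry_sub]),
    fp2020_commitment = stats::runif(n_ctry) < cfg$p_commitment
  )
}

rtnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

r_ar1 <- function(n, rho, tau) {
  if (n == 0) return(numeric(0))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, tau)
  for (t in seq_len(n - 1) + 1) {
    x[t] <- stats::rnorm(1, rho * x[t - 1], tau * sqrt(1 - rho^2))
  }
  x
}

#' Draw a synthetic truth from the model's priors
#'
#' Samples world means, level SDs, region/subregion means and country
#' parameters from the declared hierarchy, AR parameters and distortion
#' series from their priors, and builds the true trajectory for every
#' country. Deterministic given `seed` (each country consumes its own
#' derived sub-stream, so results do not depend on iteration order).
#'
#' @param cfg a [make_scenario()] configuration.
#' @param seed integer master seed.
#' @param model_cfg an [fpem_config()]; its priors are the generative
#'   distributions.
#' @return list of class `fpem_truth` with `params` and `distortions`
#'   (shaped as [joint_logposterior()] expects), `trajectories`,
#'   `proportions` (per-country matrices), `meta`, `grid`, `seed`, `cfg`.
#' @export
gen_truth <- function(cfg, seed = 1, model_cfg = fpem_config()) {
  meta <- scenario_meta(cfg, seed)
  grid <- seq(model_cfg$grid$year_min, model_cfg$grid$year_max)
  pr <- model_cfg$priors
  regions <- unique(meta$region)
  subregions <- unique(meta$subregion)
  sub2reg <- unique(meta[, c("subregion", "region")])

  prior_spec <- list(
    logit_ptilde = pr$logit_ptilde, log_omega = pr$log_omega,
    midpoint = pr$midpoint, logit_rtilde = pr$logit_rtilde,
    log_psi = pr$log_psi, share_midpoint = pr$share_midpoint,
    alpha = pr$alpha
  )

  set.seed(sub_seed(seed, 901))
  hyper <- list()
  for (k in names(prior_spec)) {
    spec <- prior_spec[[k]]
    lo <- spec$lower %||% -Inf
    hi <- spec$upper %||% Inf
    world <- rtnorm1(spec$mean, spec$sd, lo, hi)
    sds <- abs(stats::rnorm(3, 0, pr$level_sd_scale))
    names(sds) <- c("region", "subregion", "country")
    reg_m <- stats::rnorm(length(regions), world, sds[["region"]])
    names(reg_m) <- regions
    sub_m <- stats::rnorm(length(subregions),
                          reg_m[sub2reg$region], sds[["subregion"]])
    names(sub_m) <- subregions
    hyper[[k]] <- list(world = world, region = reg_m, subregion = sub_m,
                       sd = sds)
  }
  beta <- stats::rnorm(1, 0, pr$beta_sd)
  ar <- list(
    eta = list(rho = stats::runif(1, 0, pr$rho_max),
               tau = abs(stats::rnorm(1, 0, pr$tau_scale))),
    unmet = list(rho = stats::runif(1, 0, pr$rho_max),
                 tau = abs(stats::rnorm(1, 0, pr$tau_scale)))
  )
  # measurement-error settings come from the scenario, not the prior:
  # they are observation conditions, fixed per scenario
  err <- list(nonsampling_sd = cfg$nonsampling_sd, bias = cfg$bias)

  country <- meta["country_code"]
  for (k in names(prior_spec)) country[[k]] <- NA_real_
  distortions <- list()
  for (i in seq_len(nrow(meta))) {
    set.seed(sub_seed(seed, 1000 + i))
    cc <- meta$country_code[i]
    for (k in names(prior_spec)) {
      spec <- prior_spec[[k]]
      country[[k]][i] <- rtnorm1(
        hyper[[k]]$subregion[[meta$subregion[i]]],
        hyper[[k]]$sd[["country"]],
        spec$lower %||% -Inf, spec$upper %||% Inf
      )
    }
    distortions[[cc]] <- list(
      delta_eta = r_ar1(length(grid) - 1, ar$eta$rho, ar$eta$tau),
      delta_u = r_ar1(length(grid), ar$unmet$rho, ar$unmet$tau)
    )
  }

  params <- list(hyper = hyper, country = country, beta = beta, ar = ar,
                 error = err)
  trajectories <- lapply(meta$country_code, function(cc) {
    country_trajectory_from_params(params, distortions, cc, grid)
  })
  names(trajectories) <- meta$country_code
  structure(
    list(params = params, distortions = distortions,
         trajectories = trajectories,
         proportions = lapply(trajectories, trajectory_proportions),
         meta = meta, grid = grid, seed = seed, cfg = cfg),
    class = "fpem_truth"
  )
}

#' Generate observations from a synthetic truth
#'
#' Surveys are placed at random years inside the observation window with
#' one- or two-year reference periods; each survey reports total and
#' modern prevalence and, with configured probability, unmet need. The
#' observed value is the period-averaged truth perturbed on the logit
#' scale by the source bias plus noise with the full (sampling +
#' non-sampling) variance. DHS rows always carry their sampling SE; a
#' configured fraction of other rows lose it (to be imputed downstream).
#' EMU series add a country-level offset and noise to logit modern use.
#'
#' @param truth a [gen_truth()] result.
#' @param cfg the scenario used to build `truth` (defaults to the one
#'   stored in it).
#' @param model_cfg an [fpem_config()]; supplies the EMU variance.
#' @return an [fpem_dataset].
#' @export
gen_observations <- function(truth, cfg = truth$cfg,
                             model_cfg = fpem_config()) {
  meta <- truth$meta
  grid <- truth$grid
  window <- max(cfg$obs_window[1], grid[1]):min(cfg$obs_window[2], max(grid))
  seed <- truth$seed

  rows <- list()
  emu_rows <- list()
  pop_rows <- list()
  emu_countries <- meta$country_code[seq_len(min(cfg$n_emu_countries,
                                                 nrow(meta)))]
  for (i in seq_len(nrow(meta))) {
    set.seed(sub_seed(seed, 2000 + i))
    cc <- meta$country_code[i]
    props <- truth$proportions[[cc]]
    n_sv <- max(1, stats::rpois(1, cfg$surveys_per_country))
    yrs <- sort(sample(window, min(n_sv, length(window))))
    for (y in yrs) {
      two <- stats::runif(1) < cfg$p_period_two && (y + 1) <= max(window)
      ps <- y + 0.5
      pe <- if (two) y + 1.5 else y + 0.5
      src <- sample(names(cfg$source_mix), 1, prob = cfg$source_mix)
      inds <- c("total_cpr", "modern_cpr",
                if (stats::runif(1) < cfg$p_unmet) "unmet_any")
      w <- period_weights(ps, pe, grid)
      n_eff <- stats::runif(1, cfg$n_eff_range[1], cfg$n_eff_range[2])
      for (ind in inds) {
        p_true <- sum(w * props[, ind])
        # survey sampling variance scales as p(1-p)/n_eff; on the logit
        # scale (delta method) that is 1/(n_eff p(1-p))
        v_samp <- 1 / (n_eff * p_true * (1 - p_true))
        v_tot <- v_samp + cfg$nonsampling_sd[[src]]^2
        z <- logit(p_true) + cfg$bias[[src]] +
          stats::rnorm(1, 0, sqrt(v_tot))
        value <- expit(z)
        # the SE a survey would report is computed from its own estimate
        se_p <- sqrt(value * (1 - value) / n_eff)
        keep_se <- src == "DHS" || stats::runif(1) >= cfg$p_se_missing
        rows[[length(rows) + 1]] <- tibble::tibble(
          country_code = cc, indicator = ind, value = value,
          source_type = src, period_start = ps, period_end = pe,
          sampling_se = if (keep_se) se_p else NA_real_
        )
      }
    }
    # EMU series
    if (cc %in% emu_countries) {
      n_emu <- max(2, stats::rpois(1, cfg$emu_points))
      last <- max(window)
      e_yrs <- sort(sample(seq(last - 9, last), min(n_emu, 10)))
      offset <- stats::rnorm(1, 0, cfg$emu_offset_sd)
      modern <- props[as.character(e_yrs), "modern_cpr"]
      emu <- expit(logit(modern) + offset +
                     stats::rnorm(length(e_yrs), 0,
                                  sqrt(model_cfg$emu$variance)))
      emu_rows[[length(emu_rows) + 1]] <- tibble::tibble(
        country_code = cc, year = e_yrs, emu = emu
      )
    }
    # populations over the whole grid
    base <- stats::rlnorm(1, cfg$pop_meanlog, cfg$pop_sdlog)
    pop_rows[[length(pop_rows) + 1]] <- tibble::tibble(
      country_code = cc, year = grid,
      mwra = base * (1 + cfg$pop_growth)^(grid - grid[1])
    )
  }

  fpem_dataset(
    surveys = dplyr::bind_rows(rows),
    meta = meta,
    populations = dplyr::bind_rows(pop_rows),
    service_stats = if (length(emu_rows)) dplyr::bind_rows(emu_rows) else NULL
  )
}

#' Simulate a complete scenario
#'
#' Convenience wrapper: draw a truth and its observations in one call.
#'
#' @param scenario scenario name or a [make_scenario()] list.
#' @param seed integer master seed.
#' @param model_cfg an [fpem_config()].
#' @return list with `data` (an [fpem_dataset]) and `truth`.
#' @export
simulate_dataset <- function(scenario = "small", seed = 1,
                             model_cfg = fpem_config()) {
  cfg <- if (is.character(scenario)) make_scenario(scenario) else scenario
  truth <- gen_truth(cfg, seed = seed, model_cfg = model_cfg)
  list(data = gen_observations(truth, cfg, model_cfg), truth = truth)
}
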