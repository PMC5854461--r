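# Latent process and joint log-posterior. Total prevalence follows a
# hierarchical logistic growth curve on an annual grid; AR(1) distortions
# act on the annual rates of change (logit increments) so that departures
# of *pace* -- not just level -- propagate into projections. The modern
# share follows its own logistic curve; unmet need among non-users is
# linked linearly (logit scale) to total prevalence with AR(1) level
# distortions.

#' Expected logistic trend
#'
#' `p_tilde / (1 + exp(-omega (t - midpoint)))`: prevalence rises slowly,
#' accelerates around the midpoint year, and saturates at the asymptote
#' `p_tilde`.
#'
#' @param t decimal year(s).
#' @param params list with `p_tilde` (asymptote in (0,1)), `omega` (growth
#'   rate per year, > 0), `midpoint` (decimal year).
#' @return proportion(s) in (0, `p_tilde`).
#' @export
#' @examples
#' logistic_curve(2000, list(p_tilde = 0.8, omega = 0.2, midpoint = 2000))
logistic_curve <- function(t, params) {
  stopifnot(params$p_tilde > 0, params$p_tilde < 1, params$omega > 0)
  params$p_tilde / (1 + exp(-params$omega * (t - params$midpoint)))
}

#' Expected annual logit increments of the trend
#'
#' `d*_t = logit(curve(t+1)) - logit(curve(t))` for consecutive grid
#' years; always positive for a rising logistic curve.
#'
#' @param params as in [logistic_curve()].
#' @param grid contiguous integer years.
#' @return numeric vector of length `length(grid) - 1`.
#' @export
expected_increments <- function(params, grid) {
  stopifnot(length(grid) >= 2, all(diff(grid) == 1))
  lc <- logit(logistic_curve(grid, params))
  diff(lc)
}

#' Log density of a stationary AR(1) distortion series
#'
#' `delta_1 ~ N(0, tau^2)`; `delta_(t+1) | delta_t ~
#' N(rho delta_t, tau^2 (1 - rho^2))`, so the marginal variance is
#' `tau^2` at every step.
#'
#' @param delta numeric series.
#' @param rho autocorrelation, strictly inside (-1, 1).
#' @param tau stationary standard deviation (> 0).
#' @return scalar log density.
#' @export
ar1_logdensity <- function(delta, rho, tau) {
  if (!is.finite(rho) || abs(rho) >= 1) stop_fpem("|rho| must be < 1")
  if (!is.finite(tau) || tau <= 0) stop_fpem("tau must be > 0")
  n <- length(delta)
  if (n == 0) return(0)
  ll <- stats::dnorm(delta[1], 0, tau, log = TRUE)
  if (n > 1) {
    sd_cond <- tau * sqrt(1 - rho^2)
    ll <- ll + sum(stats::dnorm(delta[-1], rho * delta[-n], sd_cond,
                                log = TRUE))
  }
  ll
}

#' Build a country trajectory from parameters and distortions
#'
#' The logit total prevalence `eta` starts on the expected curve at the
#' first grid year and accumulates expected increments plus rate-of-change
#' distortions; the logit modern share `s` is the share curve itself; the
#' logit unmet need among non-users is `u_t = alpha + beta eta_t +
#' delta_u_t`.
#'
#' @param logistic list(`p_tilde`, `omega`, `midpoint`) for total
#'   prevalence.
#' @param share list(`p_tilde`, `omega`, `midpoint`) for the modern share
#'   (asymptotic share, rate, midpoint year).
#' @param unmet list(`alpha`, `beta`).
#' @param delta_eta rate-of-change distortions, length `length(grid) - 1`.
#' @param delta_u unmet-need level distortions, length `length(grid)`.
#' @param grid contiguous integer years.
#' @return object of class `fpem_trajectory`: list with `grid`, `eta`,
#'   `s`, `u` (all logit scale).
#' @export
build_trajectory <- function(logistic, share, unmet, delta_eta, delta_u,
                             grid) {
  n <- length(grid)
  stopifnot(n >= 1, all(diff(grid) == 1))
  if (length(delta_eta) != n - 1)
    stop_fpem("delta_eta must have length ", n - 1, ", got ",
              length(delta_eta))
  if (length(delta_u) != n)
    stop_fpem("delta_u must have length ", n, ", got ", length(delta_u))
  eta <- numeric(n)
  eta[1] <- logit(logistic_curve(grid[1], logistic))
  if (n > 1) {
    dstar <- expected_increments(logistic, grid)
    eta[-1] <- eta[1] + cumsum(dstar + delta_eta)
  }
  s <- logit(logistic_curve(grid, share))
  u <- unmet$alpha + unmet$beta * eta + delta_u
  structure(list(grid = grid, eta = eta, s = s, u = u),
            class = "fpem_trajectory")
}

#' Indicator proportions along a trajectory
#'
#' Converts the logit-scale trajectory into the four indicator
#' proportions. By construction `modern + trad = total` and
#' `total + unmet_any <= 1` (unmet need applies to non-users only).
#'
#' @param traj an `fpem_trajectory`.
#' @return matrix `length(grid) x 4` with columns [fpem_quantities].
#' @export
trajectory_proportions <- function(traj) {
  total <- expit(traj$eta)
  modern <- total * expit(traj$s)
  out <- cbind(
    total_cpr = total,
    modern_cpr = modern,
    trad_cpr = total - modern,
    unmet_any = (1 - total) * expit(traj$u)
  )
  rownames(out) <- traj$grid
  out
}

#' Reference-period weights over the annual grid
#'
#' A grid year `Y` represents the calendar interval `[Y, Y+1)`. Weights
#' are proportional to the overlap of the reference period with each
#' interval; a point period (start == end) loads entirely on its year.
#'
#' @param period_start,period_end decimal years, `end >= start`.
#' @param grid contiguous integer years.
#' @return numeric weights over `grid`, summing to 1.
#' @export
period_weights <- function(period_start, period_end, grid) {
  if (period_end < period_start) stop_fpem("period_end < period_start")
  if (period_start == period_end) {
    y <- floor(period_start)
    w <- as.numeric(grid == y)
    if (sum(w) == 0)
      stop_fpem("reference period ", period_start, " outside the grid")
    return(w)
  }
  w <- pmax(0, pmin(period_end, grid + 1) - pmax(period_start, grid))
  if (sum(w) <= 0)
    stop_fpem("reference period [", period_start, ", ", period_end,
              "] does not overlap the grid")
  w / sum(w)
}

#' Log likelihood of one transformed survey observation
#'
#' The model value is the reference-period weighted average of the
#' relevant indicator on the proportion scale, taken through the logit;
#' the observation's `z` is normal around that value plus the source bias,
#' with variance `v_sampling + nonsampling_sd[source]^2`.
#'
#' @param obs list or one-row data frame with `indicator`,
#'   `period_start`, `period_end`, `z`, `v_sampling`, `source_type`.
#' @param traj an `fpem_trajectory` for the observation's country.
#' @param error list with named vectors `nonsampling_sd` and `bias` by
#'   source type (DHS bias 0 by convention).
#' @return scalar log likelihood.
#' @export
observation_loglik <- function(obs, traj, error) {
  w <- period_weights(obs$period_start, obs$period_end, traj$grid)
  props <- trajectory_proportions(traj)
  model_p <- sum(w * props[, obs$indicator])
  mu <- logit(model_p) + (error$bias[[obs$source_type]] %||% 0)
  v_tot <- total_variance(obs$v_sampling, obs$source_type,
                          error$nonsampling_sd)
  stats::dnorm(obs$z, mu, sqrt(v_tot), log = TRUE)
}

#' Log likelihood of a service-statistic (EMU) series
#'
#' EMU levels are biased, but their changes track changes in modern use,
#' so first differences of logit EMU are modelled as normal around first
#' differences of the logit modern prevalence (the level bias cancels by
#' differencing). A series with fewer than two points carries no
#' information and contributes 0 with a warning.
#'
#' @param years integer years of the EMU observations (must lie on the
#'   grid).
#' @param emu EMU proportions in (0,1), same length as `years`.
#' @param traj an `fpem_trajectory`.
#' @param variance_emu variance of the logit-difference residuals.
#' @return scalar log likelihood.
#' @export
service_stat_loglik <- function(years, emu, traj, variance_emu) {
  if (length(years) < 2) {
    warning("EMU series with fewer than 2 points contributes no information",
            call. = FALSE)
    return(0)
  }
  ord <- order(years)
  years <- years[ord]; emu <- emu[ord]
  idx <- match(floor(years), traj$grid)
  if (anyNA(idx)) stop_fpem("EMU year outside the grid")
  modern <- trajectory_proportions(traj)[, "modern_cpr"]
  dz <- diff(logit(emu))
  dmu <- diff(logit(modern[idx]))
  sum(stats::dnorm(dz, dmu, sqrt(variance_emu), log = TRUE))
}

#' Outlier screen against a projected trend
#'
#' Flags an observation whose distance from the projection mean strictly
#' exceeds two projection standard deviations; a value at exactly 2 SD is
#' not flagged.
#'
#' @param value observed proportion.
#' @param projection_mean,projection_sd projection mean and SD on the same
#'   scale (`projection_sd > 0`).
#' @return logical.
#' @export
flag_outliers <- function(value, projection_mean, projection_sd) {
  if (!is.finite(projection_sd) || projection_sd <= 0)
    stop_fpem("projection_sd must be > 0")
  abs(value - projection_mean) > 2 * projection_sd
}

# ---------------------------------------------------------------------------
# Joint log-posterior (reference density; the sampler mirrors it)

par_names <- c("logit_ptilde", "log_omega", "midpoint",
               "logit_rtilde", "log_psi", "share_midpoint", "alpha")

country_logistic <- function(row) {
  list(p_tilde = expit(row$logit_ptilde), omega = exp(row$log_omega),
       midpoint = row$midpoint)
}
country_share <- function(row) {
  list(p_tilde = expit(row$logit_rtilde), omega = exp(row$log_psi),
       midpoint = row$share_midpoint)
}

country_trajectory_from_params <- function(params, distortions, cc, grid) {
  row <- params$country[params$country$country_code == cc, ]
  if (nrow(row) != 1) stop_fpem("no parameters for country ", cc)
  build_trajectory(
    logistic = country_logistic(row),
    share = country_share(row),
    unmet = list(alpha = row$alpha, beta = params$beta),
    delta_eta = distortions[[cc]]$delta_eta,
    delta_u = distortions[[cc]]$delta_u,
    grid = grid
  )
}

#' Joint log-posterior of the full model
#'
#' Sum of the hierarchical prior terms (world mean, region, subregion and
#' country levels for each trend parameter, with half-normal priors on the
#' level SDs), the AR(1) distortion densities, and all survey and
#' service-statistic log likelihoods. This is the package's reference
#' statement of the model; the MCMC engine samples from the same density.
#'
#' @param params structured parameter list:
#'   * `hyper`: per parameter in `logit_ptilde, log_omega, midpoint,
#'     logit_rtilde, log_psi, share_midpoint, alpha`, a list with `world`
#'     (scalar), `region` and `subregion` (named means), and `sd` (named
#'     `region`, `subregion`, `country` level SDs);
#'   * `country`: tibble of country-level values, one column per parameter
#'     plus `country_code`;
#'   * `beta`: global slope linking unmet need to prevalence;
#'   * `ar`: list `eta = list(rho, tau)`, `unmet = list(rho, tau)`;
#'   * `error`: list `nonsampling_sd`, `bias` (named by source type, DHS
#'     bias must be 0).
#' @param distortions named list by country: `delta_eta` (length
#'   `|grid|-1`) and `delta_u` (length `|grid|`).
#' @param data an [fpem_dataset].
#' @param cfg an [fpem_config()].
#' @param grid integer years (default from `cfg`).
#' @return scalar log posterior (finite for valid inputs).
#' @export
joint_logposterior <- function(params, distortions, data,
                               cfg = fpem_config(),
                               grid = seq(cfg$grid$year_min,
                                          cfg$grid$year_max)) {
  pr <- cfg$priors
  if (abs(params$error$bias[["DHS"]] %||% 0) > 0)
    stop_fpem("DHS bias is the reference and must be 0")
  for (blk in params$ar) {
    if (abs(blk$rho) >= 1) stop_fpem("|rho| must be < 1")
    if (blk$tau <= 0) stop_fpem("tau must be > 0")
  }

  meta <- data$meta
  sub2reg <- unique(meta[, c("subregion", "region")])
  lp <- 0

  for (k in par_names) {
    h <- params$hyper[[k]]
    spec <- switch(k,
      logit_ptilde = pr$logit_ptilde, log_omega = pr$log_omega,
      midpoint = pr$midpoint, logit_rtilde = pr$logit_rtilde,
      log_psi = pr$log_psi, share_midpoint = pr$share_midpoint,
      alpha = pr$alpha
    )
    lo <- spec$lower %||% -Inf
    hi <- spec$upper %||% Inf
    lp <- lp + dtnorm_log(h$world, spec$mean, spec$sd, lo, hi)
    lp <- lp + sum(dhalfnorm_log(h$sd, pr$level_sd_scale))
    lp <- lp + sum(stats::dnorm(h$region, h$world, h$sd[["region"]],
                                log = TRUE))
    parent_reg <- h$region[sub2reg$region[match(names(h$subregion),
                                                sub2reg$subregion)]]
    lp <- lp + sum(stats::dnorm(h$subregion, parent_reg,
                                h$sd[["subregion"]], log = TRUE))
    sub_mean <- h$subregion[meta$subregion[match(params$country$country_code,
                                                 meta$country_code)]]
    lp <- lp + sum(dtnorm_log(params$country[[k]], sub_mean,
                              h$sd[["country"]], lo, hi))
  }

  lp <- lp + stats::dnorm(params$beta, 0, pr$beta_sd, log = TRUE)
  for (blk in params$ar) {
    lp <- lp + (if (blk$rho >= 0 && blk$rho < pr$rho_max)
      -log(pr$rho_max) else -Inf)
    lp <- lp + dhalfnorm_log(blk$tau, pr$tau_scale)
  }
  lp <- lp + sum(dhalfnorm_log(params$error$nonsampling_sd,
                               cfg$error$nonsampling_prior_scale))
  nondhs <- setdiff(names(params$error$bias), "DHS")
  lp <- lp + sum(stats::dnorm(params$error$bias[nondhs], 0, pr$bias_sd,
                              log = TRUE))

  obs <- prepare_observations(data$surveys, cfg)
  trajs <- list()
  for (cc in params$country$country_code) {
    trajs[[cc]] <- country_trajectory_from_params(params, distortions, cc,
                                                  grid)
    lp <- lp + ar1_logdensity(distortions[[cc]]$delta_eta,
                              params$ar$eta$rho, params$ar$eta$tau)
    lp <- lp + ar1_logdensity(distortions[[cc]]$delta_u,
                              params$ar$unmet$rho, params$ar$unmet$tau)
  }
  for (i in seq_len(nrow(obs))) {
    lp <- lp + observation_loglik(obs[i, ], trajs[[obs$country_code[i]]],
                                  params$error)
  }
  emu <- data$service_stats
  for (cc in unique(emu$country_code)) {
    sel <- emu[emu$country_code == cc, ]
    lp <- lp + withCallingHandlers(
      service_stat_loglik(sel$year, sel$emu, trajs[[cc]],
                          cfg$emu$variance),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  lp
}
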