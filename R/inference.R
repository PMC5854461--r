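# MCMC inference. The sampler is JAGS (via rjags), the standard engine for
# this model class; the program below states the same joint density as
# joint_logposterior() in the centered hierarchical parameterisation.

jags_model_string <- function(has_emu, fixed_sigma = FALSE) {
  sig_lines <- if (fixed_sigma) '' else '
    sig_r[k] ~ dnorm(0, prec_lvl) T(0,)
    sig_s[k] ~ dnorm(0, prec_lvl) T(0,)
    sig_c[k] ~ dnorm(0, prec_lvl) T(0,)'
  paste0('
model {
  # hierarchy: world -> region -> subregion -> country, per parameter k
  for (k in 1:7) {
    w[k] ~ dnorm(pm[k], 1 / (psd[k] * psd[k])) T(lb[k], ub[k])', sig_lines, '
    for (r in 1:R) { mr[k, r] ~ dnorm(w[k], 1 / (sig_r[k] * sig_r[k])) }
    for (s in 1:S) {
      ms[k, s] ~ dnorm(mr[k, reg[s]], 1 / (sig_s[k] * sig_s[k]))
    }
    for (c in 1:C) {
      pc_raw[k, c] ~ dnorm(ms[k, sub[c]],
                           1 / (sig_c[k] * sig_c[k])) T(lb[k], ub[k])
    }
  }
  beta ~ dnorm(0, 1 / (beta_sd * beta_sd))
  rho ~ dunif(0, rho_max)
  tau ~ dnorm(0, prec_tau) T(0,)
  rho_u ~ dunif(0, rho_max)
  tau_u ~ dnorm(0, prec_tau) T(0,)
  prec_d <- 1 / (tau * tau * (1 - rho * rho))
  prec_du <- 1 / (tau_u * tau_u * (1 - rho_u * rho_u))

  for (c in 1:C) {
    ptilde[c] <- ilogit(pc_raw[1, c])
    omega[c] <- exp(pc_raw[2, c])
    Om[c] <- pc_raw[3, c]
    rtilde[c] <- ilogit(pc_raw[4, c])
    psi[c] <- exp(pc_raw[5, c])
    Xi[c] <- pc_raw[6, c]
    alpha[c] <- pc_raw[7, c]

    for (t in 1:T) {
      # clamp away from exact 0/1 so the logit stays finite even when a
      # burn-in excursion makes exp() overflow
      curve[c, t] <- ptilde[c] / (1 + exp(-omega[c] * (yr[t] - Om[c])))
      lcurve[c, t] <- logit(max(min(curve[c, t], 1 - 1.0E-12), 1.0E-12))
      shp[c, t] <- rtilde[c] / (1 + exp(-psi[c] * (yr[t] - Xi[c])))
    }
    delta[c, 1] ~ dnorm(0, 1 / (tau * tau))
    for (t in 2:(T - 1)) {
      delta[c, t] ~ dnorm(rho * delta[c, t - 1], prec_d)
    }
    du[c, 1] ~ dnorm(0, 1 / (tau_u * tau_u))
    for (t in 2:T) { du[c, t] ~ dnorm(rho_u * du[c, t - 1], prec_du) }

    eta[c, 1] <- lcurve[c, 1]
    for (t in 2:T) {
      eta[c, t] <- eta[c, t - 1] + (lcurve[c, t] - lcurve[c, t - 1]) +
                   delta[c, t - 1]
    }
    for (t in 1:T) {
      u[c, t] <- alpha[c] + beta * eta[c, t] + du[c, t]
      P[c, t, 1] <- ilogit(eta[c, t])
      P[c, t, 2] <- P[c, t, 1] * shp[c, t]
      P[c, t, 3] <- P[c, t, 1] - P[c, t, 2]
      P[c, t, 4] <- (1 - P[c, t, 1]) * ilogit(u[c, t])
    }
  }

  # measurement error: per-source non-sampling SD and bias (DHS = 0)
  for (j in 1:6) { sig_ns[j] ~ dnorm(0, prec_ns) T(0,) }
  bias[1] <- 0
  for (j in 2:6) { bias[j] ~ dnorm(0, 1 / (bias_sd * bias_sd)) }

  for (i in 1:n_obs) {
    pobs[i] <- inprod(W[i, 1:T], P[oc[i], 1:T, oind[i]])
    mu_obs[i] <- logit(max(min(pobs[i], 1 - 1.0E-12), 1.0E-12)) +
                 bias[osrc[i]]
    z[i] ~ dnorm(mu_obs[i],
                 1 / (vs[i] + sig_ns[osrc[i]] * sig_ns[osrc[i]]))
  }
', if (has_emu) '
  for (j in 1:n_emu) {
    mue[j] <- logit(max(min(P[ec[j], ei2[j], 2], 1 - 1.0E-12), 1.0E-12)) -
              logit(max(min(P[ec[j], ei1[j], 2], 1 - 1.0E-12), 1.0E-12))
    dze[j] ~ dnorm(mue[j], prec_emu)
  }
' else '', '
}
')
}

jags_data <- function(data, cfg, grid) {
  meta <- data$meta
  countries <- meta$country_code
  subregions <- unique(meta$subregion)
  regions <- unique(meta$region)
  sub2reg <- unique(meta[, c("subregion", "region")])

  obs <- prepare_observations(data$surveys, cfg)
  W <- t(vapply(seq_len(nrow(obs)), function(i) {
    period_weights(obs$period_start[i], obs$period_end[i], grid)
  }, numeric(length(grid))))

  pr <- cfg$priors
  pm <- c(pr$logit_ptilde$mean, pr$log_omega$mean, pr$midpoint$mean,
          pr$logit_rtilde$mean, pr$log_psi$mean, pr$share_midpoint$mean,
          pr$alpha$mean)
  psd <- c(pr$logit_ptilde$sd, pr$log_omega$sd, pr$midpoint$sd,
           pr$logit_rtilde$sd, pr$log_psi$sd, pr$share_midpoint$sd,
           pr$alpha$sd)
  big <- 1e6
  lb <- c(pr$logit_ptilde$lower, -big, -big, pr$logit_rtilde$lower,
          -big, -big, -big)
  ub <- c(pr$logit_ptilde$upper, big, big, pr$logit_rtilde$upper,
          big, big, big)

  fixed_sigma <- !is.null(pr$level_sd_fixed)
  jd <- list(
    C = length(countries), S = length(subregions), R = length(regions),
    T = length(grid), yr = grid,
    sub = match(meta$subregion, subregions),
    reg = match(sub2reg$region, regions),
    pm = pm, psd = psd, lb = lb, ub = ub,
    prec_lvl = 1 / pr$level_sd_scale^2,
    prec_tau = 1 / pr$tau_scale^2,
    prec_ns = 1 / cfg$error$nonsampling_prior_scale^2,
    beta_sd = pr$beta_sd, rho_max = pr$rho_max, bias_sd = pr$bias_sd,
    n_obs = nrow(obs),
    oc = match(obs$country_code, countries),
    oind = match(obs$indicator, fpem_indicators),
    osrc = match(obs$source_type, fpem_source_types),
    z = obs$z, vs = obs$v_sampling, W = W
  )

  emu <- data$service_stats
  ec <- ei1 <- ei2 <- integer(0); dze <- numeric(0)
  for (cc in unique(emu$country_code)) {
    sel <- emu[emu$country_code == cc, ]
    sel <- sel[order(sel$year), ]
    if (nrow(sel) < 2) {
      warning("EMU series for ", cc, " has fewer than 2 points; ignored",
              call. = FALSE)
      next
    }
    idx <- match(floor(sel$year), grid)
    if (anyNA(idx)) stop_fpem("EMU year outside the grid for ", cc)
    k <- nrow(sel) - 1
    ec <- c(ec, rep(match(cc, countries), k))
    ei1 <- c(ei1, idx[-nrow(sel)])
    ei2 <- c(ei2, idx[-1])
    dze <- c(dze, diff(logit(sel$emu)))
  }
  if (length(dze) > 0) {
    jd <- c(jd, list(n_emu = length(dze), ec = ec, ei1 = ei1, ei2 = ei2,
                     dze = dze, prec_emu = 1 / cfg$emu$variance))
  }
  if (fixed_sigma) {
    jd$prec_lvl <- NULL
    jd$sig_r <- jd$sig_s <- jd$sig_c <- rep(pr$level_sd_fixed, 7)
  }
  list(jags = jd, obs = obs, countries = countries,
       has_emu = length(dze) > 0, fixed_sigma = fixed_sigma)
}

jags_inits <- function(jd, fit_cfg, fixed_sigma = FALSE) {
  pm <- jd$pm
  lapply(seq_len(fit_cfg$n_chains), function(ch) {
    jit <- 0.05 * (ch - 1)
    sig_init <- if (fixed_sigma) NULL else rep(0.2, 7)
    list(
      w = pm + jit,
      sig_r = sig_init, sig_s = sig_init, sig_c = sig_init,
      mr = matrix(pm + jit, 7, jd$R),
      ms = matrix(pm + jit, 7, jd$S),
      pc_raw = matrix(pm + jit, 7, jd$C),
      beta = 0, rho = 0.3, tau = 0.05, rho_u = 0.3, tau_u = 0.05,
      delta = matrix(0, jd$C, jd$T - 1), du = matrix(0, jd$C, jd$T),
      sig_ns = rep(0.05, 6), bias = c(NA, rep(0, 5)),
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = sub_seed(fit_cfg$seed, ch)
    )
  })
}

scalar_monitors <- c("w", "sig_r", "sig_s", "sig_c", "pc_raw", "beta",
                     "rho", "tau", "rho_u", "tau_u", "sig_ns", "bias")

#' Fit the model by MCMC
#'
#' Draws from the joint posterior of all country trajectories and model
#' parameters. Results are reproducible bitwise for identical data,
#' configuration and seed. Non-convergence (any split R-hat >= 1.1 among
#' the monitored parameters) is reported via `diagnostics$converged` and a
#' warning, never an error, so downstream pipelines keep partial results.
#'
#' @param data an [fpem_dataset]; must pass [validate_dataset()].
#' @param model_cfg an [fpem_config()].
#' @param fit_cfg a [fit_config()].
#' @param quiet suppress JAGS progress output.
#' @return object of class `fpem_fit`: list with `draws` (an `fpem_draws`:
#'   array `prop` of dimension draws x countries x years x 4 on the
#'   proportion scale, plus `params`, `chain`, `countries`, `years`) and
#'   `diagnostics` (see [check_convergence()]).
#' @export
fit_fpem <- function(data, model_cfg = fpem_config(),
                     fit_cfg = fit_config(), quiet = TRUE) {
  issues <- validate_dataset(data)
  if (nrow(issues) > 0)
    stop_fpem("dataset fails validation (", nrow(issues), " issue(s))")
  grid <- seq(model_cfg$grid$year_min, model_cfg$grid$year_max)
  prep <- jags_data(data, model_cfg, grid)
  jd <- prep$jags

  model_txt <- jags_model_string(prep$has_emu, prep$fixed_sigma)
  n_adapt <- max(50L, fit_cfg$n_warmup %/% 2L)
  monitors <- if (prep$fixed_sigma) {
    setdiff(scalar_monitors, c("sig_r", "sig_s", "sig_c"))
  } else scalar_monitors
  jm <- rjags::jags.model(
    textConnection(model_txt), data = jd,
    inits = jags_inits(jd, fit_cfg, prep$fixed_sigma),
    n.chains = fit_cfg$n_chains, n.adapt = n_adapt, quiet = quiet
  )
  stats::update(jm, n.iter = max(1L, fit_cfg$n_warmup - n_adapt),
                progress.bar = "none")
  samp <- rjags::coda.samples(
    jm, variable.names = c("P", monitors),
    n.iter = fit_cfg$n_samples * fit_cfg$thin, thin = fit_cfg$thin,
    progress.bar = "none"
  )

  vn <- colnames(samp[[1]])
  p_cols <- grep("^P\\[", vn)
  s_cols <- setdiff(seq_along(vn), p_cols)
  n_chain <- length(samp)
  n_iter <- nrow(samp[[1]])

  # assemble the proportion array: draws x country x year x quantity
  idx <- do.call(rbind, lapply(
    regmatches(vn[p_cols], regexec("^P\\[(\\d+),(\\d+),(\\d+)\\]$",
                                   vn[p_cols])),
    function(m) as.integer(m[2:4])
  ))
  C <- jd$C; TT <- jd$T
  prop <- array(NA_real_,
                dim = c(n_chain * n_iter, C, TT, 4),
                dimnames = list(NULL, prep$countries, grid,
                                fpem_quantities))
  for (ch in seq_len(n_chain)) {
    rows <- (ch - 1L) * n_iter + seq_len(n_iter)
    m <- as.matrix(samp[[ch]])[, p_cols, drop = FALSE]
    for (jj in seq_along(p_cols)) {
      k3 <- idx[jj, 3]
      prop[rows, idx[jj, 1], idx[jj, 2], k3] <- m[, jj]
    }
  }

  param_chains <- lapply(samp, function(s) as.matrix(s)[, s_cols,
                                                        drop = FALSE])
  params <- do.call(rbind, param_chains)
  chain <- rep(seq_len(n_chain), each = n_iter)

  diagnostics <- check_convergence(param_chains)
  if (!attr(diagnostics, "converged"))
    warning("MCMC has not converged by split R-hat < 1.1; ",
            "returning draws anyway", call. = FALSE)

  draws <- structure(
    list(prop = prop, params = params, chain = chain,
         countries = prep$countries, years = grid,
         n_chains = n_chain, n_iter = n_iter),
    class = "fpem_draws"
  )
  structure(list(draws = draws, diagnostics = diagnostics,
                 fit_cfg = fit_cfg, model_cfg = model_cfg),
            class = "fpem_fit")
}

#' @export
print.fpem_fit <- function(x, ...) {
  cat("<fpem_fit>\n")
  cat("  countries:", length(x$draws$countries),
      " years:", length(x$draws$years),
      " draws:", dim(x$draws$prop)[1], "\n")
  cat("  converged:", attr(x$diagnostics, "converged"),
      " (max split R-hat ",
      round(max(x$diagnostics$rhat, na.rm = TRUE), 3), ")\n", sep = "")
  invisible(x)
}

#' @export
print.fpem_draws <- function(x, ...) {
  cat("<fpem_draws> ", dim(x$prop)[1], " draws x ",
      length(x$countries), " countries x ", length(x$years),
      " years x 4 quantities\n", sep = "")
  invisible(x)
}

#' Extract posterior draws at one country/year/quantity
#'
#' @param draws an `fpem_draws` (or `fpem_fit`).
#' @param country country code.
#' @param year grid year.
#' @param quantity one of [fpem_quantities].
#' @return numeric vector of posterior draws.
#' @export
draws_at <- function(draws, country, year, quantity = "modern_cpr") {
  if (inherits(draws, "fpem_fit")) draws <- draws$draws
  ci <- match(country, draws$countries)
  yi <- match(year, draws$years)
  if (is.na(ci)) stop_fpem("unknown country ", country)
  if (is.na(yi)) stop_fpem("year ", year, " off the grid")
  draws$prop[, ci, yi, quantity]
}

#' Tidy posterior trajectory draws
#'
#' @param draws an `fpem_draws` or `fpem_fit`.
#' @return tibble `draw`, `country_code`, `year`, `quantity`, `value`.
#' @export
draws_to_table <- function(draws) {
  if (inherits(draws, "fpem_fit")) draws <- draws$draws
  nd <- dim(draws$prop)[1]
  out <- expand.grid(
    draw = seq_len(nd), country_code = draws$countries,
    year = draws$years, quantity = fpem_quantities,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out$value <- as.vector(draws$prop)
  tibble::as_tibble(out)
}

#' Persist posterior draws to CSV
#'
#' One row per (draw, country, year, quantity); [read_draws()] restores
#' an `fpem_draws` (trajectory array only).
#'
#' @param draws an `fpem_draws` or `fpem_fit`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  readr::write_csv(draws_to_table(draws), path)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    draw = "i", country_code = "c", year = "d", quantity = "c",
    value = "d"
  ), progress = FALSE)
  countries <- unique(x$country_code)
  years <- sort(unique(x$year))
  nd <- max(x$draw)
  prop <- array(
    NA_real_, dim = c(nd, length(countries), length(years), 4),
    dimnames = list(NULL, countries, years, fpem_quantities)
  )
  prop[cbind(x$draw, match(x$country_code, countries),
             match(x$year, years), match(x$quantity, fpem_quantities))] <-
    x$value
  structure(
    list(prop = prop, params = NULL, chain = NULL, countries = countries,
         years = years, n_chains = NA_integer_, n_iter = nd),
    class = "fpem_draws"
  )
}

# ---------------------------------------------------------------------------
# Convergence diagnostics

split_rhat_one <- function(chains) {
  halves <- list()
  for (x in chains) {
    n <- length(x) %/% 2
    halves[[length(halves) + 1]] <- x[seq_len(n)]
    halves[[length(halves) + 1]] <- x[n + seq_len(n)]
  }
  n <- length(halves[[1]])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W < 1e-300) {
    return(if (is.finite(B) && B < 1e-300) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split R-hat and effective sample size per parameter
#'
#' Each chain is split in half; R-hat compares between- and within-half
#' variances (values near 1 indicate mixing). ESS comes from
#' [coda::effectiveSize()]. At least two chains are required.
#'
#' @param chains list of per-chain draw matrices (iterations x
#'   parameters) with identical column names, or a [coda::mcmc.list].
#' @return tibble with `param`, `rhat`, `ess`; attribute `converged` is
#'   `TRUE` iff all finite R-hat < 1.1.
#' @export
check_convergence <- function(chains) {
  if (inherits(chains, "mcmc.list")) chains <- lapply(chains, as.matrix)
  if (length(chains) < 2)
    stop_fpem("convergence diagnostics require at least 2 chains")
  pn <- colnames(chains[[1]])
  rhat <- vapply(seq_along(pn), function(j) {
    split_rhat_one(lapply(chains, function(m) m[, j]))
  }, numeric(1))
  pooled <- do.call(rbind, chains)
  ess <- as.numeric(coda::effectiveSize(pooled))
  out <- tibble::tibble(param = pn, rhat = rhat, ess = ess)
  # constant-and-equal chains (e.g. the pinned DHS bias) give rhat = 1;
  # constant-but-different chains give Inf and fail the check
  attr(out, "converged") <- all(rhat < 1.1, na.rm = TRUE)
  out
}
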