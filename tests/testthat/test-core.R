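test_that("logistic curve hits its midpoint, limits and a fixed value", {
  p <- list(p_tilde = 0.8, omega = 0.2, midpoint = 2000)
  expect_equal(logistic_curve(2000, p), 0.4)                  # half asymptote
  expect_equal(logistic_curve(2010, p), 0.8 / (1 + exp(-2)))  # 0.70463...
  expect_equal(logistic_curve(2010, p), 0.7046377, tolerance = 1e-7)
  expect_lt(logistic_curve(1800, p), 1e-15)
  # strictly increasing and bounded by the asymptote
  tt <- seq(1950, 2050, by = 5)
  v <- logistic_curve(tt, p)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 0.8))
})

test_that("expected increments telescope and vanish for a flat curve", {
  p <- list(p_tilde = 0.8, omega = 0.2, midpoint = 2000)
  grid <- 1990:2020
  d <- expected_increments(p, grid)
  expect_true(all(d > 0))
  expect_equal(sum(d),
               qlogis(logistic_curve(2020, p)) -
                 qlogis(logistic_curve(1990, p)))
  expect_equal(
    expected_increments(p, 2000:2001),
    qlogis(logistic_curve(2001, p)) - qlogis(0.4)
  )
  flat <- expected_increments(list(p_tilde = 0.8, omega = 1e-9,
                                   midpoint = 2000), grid)
  expect_true(all(abs(flat) < 1e-6))
})

test_that("AR(1) log density matches the dense multivariate-normal oracle", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    rho <- runif(1, -0.9, 0.9)
    tau <- runif(1, 0.02, 0.5)
    x <- rnorm(n, 0, tau)
    expect_equal(ar1_logdensity(x, rho, tau),
                 mvn_ar1_logdensity(x, rho, tau), tolerance = 1e-8)
  }
  # independence limit
  x <- rnorm(6, 0, 0.1)
  expect_equal(ar1_logdensity(x, 0, 0.1),
               sum(dnorm(x, 0, 0.1, log = TRUE)))
  expect_error(ar1_logdensity(x, 1.0, 0.1), "rho")
  expect_error(ar1_logdensity(x, 0.5, 0), "tau")
})

test_that("zero-distortion trajectories reproduce the expected curves", {
  grid <- 1990:2020
  log_p <- list(p_tilde = 0.75, omega = 0.15, midpoint = 2005)
  shr_p <- list(p_tilde = 0.9, omega = 0.1, midpoint = 2000)
  un <- list(alpha = -0.6, beta = -0.4)
  traj <- build_trajectory(log_p, shr_p, un,
                           delta_eta = rep(0, length(grid) - 1),
                           delta_u = rep(0, length(grid)), grid = grid)
  expect_equal(traj$eta, qlogis(logistic_curve(grid, log_p)))
  expect_equal(traj$s, qlogis(logistic_curve(grid, shr_p)))
  expect_equal(traj$u, un$alpha + un$beta * traj$eta)
  # monotone increasing total prevalence
  expect_true(all(diff(plogis(traj$eta)) > 0))
  # beta = 0, no distortion: u constant at alpha
  traj0 <- build_trajectory(log_p, shr_p, list(alpha = -0.6, beta = 0),
                            rep(0, length(grid) - 1), rep(0, length(grid)),
                            grid)
  expect_equal(traj0$u, rep(-0.6, length(grid)))
})

test_that("distortions accumulate additively and telescope exactly", {
  grid <- 2000:2010
  log_p <- list(p_tilde = 0.7, omega = 0.2, midpoint = 2003)
  shr_p <- list(p_tilde = 0.8, omega = 0.1, midpoint = 2005)
  un <- list(alpha = 0, beta = 0)
  k <- 0.03
  traj <- build_trajectory(log_p, shr_p, un,
                           delta_eta = rep(k, 10), delta_u = rep(0, 11),
                           grid)
  base <- qlogis(logistic_curve(grid, log_p))
  expect_equal(traj$eta, base + k * (grid - grid[1]))
  # telescoping with arbitrary distortions
  set.seed(8)
  de <- rnorm(10, 0, 0.05)
  traj2 <- build_trajectory(log_p, shr_p, un, de, rep(0, 11), grid)
  dstar <- expected_increments(log_p, grid)
  expect_equal(traj2$eta[11] - traj2$eta[1], sum(dstar + de))
  expect_error(
    build_trajectory(log_p, shr_p, un, rep(0, 3), rep(0, 11), grid),
    "delta_eta"
  )
})

test_that("reference-period weights partition the period over grid years", {
  grid <- 2000:2010
  expect_equal(period_weights(2005.5, 2005.5, grid),
               as.numeric(grid == 2005))
  w <- period_weights(2003.0, 2005.0, grid)
  expect_equal(w[grid %in% 2003:2004], c(0.5, 0.5))
  expect_equal(sum(w), 1)
  w2 <- period_weights(2003.25, 2004.75, grid)
  expect_equal(w2[grid %in% 2003:2004], c(0.5, 0.5))
  expect_error(period_weights(1980, 1981, grid), "overlap")
})

test_that("observation likelihood averages on the proportion scale", {
  err <- list(nonsampling_sd = c(DHS = 0.1), bias = c(DHS = 0))
  grid <- 2000:2001
  traj <- toy_trajectory(grid, total = c(0.30, 0.40))
  obs <- list(indicator = "total_cpr", period_start = 2000.0,
              period_end = 2002.0, z = qlogis(0.33), v_sampling = 0.0016,
              source_type = "DHS")
  # two-year period, equal overlap: model value 0.35 before logit
  expect_equal(
    observation_loglik(obs, traj, err),
    dnorm(qlogis(0.33), qlogis(0.35), sqrt(0.0016 + 0.01), log = TRUE)
  )
  # degenerate single-year period: plain normal log density
  obs1 <- modifyList(obs, list(period_start = 2000.5, period_end = 2000.5))
  expect_equal(
    observation_loglik(obs1, traj, err),
    dnorm(qlogis(0.33), qlogis(0.30), sqrt(0.0016 + 0.01), log = TRUE)
  )
  # constant trajectory: any period gives the single-year value
  trajc <- toy_trajectory(grid, total = c(0.30, 0.30))
  obs2 <- modifyList(obs, list(period_start = 2000.0, period_end = 2001.7))
  expect_equal(
    observation_loglik(obs2, trajc, err),
    dnorm(qlogis(0.33), qlogis(0.30), sqrt(0.0016 + 0.01), log = TRUE)
  )
  # source bias shifts the mean additively
  err_b <- list(nonsampling_sd = c(NATIONAL = 0.1),
                bias = c(NATIONAL = 0.2))
  obs3 <- modifyList(obs1, list(source_type = "NATIONAL"))
  expect_equal(
    observation_loglik(obs3, traj, err_b),
    dnorm(qlogis(0.33), qlogis(0.30) + 0.2, sqrt(0.0016 + 0.01),
          log = TRUE)
  )
})

test_that("service statistics inform through first differences only", {
  grid <- 2008:2012
  traj <- toy_trajectory(grid, total = c(0.30, 0.32, 0.34, 0.36, 0.38))
  modern <- trajectory_proportions(traj)[, "modern_cpr"]
  # EMU exactly equal to model modern use: zero residuals
  ll <- service_stat_loglik(grid, modern, traj, variance_emu = 0.01)
  expect_equal(ll, sum(dnorm(rep(0, 4), 0, 0.1, log = TRUE)))
  # a constant level offset cancels entirely
  shifted <- plogis(qlogis(modern) + 0.4)
  expect_equal(service_stat_loglik(grid, shifted, traj, 0.01), ll)
  # a single point carries no information and warns
  expect_warning(
    ll1 <- service_stat_loglik(2010, 0.3, traj, 0.01),
    "fewer than 2"
  )
  expect_identical(ll1, 0)
})

test_that("the 2-SD outlier screen is strict at the boundary", {
  expect_true(flag_outliers(0.36, 0.30, 0.025))   # 0.06 > 0.05
  expect_false(flag_outliers(0.30, 0.30, 0.025))
  expect_false(flag_outliers(0.35, 0.30, 0.025))  # exactly 2 SD
  expect_error(flag_outliers(0.3, 0.3, 0), "projection_sd")
})

# ---------------------------------------------------------------------------
# joint log-posterior against an independent term-by-term oracle

toy_params <- function(meta, cfg) {
  hyper <- list()
  specs <- list(
    logit_ptilde = cfg$priors$logit_ptilde, log_omega = cfg$priors$log_omega,
    midpoint = cfg$priors$midpoint, logit_rtilde = cfg$priors$logit_rtilde,
    log_psi = cfg$priors$log_psi, share_midpoint = cfg$priors$share_midpoint,
    alpha = cfg$priors$alpha
  )
  vals <- list(logit_ptilde = 0.6, log_omega = log(0.12), midpoint = 2002,
               logit_rtilde = 0.4, log_psi = log(0.09),
               share_midpoint = 1998, alpha = -0.4)
  for (k in names(specs)) {
    hyper[[k]] <- list(
      world = vals[[k]],
      region = setNames(vals[[k]] + 0.05, "R1"),
      subregion = setNames(vals[[k]] - 0.03, "S1"),
      sd = c(region = 0.3, subregion = 0.25, country = 0.2)
    )
  }
  country <- tibble::tibble(country_code = meta$country_code)
  for (k in names(specs)) {
    country[[k]] <- vals[[k]] + c(0.04, -0.06)[seq_len(nrow(meta))]
  }
  list(
    hyper = hyper, country = country, beta = -0.3,
    ar = list(eta = list(rho = 0.4, tau = 0.06),
              unmet = list(rho = 0.3, tau = 0.08)),
    error = list(
      nonsampling_sd = c(DHS = 0.05, MICS = 0.08, PMA = 0.08, RHS = 0.08,
                         NATIONAL = 0.1, OTHER = 0.12),
      bias = c(DHS = 0, MICS = -0.05, PMA = 0.05, RHS = 0, NATIONAL = 0.1,
               OTHER = -0.1)
    )
  )
}

test_that("joint log-posterior equals the term-sum oracle on a toy", {
  cfg <- fpem_config(grid = list(year_min = 2000, year_max = 2012))
  grid <- 2000:2012
  surveys <- toy_surveys()
  surveys$sampling_se[3] <- 0.02  # avoid imputation in the oracle
  d <- fpem_dataset(surveys, toy_meta(), toy_populations(),
                    service_stats = tibble::tibble(
                      country_code = "AAA", year = c(2009, 2010, 2011),
                      emu = c(0.21, 0.23, 0.24)
                    ))
  params <- toy_params(d$meta, cfg)
  set.seed(33)
  distortions <- list(
    AAA = list(delta_eta = rnorm(12, 0, 0.03), delta_u = rnorm(13, 0, 0.04)),
    BBB = list(delta_eta = rnorm(12, 0, 0.03), delta_u = rnorm(13, 0, 0.04))
  )
  got <- joint_logposterior(params, distortions, d, cfg)
  expect_true(is.finite(got))

  # --- independent recomputation, term by term -------------------------
  pr <- cfg$priors
  tn <- function(x, m, s, lo = -Inf, hi = Inf) {
    dnorm(x, m, s, log = TRUE) - log(pnorm(hi, m, s) - pnorm(lo, m, s))
  }
  hn <- function(x, s) log(2) + dnorm(x, 0, s, log = TRUE)
  want <- 0
  specs <- list(
    logit_ptilde = pr$logit_ptilde, log_omega = pr$log_omega,
    midpoint = pr$midpoint, logit_rtilde = pr$logit_rtilde,
    log_psi = pr$log_psi, share_midpoint = pr$share_midpoint,
    alpha = pr$alpha
  )
  for (k in names(specs)) {
    h <- params$hyper[[k]]; sp <- specs[[k]]
    lo <- if (is.null(sp$lower)) -Inf else sp$lower
    hi <- if (is.null(sp$upper)) Inf else sp$upper
    want <- want + tn(h$world, sp$mean, sp$sd, lo, hi) +
      sum(hn(h$sd, pr$level_sd_scale)) +
      dnorm(h$region[["R1"]], h$world, h$sd[["region"]], log = TRUE) +
      dnorm(h$subregion[["S1"]], h$region[["R1"]], h$sd[["subregion"]],
            log = TRUE) +
      sum(tn(params$country[[k]], h$subregion[["S1"]], h$sd[["country"]],
             lo, hi))
  }
  want <- want + dnorm(params$beta, 0, pr$beta_sd, log = TRUE)
  for (blk in params$ar) want <- want - log(pr$rho_max) + hn(blk$tau, pr$tau_scale)
  want <- want + sum(hn(params$error$nonsampling_sd,
                        cfg$error$nonsampling_prior_scale))
  want <- want + sum(dnorm(params$error$bias[-1], 0, pr$bias_sd, log = TRUE))
  for (cc in c("AAA", "BBB")) {
    want <- want +
      mvn_ar1_logdensity(distortions[[cc]]$delta_eta,
                         params$ar$eta$rho, params$ar$eta$tau) +
      mvn_ar1_logdensity(distortions[[cc]]$delta_u,
                         params$ar$unmet$rho, params$ar$unmet$tau)
  }
  # trajectories and likelihood terms
  props <- list()
  for (cc in c("AAA", "BBB")) {
    row <- params$country[params$country$country_code == cc, ]
    eta <- numeric(13); s <- numeric(13)
    pt <- plogis(row$logit_ptilde); om <- exp(row$log_omega)
    rt <- plogis(row$logit_rtilde); ps <- exp(row$log_psi)
    curve <- pt / (1 + exp(-om * (grid - row$midpoint)))
    eta[1] <- qlogis(curve[1])
    for (t in 2:13) {
      eta[t] <- eta[t - 1] + (qlogis(curve[t]) - qlogis(curve[t - 1])) +
        distortions[[cc]]$delta_eta[t - 1]
    }
    shp <- rt / (1 + exp(-ps * (grid - row$share_midpoint)))
    u <- row$alpha + params$beta * eta + distortions[[cc]]$delta_u
    tot <- plogis(eta)
    props[[cc]] <- cbind(total_cpr = tot, modern_cpr = tot * shp,
                         trad_cpr = tot * (1 - shp),
                         unmet_any = (1 - tot) * plogis(u))
  }
  for (i in seq_len(nrow(surveys))) {
    o <- surveys[i, ]
    w <- pmax(0, pmin(o$period_end, grid + 1) - pmax(o$period_start, grid))
    if (o$period_start == o$period_end) w <- as.numeric(grid == floor(o$period_start))
    w <- w / sum(w)
    mp <- sum(w * props[[o$country_code]][, o$indicator])
    vtot <- (o$sampling_se / (o$value * (1 - o$value)))^2 +
      params$error$nonsampling_sd[[o$source_type]]^2
    want <- want + dnorm(qlogis(o$value),
                         qlogis(mp) + params$error$bias[[o$source_type]],
                         sqrt(vtot), log = TRUE)
  }
  emu <- c(0.21, 0.23, 0.24)
  mod <- props$AAA[match(c(2009, 2010, 2011), grid), "modern_cpr"]
  want <- want + sum(dnorm(diff(qlogis(emu)), diff(qlogis(mod)),
                           sqrt(cfg$emu$variance), log = TRUE))
  expect_equal(got, want, tolerance = 1e-10)

  # duplicating an observation adds exactly its log likelihood
  d2 <- fpem_dataset(dplyr::bind_rows(surveys, surveys[1, ]), toy_meta(),
                     toy_populations(), d$service_stats)
  got2 <- joint_logposterior(params, distortions, d2, cfg)
  o <- prepare_observations(surveys, cfg)[1, ]
  traj <- build_trajectory(
    list(p_tilde = plogis(params$country$logit_ptilde[1]),
         omega = exp(params$country$log_omega[1]),
         midpoint = params$country$midpoint[1]),
    list(p_tilde = plogis(params$country$logit_rtilde[1]),
         omega = exp(params$country$log_psi[1]),
         midpoint = params$country$share_midpoint[1]),
    list(alpha = params$country$alpha[1], beta = params$beta),
    distortions$AAA$delta_eta, distortions$AAA$delta_u, grid
  )
  expect_equal(got2 - got, observation_loglik(o, traj, params$error),
               tolerance = 1e-10)

  # invariant to observation ordering
  perm <- sample(nrow(surveys))
  d3 <- fpem_dataset(surveys[perm, ], toy_meta(), toy_populations(),
                     d$service_stats)
  expect_equal(joint_logposterior(params, distortions, d3, cfg), got,
               tolerance = 1e-12)
})
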