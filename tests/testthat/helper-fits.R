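# Cached MCMC fits shared across test files (each is computed at most once
# per test run). Scales: the calibration study uses the 16-country "small"
# scenario on a 1980--2025 grid with 2 chains x 500 warmup + 500 samples;
# smoke tests use the 3-country "tiny" scenario on a short grid.

.fit_cache <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fit_cache$small)) {
    cfg <- fpem_config(grid = list(year_min = 1980, year_max = 2025))
    sim <- simulate_dataset("small", seed = 5, model_cfg = cfg)
    fit <- suppressWarnings(
      fit_fpem(sim$data, cfg,
               fit_config(n_chains = 2, n_warmup = 500, n_samples = 500,
                          seed = 11))
    )
    .fit_cache$small <- list(cfg = cfg, sim = sim, fit = fit)
  }
  .fit_cache$small
}

tiny_study <- function() {
  if (is.null(.fit_cache$tiny)) {
    cfg <- fpem_config(grid = list(year_min = 1990, year_max = 2015))
    sim <- simulate_dataset("tiny", seed = 3, model_cfg = cfg)
    fit <- suppressWarnings(
      fit_fpem(sim$data, cfg,
               fit_config(n_chains = 2, n_warmup = 150, n_samples = 150,
                          seed = 21))
    )
    .fit_cache$tiny <- list(cfg = cfg, sim = sim, fit = fit)
  }
  .fit_cache$tiny
}
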