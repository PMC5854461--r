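# Hand-built toy inputs shared across test files.

toy_meta <- function() {
  tibble::tibble(
    country_code = c("AAA", "BBB"),
    name = c("Alpha", "Beta"),
    subregion = "S1", region = "R1",
    fp2020_commitment = c(TRUE, FALSE)
  )
}

toy_surveys <- function() {
  tibble::tibble(
    country_code = c("AAA", "AAA", "BBB", "BBB"),
    indicator = c("total_cpr", "modern_cpr", "total_cpr", "unmet_any"),
    value = c(0.40, 0.30, 0.25, 0.20),
    source_type = c("DHS", "DHS", "MICS", "NATIONAL"),
    period_start = c(2005.5, 2005.5, 2010.5, 2012.0),
    period_end = c(2005.5, 2005.5, 2011.5, 2012.0),
    sampling_se = c(0.010, 0.012, NA, 0.02)
  )
}

toy_populations <- function(years = 2000:2020) {
  dplyr::bind_rows(
    tibble::tibble(country_code = "AAA", year = years, mwra = 1e6),
    tibble::tibble(country_code = "BBB", year = years, mwra = 3e6)
  )
}

toy_dataset <- function() {
  fpem_dataset(
    surveys = toy_surveys(),
    meta = toy_meta(),
    populations = toy_populations(),
    service_stats = tibble::tibble(
      country_code = "AAA", year = c(2010, 2011, 2012),
      emu = c(0.20, 0.22, 0.25)
    )
  )
}

# a deterministic trajectory with chosen total prevalences, for
# observation-likelihood arithmetic
toy_trajectory <- function(grid, total, share = 0.6, unmet_u = -0.8) {
  structure(
    list(grid = grid, eta = qlogis(total),
         s = rep(qlogis(share), length(grid)),
         u = rep(unmet_u, length(grid))),
    class = "fpem_trajectory"
  )
}

# dense multivariate-normal log density of a stationary AR(1) series:
# independent oracle for ar1_logdensity
mvn_ar1_logdensity <- function(x, rho, tau) {
  n <- length(x)
  S <- tau^2 * rho^abs(outer(seq_len(n), seq_len(n), "-"))
  L <- chol(S)
  q <- sum(backsolve(L, x, transpose = TRUE)^2)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + q)
}
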