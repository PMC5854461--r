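# Small numeric helpers shared across modules.

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Report-table rounding: ties go away from zero (2.25 -> 2.3, -2.25 ->
#' -2.3), unlike [round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic sub-seed derivation: keeps every derived seed a valid
# 32-bit integer regardless of the master seed.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647L) * 48271 + k) %% 2147483629L
}

# log density of a half-normal with scale `scale`, support x >= 0
dhalfnorm_log <- function(x, scale) {
  ifelse(x < 0, -Inf, log(2) + stats::dnorm(x, 0, scale, log = TRUE))
}

# log density of a normal truncated to [lower, upper]
dtnorm_log <- function(x, mean, sd, lower = -Inf, upper = Inf) {
  ifelse(
    x < lower | x > upper,
    -Inf,
    stats::dnorm(x, mean, sd, log = TRUE) -
      log(stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd))
  )
}

stop_fpem <- function(...) stop(..., call. = FALSE)
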