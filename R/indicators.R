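# Reported indicators, computed draw-wise before any summarisation so that
# uncertainty intervals have a joint-posterior interpretation; ratios of
# summaries are *not* used (the plug-in identity on published medians holds
# only approximately).

#' Derive reported indicators per posterior draw
#'
#' From each draw's total, modern and traditional prevalence and unmet
#' need for any method, derives unmet need for modern methods
#' (`unmet_any + trad_cpr`) and demand satisfied with modern methods
#' (`mcpr / (mcpr + unmet_modern)`). With populations supplied, also the
#' number of modern-method users (persons).
#'
#' @param draws an `fpem_draws` or `fpem_fit`.
#' @param populations optional populations table (`country_code`, `year`,
#'   `mwra`) to add `users`.
#' @param years optional subset of grid years to keep (default: all).
#' @return tibble with columns `draw`, `country_code`, `year`, `mcpr`,
#'   `trad_cpr`, `unmet_any`, `unmet_modern`, `demand_satisfied` and
#'   optionally `users`.
#' @export
derive_indicators <- function(draws, populations = NULL, years = NULL) {
  if (inherits(draws, "fpem_fit")) draws <- draws$draws
  yrs <- years %||% draws$years
  yi <- match(yrs, draws$years)
  if (anyNA(yi)) stop_fpem("requested year(s) off the grid")
  nd <- dim(draws$prop)[1]
  grid_tbl <- expand.grid(
    draw = seq_len(nd),
    country_code = draws$countries,
    year = yrs,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  sub <- draws$prop[, , yi, , drop = FALSE]
  out <- tibble::as_tibble(grid_tbl)
  out$mcpr <- as.vector(sub[, , , "modern_cpr"])
  out$trad_cpr <- as.vector(sub[, , , "trad_cpr"])
  out$unmet_any <- as.vector(sub[, , , "unmet_any"])
  out$unmet_modern <- out$unmet_any + out$trad_cpr
  denom <- out$mcpr + out$unmet_modern
  if (any(denom == 0))
    stop_fpem("demand satisfied undefined: mcpr + unmet_modern = 0")
  out$demand_satisfied <- out$mcpr / denom
  if (!is.null(populations)) {
    out <- dplyr::left_join(
      out, populations[, c("country_code", "year", "mwra")],
      by = c("country_code", "year")
    )
    if (anyNA(out$mwra))
      stop_fpem("population counts missing for some country-years")
    out$users <- out$mwra * out$mcpr
    out$mwra <- NULL
  }
  out
}

#' Posterior summary: median and 95% uncertainty interval
#'
#' Median and 2.5th / 97.5th percentiles with linear interpolation
#' between order statistics (quantile type 7).
#'
#' @param values numeric draws (at least one).
#' @return tibble with `median`, `lower`, `upper`.
#' @export
summarize_draws <- function(values) {
  if (length(values) == 0) stop_fpem("no draws to summarise")
  q <- stats::quantile(values, c(0.5, 0.025, 0.975), type = 7,
                       names = FALSE)
  tibble::tibble(median = q[1], lower = q[2], upper = q[3])
}

#' Additional users of modern methods between two years
#'
#' Per draw, the difference in the total number of modern-method users
#' between `y1` and `y0` across all countries in `ind`, using
#' deterministic population counts; summarised to a median and 95%
#' interval.
#'
#' @param ind indicator draws from [derive_indicators()].
#' @param populations populations table covering `y0` and `y1`.
#' @param y0,y1 grid years.
#' @return tibble `median`, `lower`, `upper` (persons).
#' @export
additional_users <- function(ind, populations, y0, y1) {
  cc <- unique(ind$country_code)
  for (y in c(y0, y1)) {
    have <- populations$country_code[populations$year == y]
    if (!all(cc %in% have))
      stop_fpem("population counts missing for year ", y)
  }
  sub <- ind[ind$year %in% c(y0, y1),
             c("draw", "country_code", "year", "mcpr")]
  sub <- dplyr::left_join(
    sub, populations[, c("country_code", "year", "mwra")],
    by = c("country_code", "year")
  )
  sub$users <- sub$mwra * sub$mcpr
  tot <- dplyr::summarise(
    dplyr::group_by(sub, .data$draw, .data$year),
    users = sum(.data$users), .groups = "drop"
  )
  per_draw <- tot$users[tot$year == y1] - tot$users[tot$year == y0]
  summarize_draws(per_draw)
}

#' Population-weighted aggregation of indicator draws
#'
#' Group prevalence per draw is the mwra-weighted mean of country
#' prevalences; users add exactly; demand satisfied is recomputed from
#' the aggregated mcpr and unmet_modern within each draw.
#'
#' @param ind indicator draws from [derive_indicators()].
#' @param populations populations table covering all country-years in
#'   `ind`.
#' @param grouping country-to-group map: named character vector
#'   (names = country codes) or a data frame with `country_code` and
#'   `group`. Default: one overall group `"all"`.
#' @return tibble shaped like `ind` with `group` replacing
#'   `country_code`.
#' @export
aggregate_indicators <- function(ind, populations, grouping = NULL) {
  cc <- unique(ind$country_code)
  if (is.null(grouping)) {
    grouping <- stats::setNames(rep("all", length(cc)), cc)
  }
  if (is.data.frame(grouping)) {
    grouping <- stats::setNames(grouping$group, grouping$country_code)
  }
  if (!all(cc %in% names(grouping)))
    stop_fpem("grouping missing for: ",
              paste(setdiff(cc, names(grouping)), collapse = ", "))
  x <- dplyr::left_join(
    ind, populations[, c("country_code", "year", "mwra")],
    by = c("country_code", "year")
  )
  if (anyNA(x$mwra))
    stop_fpem("population weights missing for some country-years")
  x$group <- unname(grouping[x$country_code])
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$draw, .data$group, .data$year),
    mcpr = sum(.data$mwra * .data$mcpr) / sum(.data$mwra),
    trad_cpr = sum(.data$mwra * .data$trad_cpr) / sum(.data$mwra),
    unmet_any = sum(.data$mwra * .data$unmet_any) / sum(.data$mwra),
    unmet_modern = sum(.data$mwra * .data$unmet_modern) / sum(.data$mwra),
    users = if ("users" %in% names(x)) sum(.data$users) else NA_real_,
    .groups = "drop"
  )
  out$demand_satisfied <- out$mcpr / (out$mcpr + out$unmet_modern)
  if (all(is.na(out$users))) out$users <- NULL
  out
}

#' Per-country changes between two years
#'
#' Draw-wise differences (`y1 - y0`) in mcpr, unmet need for modern
#' methods, demand satisfied and (with populations) users, summarised per
#' country. The positive-progress flag requires both the median mcpr
#' change and the median demand-satisfied change to be positive.
#'
#' @param ind indicator draws from [derive_indicators()].
#' @param y0,y1 grid years present in `ind`.
#' @param populations optional populations for the user change.
#' @return tibble per country: `<indicator>_change`,
#'   `<indicator>_change_lower/upper`, and `progress_positive`.
#' @export
change_table <- function(ind, y0, y1, populations = NULL) {
  for (y in c(y0, y1)) {
    if (!y %in% ind$year) stop_fpem("year ", y, " not in indicator draws")
  }
  if (!is.null(populations) && !"users" %in% names(ind)) {
    ind <- dplyr::left_join(
      ind, populations[, c("country_code", "year", "mwra")],
      by = c("country_code", "year")
    )
    ind$users <- ind$mwra * ind$mcpr
    ind$mwra <- NULL
  }
  vars <- intersect(c("mcpr", "unmet_modern", "demand_satisfied", "users"),
                    names(ind))
  a <- ind[ind$year == y0, c("draw", "country_code", vars)]
  b <- ind[ind$year == y1, c("draw", "country_code", vars)]
  m <- dplyr::left_join(a, b, by = c("draw", "country_code"),
                        suffix = c("_0", "_1"))
  rows <- lapply(split(m, m$country_code), function(g) {
    out <- tibble::tibble(country_code = g$country_code[1])
    for (v in vars) {
      s <- summarize_draws(g[[paste0(v, "_1")]] - g[[paste0(v, "_0")]])
      out[[paste0(v, "_change")]] <- s$median
      out[[paste0(v, "_change_lower")]] <- s$lower
      out[[paste0(v, "_change_upper")]] <- s$upper
    }
    out$progress_positive <- out$mcpr_change > 0 &
      out$demand_satisfied_change > 0
    out
  })
  dplyr::bind_rows(rows)
}
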