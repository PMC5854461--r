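# Reading, validating and writing the tabular inputs, plus the packaged
# transcriptions of the published report tables used as validation fixtures.

survey_cols <- c("country_code", "indicator", "value", "source_type",
                 "period_start", "period_end", "sampling_se")

#' Construct a dataset
#'
#' Bundle the four input tables into a validated dataset object. Surveys
#' carry one row per observation (a survey typically contributes several
#' indicator rows); `sampling_se` is a proportion-scale standard error and
#' is `NA` when the survey micro-data did not yield one (it is then imputed
#' at modelling time, never silently set to zero).
#'
#' @param surveys data frame with columns `country_code`, `indicator`
#'   (one of [fpem_indicators]), `value` (proportion in (0,1)),
#'   `source_type` (one of [fpem_source_types]), `period_start`,
#'   `period_end` (decimal years), `sampling_se` (proportion scale or `NA`).
#' @param meta data frame with `country_code`, `name`, `subregion`,
#'   `region`, `fp2020_commitment`.
#' @param populations data frame with `country_code`, `year`, `mwra`
#'   (married/in-union women 15--49, persons).
#' @param service_stats data frame with `country_code`, `year`, `emu`
#'   (estimated modern use from service statistics, proportion), may be
#'   empty.
#' @param check validate invariants and stop on the first problems
#'   (default); set `FALSE` to assemble without checking, e.g. to inspect
#'   issues with [validate_dataset()].
#' @return object of class `fpem_dataset`.
#' @export
fpem_dataset <- function(surveys, meta, populations,
                         service_stats = NULL, check = TRUE) {
  if (is.null(service_stats)) {
    service_stats <- tibble::tibble(country_code = character(),
                                    year = numeric(), emu = numeric())
  }
  surveys <- tibble::as_tibble(surveys)
  for (cl in c("value", "period_start", "period_end", "sampling_se")) {
    surveys[[cl]] <- as.numeric(surveys[[cl]])
  }
  service_stats <- tibble::as_tibble(service_stats)
  service_stats$year <- as.numeric(service_stats$year)
  service_stats$emu <- as.numeric(service_stats$emu)
  populations <- tibble::as_tibble(populations)
  populations$year <- as.numeric(populations$year)
  populations$mwra <- as.numeric(populations$mwra)
  d <- structure(
    list(
      surveys = surveys[, survey_cols],
      service_stats = service_stats[, c("country_code", "year", "emu")],
      populations = populations[, c("country_code", "year", "mwra")],
      meta = tibble::as_tibble(meta)[, c("country_code", "name", "subregion",
                                         "region", "fp2020_commitment")]
    ),
    class = "fpem_dataset"
  )
  if (check) {
    issues <- validate_dataset(d)
    if (nrow(issues) > 0) {
      stop_fpem(
        "invalid dataset (", nrow(issues), " issue(s)); first: ",
        issues$table[1], " row ", issues$row[1], ": ", issues$message[1]
      )
    }
  }
  d
}

#' @export
print.fpem_dataset <- function(x, ...) {
  cat("<fpem_dataset>\n")
  cat("  countries:     ", nrow(x$meta), "\n")
  cat("  survey obs:    ", nrow(x$surveys), "\n")
  cat("  service stats: ", nrow(x$service_stats), "\n")
  cat("  population rows:", nrow(x$populations), "\n")
  invisible(x)
}

#' Validate a dataset
#'
#' Checks every record against the type invariants (proportions strictly in
#' (0,1), ordered reference periods, positive sampling SEs and population
#' counts, decimal years in \[1960, 2030\], known enum levels) and the
#' referential-integrity rule that every country code appearing in any
#' table is described in `meta`. Reports, never throws.
#'
#' @param d an `fpem_dataset` (or a bare list with the same elements).
#' @return tibble with columns `table`, `row`, `country_code`, `rule`,
#'   `message`; zero rows iff the dataset is valid.
#' @export
validate_dataset <- function(d) {
  issues <- list()
  add <- function(table, row, cc, rule, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      table = table, row = as.integer(row), country_code = cc,
      rule = rule, message = message
    )
  }
  s <- d$surveys
  for (i in seq_len(nrow(s))) {
    if (!is.finite(s$value[i]) || s$value[i] <= 0 || s$value[i] >= 1)
      add("surveys", i, s$country_code[i], "value_range",
          paste0("value ", s$value[i], " outside (0,1)"))
    if (!s$indicator[i] %in% fpem_indicators)
      add("surveys", i, s$country_code[i], "indicator_enum",
          paste0("unknown indicator '", s$indicator[i], "'"))
    if (!s$source_type[i] %in% fpem_source_types)
      add("surveys", i, s$country_code[i], "source_enum",
          paste0("unknown source_type '", s$source_type[i], "'"))
    if (is.na(s$period_start[i]) || is.na(s$period_end[i]) ||
        s$period_end[i] < s$period_start[i])
      add("surveys", i, s$country_code[i], "period_order",
          "period_end earlier than period_start")
    else if (s$period_start[i] < 1960 || s$period_end[i] > 2030)
      add("surveys", i, s$country_code[i], "period_range",
          "reference period outside [1960, 2030]")
    if (!is.na(s$sampling_se[i]) && s$sampling_se[i] <= 0)
      add("surveys", i, s$country_code[i], "se_positive",
          "sampling_se must be > 0 when present")
  }
  e <- d$service_stats
  for (i in seq_len(nrow(e))) {
    if (!is.finite(e$emu[i]) || e$emu[i] <= 0 || e$emu[i] >= 1)
      add("service_stats", i, e$country_code[i], "emu_range",
          paste0("emu ", e$emu[i], " outside (0,1)"))
    if (is.na(e$year[i]) || e$year[i] < 1960 || e$year[i] > 2030)
      add("service_stats", i, e$country_code[i], "year_range",
          "year outside [1960, 2030]")
  }
  p <- d$populations
  for (i in seq_len(nrow(p))) {
    if (!is.finite(p$mwra[i]) || p$mwra[i] <= 0)
      add("populations", i, p$country_code[i], "mwra_positive",
          "mwra must be > 0")
  }
  m <- d$meta
  if (anyDuplicated(m$country_code))
    add("meta", which(duplicated(m$country_code))[1],
        m$country_code[duplicated(m$country_code)][1],
        "meta_unique", "duplicated country_code in meta")
  sub2reg <- unique(m[, c("subregion", "region")])
  if (anyDuplicated(sub2reg$subregion))
    add("meta", NA, NA_character_, "hierarchy_nesting",
        "a subregion maps to more than one region")
  for (tbl in c("surveys", "service_stats", "populations")) {
    cc <- unique(d[[tbl]]$country_code)
    orphan <- setdiff(cc, m$country_code)
    for (o in orphan) {
      add(tbl, which(d[[tbl]]$country_code == o)[1], o,
          "referential_integrity",
          paste0("country '", o, "' absent from meta"))
    }
  }
  if (length(issues) == 0) {
    return(tibble::tibble(table = character(), row = integer(),
                          country_code = character(), rule = character(),
                          message = character()))
  }
  dplyr::bind_rows(issues)
}

#' Load a dataset from a directory of CSV files
#'
#' Expects `surveys.csv`, `service_stats.csv`, `populations.csv` and
#' `hierarchy.csv` (individual paths can be overridden). Empty
#' `sampling_se` fields become `NA` (missing, flagged for imputation).
#' Malformed rows and invariant violations are errors naming the file.
#'
#' @param dir directory containing the four CSVs.
#' @param surveys,service_stats,populations,hierarchy optional explicit
#'   paths overriding the defaults inside `dir`.
#' @return an `fpem_dataset`.
#' @export
load_dataset <- function(dir = ".",
                         surveys = file.path(dir, "surveys.csv"),
                         service_stats = file.path(dir, "service_stats.csv"),
                         populations = file.path(dir, "populations.csv"),
                         hierarchy = file.path(dir, "hierarchy.csv")) {
  read_strict <- function(path, col_types) {
    if (!file.exists(path)) stop_fpem("file not found: ", path)
    x <- readr::read_csv(path, col_types = col_types, progress = FALSE)
    probs <- readr::problems(x)
    if (nrow(probs) > 0) {
      stop_fpem("parse error in ", path, " at row ", probs$row[1], ": ",
                probs$expected[1], " but got '", probs$actual[1], "'")
    }
    x
  }
  s <- read_strict(surveys, readr::cols(
    country_code = "c", indicator = "c", value = "d", source_type = "c",
    period_start = "d", period_end = "d", sampling_se = "d"
  ))
  e <- if (file.exists(service_stats)) {
    read_strict(service_stats,
                readr::cols(country_code = "c", year = "d", emu = "d"))
  } else NULL
  p <- read_strict(populations,
                   readr::cols(country_code = "c", year = "d", mwra = "d"))
  m <- read_strict(hierarchy, readr::cols(
    country_code = "c", name = "c", subregion = "c", region = "c",
    fp2020_commitment = "l"
  ))
  fpem_dataset(surveys = s, meta = m, populations = p, service_stats = e)
}

#' Write a dataset to a directory of CSV files
#'
#' Inverse of [load_dataset()]: writes the four standard CSVs; missing
#' sampling SEs are written as empty fields, never zero.
#'
#' @param d an `fpem_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(d, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(d$surveys, file.path(dir, "surveys.csv"), na = "")
  readr::write_csv(d$service_stats, file.path(dir, "service_stats.csv"), na = "")
  readr::write_csv(d$populations, file.path(dir, "populations.csv"), na = "")
  readr::write_csv(d$meta, file.path(dir, "hierarchy.csv"), na = "")
  invisible(dir)
}

# ---------------------------------------------------------------------------
# Packaged report-table fixtures

# Fixture cells are verbatim transcriptions using the middle-dot decimal
# separator and the true minus sign; normalise both before parsing.
parse_fixture_number <- function(x) {
  as.numeric(gsub("−", "-", gsub("·", ".", x)))
}

#' Load a packaged report-table fixture
#'
#' Verbatim transcriptions of the three published report tables, shipped
#' with the package for validation: `T1` gives 2017 levels of mCPR, unmet
#' need for modern methods and demand satisfied (point estimate and 95%
#' uncertainty bounds) for the 68 focus countries; `T2` gives 2012--2017
#' changes in the same indicators plus users (millions), with a flag for
#' the 47 countries having survey or service-statistic data after 2012;
#' `T3` gives the counterfactual analysis (evaluation year, mCPR gap in
#' percentage points, user gap in millions, attainment probability in
#' percent, FP2020 commitment) for those 47 countries. Numeric cells are
#' stored with middle-dot decimal separators and parsed to doubles here.
#'
#' @param table_id one of `"T1"`, `"T2"`, `"T3"`.
#' @return tibble with one row per country; attributes `table_id`.
#' @export
load_report_fixtures <- function(table_id = c("T1", "T2", "T3")) {
  table_id <- match.arg(table_id)
  file <- c(T1 = "table1.csv", T2 = "table2.csv", T3 = "table3.csv")[[table_id]]
  path <- system.file("extdata", "fixtures", file, package = "fpem")
  if (path == "") stop_fpem("fixture not found: ", file)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, locale = readr::locale(encoding = "UTF-8"))
  out <- raw
  keep_chr <- c("country_code", "name", "commitment", "data_after_2012")
  for (cl in setdiff(names(out), keep_chr)) {
    out[[cl]] <- parse_fixture_number(out[[cl]])
  }
  if ("commitment" %in% names(out)) out$commitment <- out$commitment == "Yes"
  if ("data_after_2012" %in% names(out))
    out$data_after_2012 <- out$data_after_2012 == "TRUE"
  attr(out, "table_id") <- table_id
  out
}

#' Country name to ISO3 lookup used by the fixtures
#'
#' @return tibble with `country_code` and `name` for the 68 focus
#'   countries.
#' @export
load_country_lookup <- function() {
  path <- system.file("extdata", "fixtures", "countries.csv", package = "fpem")
  readr::read_csv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' Progress counts from the 2012--2017 change table
#'
#' Applies the two-part progress reading to the change-table fixture,
#' restricted to countries with data after 2012: a country improved when
#' its median mCPR change and median demand-satisfied change are both
#' positive; unmet need declined when its median change is negative.
#'
#' @param t2 the `T2` fixture from [load_report_fixtures()].
#' @return list with `n_post2012`, `improved_both`, `unmet_decreased`,
#'   and `not_improved` (country names).
#' @export
fixture_progress_counts <- function(t2 = load_report_fixtures("T2")) {
  fl <- t2[t2$data_after_2012, ]
  both <- fl$mcpr_change > 0 & fl$demand_satisfied_change > 0
  list(
    n_post2012 = nrow(fl),
    improved_both = sum(both),
    unmet_decreased = sum(fl$unmet_modern_change < 0),
    not_improved = fl$name[!both]
  )
}

#' Attainment-group counts from the counterfactual table
#'
#' Classifies each fixture row with [classify_attainment()] and tallies
#' the published groupings.
#'
#' @param t3 the `T3` fixture from [load_report_fixtures()].
#' @return list with `le25`, `le50`, `le50_committed`, `ge75`, `n`.
#' @export
fixture_attainment_counts <- function(t3 = load_report_fixtures("T3")) {
  p <- t3$attainment_pct / 100
  grp <- vapply(p, classify_attainment, character(1))
  list(
    n = nrow(t3),
    le25 = sum(grp == "LE25"),
    le50 = sum(p <= 0.5),
    le50_committed = sum(p <= 0.5 & t3$commitment),
    ge75 = sum(grp == "GE75")
  )
}
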