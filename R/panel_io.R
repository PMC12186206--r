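#' @title Panel containers and delimited I/O
#' @description
#' All panels are plain data frames (UTF-8 comma-separated on disk, one
#' header row, long/tidy layout) with light S3 classes attached after
#' validation. Units are fixed throughout the package: populations in
#' persons, rates per 100,000 person-years, shares as fractions in `[0, 1]`
#' (never percentages; readers reject share-like columns above 1.5 as a
#' percent-vs-fraction guard).
#' @name panel_io
NULL

SHARE_TOL <- 1e-9      # simplex sum tolerance for age / sanitation shares
PCT_GUARD <- 1.5       # a "fraction" above this is almost surely a percent

stop_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", what, paste(miss, collapse = ", ")))
}

check_no_dup_keys <- function(df, keys, what) {
  d <- duplicated(df[keys])
  if (any(d)) {
    bad <- unique(do.call(paste, c(df[d, keys, drop = FALSE], sep = "/")))
    stop(sprintf("%s: duplicate keys: %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
}

check_contiguous_years <- function(df, what) {
  for (cc in unique(df$country)) {
    yrs <- sort(df$year[df$country == cc])
    if (length(yrs) > 1 && any(diff(yrs) != 1))
      stop(sprintf("%s: years for %s are not contiguous", what, cc))
  }
}

#' Construct and validate a population panel
#'
#' One row per (country, year): total population (persons), rural share
#' (fraction) and the age-share vector over `schema` in wide columns
#' `share_<band>`. Age shares must sum to 1 within `1e-9` in every row.
#'
#' @param df data frame with columns `country`, `year`, `total_population`,
#'   `rural_share`, and one `share_*` column per band of `schema`
#' @param schema an [age_schema()]
#' @return a validated `population_panel`
#' @export
population_panel <- function(df, schema = default_age_schema()) {
  cols <- c("country", "year", "total_population", "rural_share", share_cols(schema))
  stop_missing_cols(df, cols, "population panel")
  df <- as.data.frame(df)[cols]
  check_no_dup_keys(df, c("country", "year"), "population panel")
  check_contiguous_years(df, "population panel")
  if (any(df$total_population <= 0))
    stop("population panel: total_population must be > 0")
  if (any(df$rural_share < 0 | df$rural_share > 1))
    stop("population panel: rural_share must be in [0, 1]")
  sh <- as.matrix(df[share_cols(schema)])
  if (any(sh < 0) || any(sh > PCT_GUARD))
    stop("population panel: age shares must be fractions in [0, 1]")
  s <- rowSums(sh)
  bad <- abs(s - 1) > SHARE_TOL
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("population panel: age_shares sum %.6g for (%s, %d)",
                 s[i], df$country[i], df$year[i]))
  }
  structure(df, age_schema = schema,
            class = c("population_panel", "data.frame"))
}

#' Construct and validate a sanitation-shares panel
#'
#' One row per (country, year) with the three-rung exposure distribution
#' (`sewer`, `improved`, `unimproved`), each a fraction, summing to 1 within
#' `1e-9`. Optional `<cat>_lo` / `<cat>_hi` columns carry 95% bounds.
#'
#' @param df data frame with columns `country`, `year`, `sewer`,
#'   `improved`, `unimproved` (and optional bound columns)
#' @return a validated `sanitation_shares` panel
#' @export
sanitation_shares <- function(df) {
  cols <- c("country", "year", "sewer", "improved", "unimproved")
  stop_missing_cols(df, cols, "sanitation shares")
  keep <- c(cols, intersect(names(df), paste0(rep(SAN_CATEGORIES, each = 2),
                                              c("_lo", "_hi"))))
  df <- as.data.frame(df)[keep]
  check_no_dup_keys(df, c("country", "year"), "sanitation shares")
  sh <- as.matrix(df[SAN_CATEGORIES])
  if (any(sh < 0) || any(sh > PCT_GUARD))
    stop("sanitation shares: values must be fractions in [0, 1]")
  s <- rowSums(sh)
  if (any(abs(s - 1) > SHARE_TOL)) {
    i <- which(abs(s - 1) > SHARE_TOL)[1]
    stop(sprintf("sanitation shares: sum %.6g for (%s, %d)",
                 s[i], df$country[i], df$year[i]))
  }
  for (cat in SAN_CATEGORIES) {
    lo <- paste0(cat, "_lo"); hi <- paste0(cat, "_hi")
    if (lo %in% names(df) && any(df[[lo]] > df[[cat]] | df[[cat]] > df[[hi]]))
      stop(sprintf("sanitation shares: crossed bounds in %s", cat))
  }
  structure(df, class = c("sanitation_shares", "data.frame"))
}

SAN_CATEGORIES <- c("sewer", "improved", "unimproved")

#' Construct and validate a raw sanitation-response panel
#'
#' Respondent counts per (country, year): `nonmissing_respondents`,
#' `sewer_respondents` and `improved_respondents_among_nonsewer` (improved
#' facilities counted within the non-sewer subpopulation), as the ladder
#' normalization consumes them.
#'
#' @param df data frame with the count columns above
#' @return a validated `sanitation_raw_panel`
#' @export
sanitation_raw_panel <- function(df) {
  cols <- c("country", "year", "nonmissing_respondents",
            "sewer_respondents", "improved_respondents_among_nonsewer")
  stop_missing_cols(df, cols, "sanitation raw panel")
  df <- as.data.frame(df)[cols]
  check_no_dup_keys(df, c("country", "year"), "sanitation raw panel")
  if (any(df$nonmissing_respondents < 0) || any(df$sewer_respondents < 0) ||
      any(df$improved_respondents_among_nonsewer < 0))
    stop("sanitation raw panel: counts must be non-negative")
  if (any(df$sewer_respondents > df$nonmissing_respondents))
    stop("sanitation raw panel: sewer_respondents > nonmissing_respondents")
  if (any(df$improved_respondents_among_nonsewer >
          df$nonmissing_respondents - df$sewer_respondents))
    stop("sanitation raw panel: improved count exceeds non-sewer respondents")
  structure(df, class = c("sanitation_raw_panel", "data.frame"))
}

#' Construct and validate a mortality panel
#'
#' One row per (country, year, age_band, cause): cause-specific death rate
#' per 100,000 person-years with ordered 95% bounds
#' (`rate_lo <= rate <= rate_hi`, all non-negative).
#'
#' @param df data frame with columns `country`, `year`, `age_band`, `cause`,
#'   `rate`, `rate_lo`, `rate_hi`
#' @param schema an [age_schema()]; `age_band` values must be its labels
#' @return a validated `mortality_panel`
#' @export
mortality_panel <- function(df, schema = default_age_schema()) {
  cols <- c("country", "year", "age_band", "cause", "rate", "rate_lo", "rate_hi")
  stop_missing_cols(df, cols, "mortality panel")
  df <- as.data.frame(df)[c(cols, intersect("source", names(df)))]
  check_no_dup_keys(df, c("country", "year", "age_band", "cause"), "mortality panel")
  bad_band <- setdiff(unique(df$age_band), schema$label)
  if (length(bad_band))
    stop(sprintf("mortality panel: unknown age band(s): %s",
                 paste(bad_band, collapse = ", ")))
  if (any(df$rate < 0) || any(df$rate_lo < 0))
    stop("mortality panel: rates must be non-negative")
  if (any(df$rate_lo > df$rate | df$rate > df$rate_hi))
    stop("mortality panel: bounds must satisfy rate_lo <= rate <= rate_hi")
  structure(df, age_schema = schema,
            class = c("mortality_panel", "data.frame"))
}

#' Construct and validate relative-risk records
#'
#' One row per non-referent exposure category (referent: sewer/septic),
#' optionally per cause and age band: relative risk with ordered 95% bounds.
#'
#' @param df data frame with columns `exposure_category`, `cause`, `rr`,
#'   `rr_lo`, `rr_hi` and optionally `age_band`
#' @return a validated `rr_records` data frame
#' @export
rr_records <- function(df) {
  cols <- c("exposure_category", "cause", "rr", "rr_lo", "rr_hi")
  stop_missing_cols(df, cols, "rr records")
  df <- as.data.frame(df)[c(cols, intersect("age_band", names(df)))]
  bad <- setdiff(unique(df$exposure_category), c("unimproved", "improved"))
  if (length(bad))
    stop(sprintf("rr records: unknown exposure category: %s",
                 paste(bad, collapse = ", ")))
  if (any(df$rr < 0)) stop("rr records: rr must be >= 0")
  if (any(df$rr_lo > df$rr | df$rr > df$rr_hi))
    stop("rr records: bounds must satisfy rr_lo <= rr <= rr_hi")
  structure(df, class = c("rr_records", "data.frame"))
}

# ---- readers / writers ------------------------------------------------------

read_panel_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write a population panel CSV
#'
#' Wide layout: `country,year,total_population,rural_share,share_<band>...`.
#'
#' @param path CSV file path
#' @param schema an [age_schema()]
#' @return [read_population_panel()] returns a validated `population_panel`;
#'   `write_population_panel` returns `path` invisibly.
#' @export
read_population_panel <- function(path, schema = default_age_schema()) {
  population_panel(read_panel_csv(path), schema = schema)
}

#' @rdname read_population_panel
#' @param panel a `population_panel`
#' @export
write_population_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a sanitation panel CSV
#'
#' `raw = FALSE` (default) expects pre-normalized fractional shares
#' (`sewer,improved,unimproved`); `raw = TRUE` expects respondent counts
#' for the ladder normalization.
#'
#' @param path CSV file path
#' @param raw whether the file holds respondent counts rather than shares
#' @return a `sanitation_shares` or `sanitation_raw_panel`
#' @export
read_sanitation_panel <- function(path, raw = FALSE) {
  df <- read_panel_csv(path)
  if (raw) sanitation_raw_panel(df) else sanitation_shares(df)
}

#' @rdname read_sanitation_panel
#' @param panel a sanitation panel (shares or raw counts)
#' @export
write_sanitation_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a mortality panel CSV
#'
#' Long layout: `country,year,age_band,cause,rate,rate_lo,rate_hi`
#' (rates per 100,000 person-years).
#'
#' @param path CSV file path
#' @param schema an [age_schema()]
#' @return a validated `mortality_panel`
#' @export
read_mortality_panel <- function(path, schema = default_age_schema()) {
  mortality_panel(read_panel_csv(path), schema = schema)
}

#' @rdname read_mortality_panel
#' @param panel a `mortality_panel`
#' @export
write_mortality_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Read / write relative-risk records CSV
#'
#' @param path CSV file path
#' @return validated `rr_records`
#' @export
read_rr_records <- function(path) rr_records(read_panel_csv(path))

#' @rdname read_rr_records
#' @param records an `rr_records` data frame
#' @export
write_rr_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Cross-panel completeness report
#'
#' Flags, for exclusion, every country missing any (country, year) cell in
#' any panel over `years` (default: the union of years seen anywhere).
#' Missing data lead to exclusion of the whole country — never imputation.
#' Report-only: nothing is modified and nothing errors.
#'
#' @param population a `population_panel`
#' @param sanitation a `sanitation_shares` or `sanitation_raw_panel`
#' @param mortality a `mortality_panel`
#' @param rr `rr_records`
#' @param years integer vector of years that must be covered
#' @return a `world_validation` list: `excluded` (country, reason),
#'   `included` (character vector), `years`
#' @export
validate_world <- function(population, sanitation, mortality, rr,
                           years = NULL) {
  panels <- list(population = population, sanitation = sanitation,
                 mortality = mortality)
  all_countries <- sort(unique(unlist(lapply(panels, function(p) p$country))))
  if (is.null(years))
    years <- sort(unique(unlist(lapply(panels, function(p) p$year))))
  excluded <- data.frame(country = character(), reason = character(),
                         stringsAsFactors = FALSE)
  schema <- attr(mortality, "age_schema")
  for (cc in all_countries) {
    reasons <- character()
    for (nm in names(panels)) {
      p <- panels[[nm]]
      have <- unique(p$year[p$country == cc])
      miss <- setdiff(years, have)
      if (length(miss))
        reasons <- c(reasons, sprintf("%s missing %d year(s)", nm, length(miss)))
    }
    # mortality additionally needs every age band in covered years
    if (!is.null(schema)) {
      m <- mortality[mortality$country == cc & mortality$year %in% years, ]
      if (nrow(m)) {
        n_cells <- nrow(unique(m[c("year", "age_band")]))
        need <- length(intersect(years, unique(m$year))) * nrow(schema)
        if (n_cells < need)
          reasons <- c(reasons, "mortality missing age bands")
      }
    }
    if (length(reasons))
      excluded <- rbind(excluded, data.frame(
        country = cc, reason = paste(reasons, collapse = "; "),
        stringsAsFactors = FALSE))
  }
  structure(list(excluded = excluded,
                 included = setdiff(all_countries, excluded$country),
                 years = years),
            class = "world_validation")
}

#' @export
print.world_validation <- function(x, ...) {
  cat(sprintf("world validation over years %d-%d\n",
              min(x$years), max(x$years)))
  cat(sprintf("  included: %d countries\n", length(x$included)))
  if (nrow(x$excluded)) {
    cat(sprintf("  excluded: %d countries\n", nrow(x$excluded)))
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("    %s: %s\n", x$excluded$country[i], x$excluded$reason[i]))
  } else cat("  excluded: none\n")
  invisible(x)
}
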