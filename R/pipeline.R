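#' Pipeline configuration
#'
#' @param year_start,year_end history range (observed panels must cover it)
#' @param horizon projection years beyond `year_end`
#' @param age_schema an [age_schema()]
#' @param unsafe_definition exposure categories entering the PAF
#'   (per-category scheme: both non-referent rungs by default)
#' @param std standard population weights (default: WHO World Standard
#'   aggregated to the schema)
#' @param apc an [apc_config()] (sampler settings for the mortality fits)
#' @param arima_max list `(p, d, q)` grid bounds for the share forecasts
#' @param composition_mode `"alr"` or `"independent"` (see
#'   [forecast_composition()])
#' @param breakpoints decomposition breakpoint years (clipped to the
#'   available range)
#' @param rr_bounds_in_ci include the relative-risk interval limits in the
#'   endpoint-substitution bounds (on by default; switch off to use only
#'   the exposure and mortality limits)
#' @param grouping optional data frame `country, group` for aggregation
#' @param seed master seed for every stochastic stage
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(year_start = 2000, year_end = 2020, horizon = 10,
                            age_schema = default_age_schema(),
                            unsafe_definition = c("unimproved", "improved"),
                            std = NULL,
                            apc = apc_config(),
                            arima_max = list(p = 2, d = 2, q = 2),
                            composition_mode = "alr",
                            breakpoints = c(2000, 2010, 2020, 2030),
                            rr_bounds_in_ci = TRUE,
                            grouping = NULL,
                            seed = 1L) {
  stopifnot(year_end > year_start, horizon >= 0)
  if (is.null(std)) std <- standard_population(age_schema)
  structure(list(year_start = year_start, year_end = year_end,
                 horizon = horizon, age_schema = age_schema,
                 unsafe_definition = unsafe_definition, std = std,
                 apc = apc, arima_max = arima_max,
                 composition_mode = composition_mode,
                 breakpoints = breakpoints,
                 rr_bounds_in_ci = rr_bounds_in_ci,
                 grouping = grouping, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Endpoint-substitution uncertainty propagation
#'
#' Computes attributable-death bounds by evaluating the attribution
#' formulas at the interval limits of their inputs: `deaths_lo` uses the
#' lower limits of the exposed sanitation shares, the mortality rates and
#' (optionally) the relative risks; `deaths_hi` the upper limits. Because
#' the formulas are monotone increasing in each of these inputs,
#' `lo <= point <= hi` holds at every cell. Shares or rates without bound
#' columns are treated as degenerate (lo = point = hi).
#'
#' @param population a `population_panel`
#' @param shares a `sanitation_shares` panel (with optional `_lo`/`_hi`
#'   columns)
#' @param mortality a `mortality_panel`
#' @param rr `rr_records`
#' @param rural restrict to the rural population
#' @param use_rr_bounds include the RR interval limits
#' @param protective policy passed to [paf_single()]
#' @return a `burden_panel` with fully propagated `deaths_lo`, `deaths_hi`
#' @export
propagate_bounds <- function(population, shares, mortality, rr,
                             rural = TRUE, use_rr_bounds = TRUE,
                             protective = "error") {
  for (cat in SAN_CATEGORIES) {
    for (suf in c("_lo", "_hi")) {
      col <- paste0(cat, suf)
      if (!col %in% names(shares)) shares[[col]] <- shares[[cat]]
    }
    if (any(shares[[paste0(cat, "_lo")]] > shares[[cat]] |
            shares[[cat]] > shares[[paste0(cat, "_hi")]]))
      stop(sprintf("propagate_bounds: crossed share bounds in %s", cat))
  }
  shares <- sanitation_shares(shares)
  point <- compute_paf_table(shares, rr, protective = protective)
  rr_lo_col <- if (use_rr_bounds) "rr_lo" else "rr"
  rr_hi_col <- if (use_rr_bounds) "rr_hi" else "rr"
  paf_lo <- compute_paf_table(shares, rr, rr_col = rr_lo_col,
                              share_suffix = "_lo", protective = "clamp")
  paf_hi <- compute_paf_table(shares, rr, rr_col = rr_hi_col,
                              share_suffix = "_hi", protective = "clamp")
  b_pt <- attributable_deaths(population, mortality, point, rural = rural)
  mort_lo <- mortality; mort_lo$rate <- mortality$rate_lo
  mort_hi <- mortality; mort_hi$rate <- mortality$rate_hi
  b_lo <- attributable_deaths(population, mort_lo, paf_lo, rural = rural)
  b_hi <- attributable_deaths(population, mort_hi, paf_hi, rural = rural)
  key <- c("country", "year", "age_band", "cause")
  stopifnot(identical(b_pt[key], b_lo[key]), identical(b_pt[key], b_hi[key]))
  out <- b_pt
  out$deaths_lo <- b_lo$deaths
  out$deaths_hi <- b_hi$deaths
  if (any(out$deaths_lo > out$deaths + 1e-9) ||
      any(out$deaths_hi < out$deaths - 1e-9))
    stop("propagate_bounds: monotonicity violated (crossed input bounds?)")
  out
}

#' Aggregate a burden panel over country groups
#'
#' Group deaths are the sums of member-country cells; group
#' age-standardized rates are recomputed from the pooled age-specific
#' deaths and populations (never averaged member ASRs).
#'
#' @param burden a `burden_panel`
#' @param population a `population_panel`
#' @param grouping data frame `country, group`; every burden country must
#'   be mapped
#' @param std a [standard_population()]
#' @param rural use rural denominators for the pooled ASR
#' @return list: `deaths` (group, year, deaths, lo, hi) and `asr`
#'   (group, year, asr, asr_lo, asr_hi)
#' @export
aggregate_burden <- function(burden, population, grouping,
                             std = standard_population(attr(burden, "age_schema")),
                             rural = TRUE) {
  unmapped <- setdiff(unique(burden$country), grouping$country)
  if (length(unmapped))
    stop(sprintf("aggregate_burden: unmapped countries: %s",
                 paste(unmapped, collapse = ", ")))
  sch <- attr(burden, "age_schema")
  if (is.null(sch)) sch <- default_age_schema()
  b <- merge(as.data.frame(burden), grouping, by = "country")
  deaths <- stats::aggregate(cbind(deaths, deaths_lo, deaths_hi) ~ group + year,
                             data = b, FUN = sum)
  popl <- population_long(population, sch)
  popl <- merge(popl, grouping, by = "country")
  popl$persons <- popl$total_population *
    (if (rural) popl$rural_share else 1) * popl$age_share
  cell_d <- stats::aggregate(cbind(deaths, deaths_lo, deaths_hi) ~
                               group + year + age_band, data = b, FUN = sum)
  cell_p <- stats::aggregate(persons ~ group + year + age_band,
                             data = popl, FUN = sum)
  m <- merge(cell_d, cell_p, by = c("group", "year", "age_band"))
  w <- unname(std[m$age_band])
  m$c_pt <- w * m$deaths / m$persons * 1e5
  m$c_lo <- w * m$deaths_lo / m$persons * 1e5
  m$c_hi <- w * m$deaths_hi / m$persons * 1e5
  asr <- stats::aggregate(cbind(asr = c_pt, asr_lo = c_lo, asr_hi = c_hi) ~
                            group + year, data = m, FUN = sum)
  list(deaths = deaths[order(deaths$group, deaths$year), ],
       asr = asr[order(asr$group, asr$year), ])
}

#' Run the full attributable-burden pipeline
#'
#' Stages: cross-panel validation and country exclusion; ladder
#' normalization (if raw counts are supplied); per-country Bayesian APC
#' mortality fit and projection; per-country compositional ARIMA share
#' forecast; attributable-fraction and death computation for every
#' observed and projected year with endpoint-substitution bounds; direct
#' age standardization; aggregation (global and optional groups); factor
#' decomposition at the configured breakpoints. Fully reproducible from
#' (inputs, config, seed).
#'
#' @param population a `population_panel` covering history and horizon
#'   (future population is an external input, not forecast here)
#' @param sanitation a `sanitation_shares` panel or `sanitation_raw_panel`
#'   covering the history years
#' @param mortality a `mortality_panel` covering the history years
#' @param rr `rr_records`
#' @param config a [pipeline_config()]
#' @param out_dir optional directory; when given, writes `burden.csv`,
#'   `asr.csv`, `decomposition.csv`, `exclusions.csv` and
#'   `run_report.json`
#' @return a `run_report` list: `burden` (per-cell), `dausr` (global
#'   series with bounds), `dausr_by_country`, `asr`, `asr_global`,
#'   `decomposition`, `sanitation_all`, `mortality_all`, `exclusions`,
#'   `validation`, `config`, `seed`, `version`
#' @export
run_pipeline <- function(population, sanitation, mortality, rr,
                         config = pipeline_config(), out_dir = NULL) {
  sch <- config$age_schema
  years_hist <- config$year_start:config$year_end
  years_all <- config$year_start:(config$year_end + config$horizon)

  if (inherits(sanitation, "sanitation_raw_panel"))
    sanitation <- normalize_ladder(sanitation)

  val <- validate_world(population, sanitation, mortality, rr,
                        years = years_hist)
  keep <- val$included
  # future population must also be present for kept countries
  pop_ok <- vapply(keep, function(cc)
    all(years_all %in% population$year[population$country == cc]), logical(1))
  if (any(!pop_ok)) {
    val$excluded <- rbind(val$excluded, data.frame(
      country = keep[!pop_ok], reason = "population missing projection years",
      stringsAsFactors = FALSE))
    keep <- keep[pop_ok]
  }
  if (!length(keep)) stop("run_pipeline: no country passes validation")
  population <- population_panel(
    as.data.frame(population)[population$country %in% keep &
                                population$year %in% years_all, ], schema = sch)
  sanitation <- sanitation_shares(
    as.data.frame(sanitation)[sanitation$country %in% keep &
                                sanitation$year %in% years_hist, ])
  mortality <- mortality_panel(
    as.data.frame(mortality)[mortality$country %in% keep &
                               mortality$year %in% years_hist, ], schema = sch)

  # --- mortality projection (per country) -----------------------------------
  mort_all <- as.data.frame(mortality)
  mort_all$source <- "observed"
  apc_diags <- list()
  if (config$horizon > 0) {
    proj_rows <- list()
    for (ci in seq_along(keep)) {
      cc <- keep[ci]
      sub <- mortality_panel(mort_all[mort_all$country == cc,
                                      setdiff(names(mort_all), "source")],
                             schema = sch)
      cfg_c <- config$apc
      cfg_c$seed <- config$seed + 1000L + ci
      post <- fit_apc(sub, config = cfg_c)
      apc_diags[[cc]] <- list(rhat = post$diagnostics,
                              converged = post$converged)
      pr <- project_rates(post, horizon = config$horizon,
                          force = TRUE, seed = config$seed + 2000L + ci)
      pr$cause <- unique(sub$cause)[1]
      pr$source <- "projected"
      proj_rows[[ci]] <- pr[c("country", "year", "age_band", "cause",
                              "rate", "rate_lo", "rate_hi", "source")]
    }
    mort_all <- rbind(mort_all, do.call(rbind, proj_rows))
  }
  mort_all <- mortality_panel(mort_all, schema = sch)

  # --- sanitation forecast (per country) ------------------------------------
  san_all <- as.data.frame(sanitation)
  for (cat in SAN_CATEGORIES) {   # observed shares default to degenerate bounds
    for (suf in c("_lo", "_hi")) {
      col <- paste0(cat, suf)
      if (!col %in% names(san_all)) san_all[[col]] <- san_all[[cat]]
    }
  }
  san_all$source <- "observed"
  if (config$horizon > 0) {
    fc_rows <- lapply(keep, function(cc) {
      fc <- forecast_composition(
        sanitation[sanitation$country == cc, ],
        horizon = config$horizon, mode = config$composition_mode,
        max_p = config$arima_max$p, max_d = config$arima_max$d,
        max_q = config$arima_max$q)
      fc[setdiff(names(fc), "mode")]
    })
    san_all <- rbind(san_all, do.call(rbind, fc_rows))
  }
  san_panel <- sanitation_shares(san_all[setdiff(names(san_all), "source")])

  # --- attribution with bounds ----------------------------------------------
  rr_use <- rr
  if (length(config$unsafe_definition) < 2)
    rr_use <- rr_records(rr[rr$exposure_category %in% config$unsafe_definition, ])
  burden <- propagate_bounds(population, san_panel, mort_all, rr_use,
                             rural = TRUE,
                             use_rr_bounds = config$rr_bounds_in_ci)

  # --- series ---------------------------------------------------------------
  by_country <- stats::aggregate(cbind(deaths, deaths_lo, deaths_hi) ~
                                   country + year, data = burden, FUN = sum)
  global <- stats::aggregate(cbind(deaths, deaths_lo, deaths_hi) ~ year,
                             data = burden, FUN = sum)
  asr <- age_standardized_rate(burden, population, std = config$std)
  glob_group <- data.frame(country = keep, group = "GLOBAL",
                           stringsAsFactors = FALSE)
  asr_global <- aggregate_burden(burden, population, glob_group,
                                 std = config$std)$asr
  grouped <- if (!is.null(config$grouping))
    aggregate_burden(burden, population, config$grouping, std = config$std)

  # --- decomposition --------------------------------------------------------
  bps <- config$breakpoints[config$breakpoints %in% years_all]
  decomp <- if (length(bps) >= 2)
    decompose_timeline(population, san_panel, mort_all, rr_use, bps)

  report <- structure(list(
    burden = burden, dausr = global, dausr_by_country = by_country,
    asr = asr, asr_global = asr_global, grouped = grouped,
    decomposition = decomp, sanitation_all = san_all,
    mortality_all = mort_all, exclusions = val$excluded, validation = val,
    apc_diagnostics = apc_diags, config = config, seed = config$seed,
    version = as.character(utils::packageVersion("sanburden"))),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(burden, file.path(out_dir, "burden.csv"), row.names = FALSE)
    utils::write.csv(asr, file.path(out_dir, "asr.csv"), row.names = FALSE)
    if (!is.null(decomp))
      utils::write.csv(decomp, file.path(out_dir, "decomposition.csv"),
                       row.names = FALSE)
    utils::write.csv(val$excluded, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    meta <- list(seed = config$seed, version = report$version,
                 year_start = config$year_start, year_end = config$year_end,
                 horizon = config$horizon,
                 countries = keep,
                 composition_mode = config$composition_mode,
                 apc = config$apc[c("chains", "iter", "warmup")],
                 converged = vapply(apc_diags, `[[`, logical(1), "converged"))
    jsonlite::write_json(meta, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  yrs <- range(x$dausr$year)
  cat(sprintf("attributable-burden run: %d countries, %d-%d\n",
              length(unique(x$burden$country)), yrs[1], yrs[2]))
  first <- x$dausr[which.min(x$dausr$year), ]
  last <- x$dausr[which.max(x$dausr$year), ]
  cat(sprintf("  global deaths %d: %.0f (%.0f-%.0f)\n", first$year,
              first$deaths, first$deaths_lo, first$deaths_hi))
  cat(sprintf("  global deaths %d: %.0f (%.0f-%.0f)\n", last$year,
              last$deaths, last$deaths_lo, last$deaths_hi))
  if (nrow(x$exclusions))
    cat(sprintf("  excluded countries: %d\n", nrow(x$exclusions)))
  invisible(x)
}
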