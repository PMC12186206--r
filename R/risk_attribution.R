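#' Population-average relative risk under a binary exposure
#'
#' With a fraction `p` of the population exposed at relative risk `rr`
#' (referent risk 1), the population-average relative risk is
#' `RRbar = p (rr - 1) + 1`.
#'
#' @param p exposed fraction in `[0, 1]` (vectorized)
#' @param rr relative risk, `>= 0`
#' @return population-average relative risk
#' @export
mean_relative_risk <- function(p, rr) {
  if (any(p < 0 | p > 1)) stop("exposed fraction p must be in [0, 1]")
  if (any(rr < 0)) stop("relative risk must be >= 0")
  p * (rr - 1) + 1
}

#' Population attributable fraction for one exposure category
#'
#' `PAF = (RRbar - 1) / RRbar` with `RRbar` from [mean_relative_risk()].
#' Always in `[0, 1)` for `rr >= 1`. Protective exposures (`rr < 1`) are
#' rejected by default — the attribution model covers harmful exposure
#' only; `protective = "clamp"` instead clamps the PAF at 0.
#'
#' @param p exposed fraction in `[0, 1]`
#' @param rr relative risk
#' @param protective policy for `rr < 1`: `"error"` (default) or `"clamp"`
#' @return attributable fraction(s) in `[0, 1)`
#' @examples
#' paf_single(1, 2)      # 0.5
#' paf_single(0.5, 3)    # 0.5
#' @export
paf_single <- function(p, rr, protective = c("error", "clamp")) {
  protective <- match.arg(protective)
  if (any(rr < 0)) stop("relative risk must be >= 0")
  if (any(rr < 1)) {
    if (protective == "error")
      stop("protective exposure (rr < 1) rejected; set protective = \"clamp\"")
    rr <- pmax(rr, 1)
  }
  rb <- mean_relative_risk(p, rr)
  (rb - 1) / rb
}

#' Combine attributable fractions across independent risk factors
#'
#' `PAF = 1 - prod(1 - PAF_A)`: multiplicative combination for independent
#' factors. Commutative; returns the single fraction unchanged for one
#' factor.
#'
#' @param pafs numeric vector of fractions, each in `[0, 1)`
#' @return combined attributable fraction
#' @examples
#' paf_combined(c(0.5, 0.5))      # 0.75
#' paf_combined(c(0.2, 0.3, 0.5)) # 0.72
#' @export
paf_combined <- function(pafs) {
  if (any(pafs < 0 | pafs >= 1)) stop("each PAF must be in [0, 1)")
  1 - prod(1 - pafs)
}

#' Attributable-fraction table for a shares panel
#'
#' For every (country, year): each non-referent exposure category with a
#' relative-risk record contributes `paf_single(share, rr)`; categories are
#' combined with [paf_combined()]. The referent (sewer/septic) contributes
#' nothing. Age-specific records (non-`NA` `age_band`) yield age-specific
#' rows; otherwise `age_band` is `NA` and the PAF applies to all bands.
#'
#' @param shares a `sanitation_shares` panel
#' @param rr `rr_records`
#' @param rr_col,share_suffix which RR column (`"rr"`, `"rr_lo"`, `"rr_hi"`)
#'   and share column suffix (`""`, `"_lo"`, `"_hi"`) to evaluate — used by
#'   the endpoint-substitution bound propagation
#' @param protective policy passed to [paf_single()]
#' @return a `paf_table` data frame: country, year, cause, age_band, paf
#' @export
compute_paf_table <- function(shares, rr, rr_col = "rr", share_suffix = "",
                              protective = "error") {
  stopifnot(inherits(shares, "sanitation_shares"))
  if (!inherits(rr, "rr_records")) rr <- rr_records(rr)
  bad <- setdiff(unique(rr$exposure_category), SAN_CATEGORIES)
  if (length(bad))
    stop(sprintf("rr record references unknown category: %s",
                 paste(bad, collapse = ", ")))
  has_age <- "age_band" %in% names(rr) && any(!is.na(rr$age_band))
  groups <- if (has_age) {
    unique(data.frame(cause = rr$cause, age_band = rr$age_band,
                      stringsAsFactors = FALSE))
  } else unique(data.frame(cause = rr$cause, age_band = NA_character_,
                           stringsAsFactors = FALSE))
  out <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    sel <- rr$cause == g$cause
    if (has_age) sel <- sel & (is.na(rr$age_band) | rr$age_band %in% g$age_band)
    rsub <- rr[sel, , drop = FALSE]
    paf <- rep(0, nrow(shares))
    q <- rep(1, nrow(shares))
    for (ri in seq_len(nrow(rsub))) {
      cat_col <- paste0(rsub$exposure_category[ri], share_suffix)
      if (!cat_col %in% names(shares))
        stop(sprintf("shares panel lacks column %s", cat_col))
      p <- shares[[cat_col]]
      p <- pmin(pmax(p, 0), 1)
      q <- q * (1 - paf_single(p, rsub[[rr_col]][ri], protective = protective))
    }
    out[[gi]] <- data.frame(country = shares$country, year = shares$year,
                            cause = g$cause, age_band = g$age_band,
                            paf = 1 - q, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("paf_table", "data.frame")
  res
}

#' Attributable deaths per country-year-age cell
#'
#' `deaths = POP * rural_share * AgeP_a * (rate_a / 100000) * PAF_a`.
#' The rural restriction multiplies the total population by the rural
#' share and applies the national age structure to it — i.e. the rural age
#' structure is assumed congruent with the overall population's (the
#' pipeline's stated assumption; there is no separate rural age pyramid).
#' Cell bounds come from the mortality rate bounds at the point PAF; for
#' fully propagated bounds see [propagate_bounds()].
#'
#' @param population a `population_panel`
#' @param mortality a `mortality_panel`
#' @param paf a `paf_table` from [compute_paf_table()]
#' @param rural if `FALSE`, the rural share is ignored (whole population)
#' @return a `burden_panel`: country, year, age_band, cause, deaths,
#'   deaths_lo, deaths_hi
#' @export
attributable_deaths <- function(population, mortality, paf, rural = TRUE) {
  sch <- attr(mortality, "age_schema")
  if (is.null(sch)) sch <- default_age_schema()
  popl <- population_long(population, sch)
  m <- merge(as.data.frame(mortality), popl,
             by = c("country", "year", "age_band"))
  if (nrow(m) < nrow(mortality)) {
    miss <- nrow(mortality) - nrow(m)
    stop(sprintf("attributable_deaths: %d mortality cell(s) lack matching population rows", miss))
  }
  pf <- as.data.frame(paf)
  age_specific <- any(!is.na(pf$age_band))
  if (age_specific) {
    m <- merge(m, pf, by = c("country", "year", "age_band", "cause"))
  } else {
    m <- merge(m, pf[setdiff(names(pf), "age_band")],
               by = c("country", "year", "cause"))
  }
  if (!nrow(m)) stop("attributable_deaths: no overlapping (country, year) cells between panels and PAF table")
  base <- m$total_population * (if (rural) m$rural_share else 1) * m$age_share
  out <- data.frame(country = m$country, year = m$year,
                    age_band = m$age_band, cause = m$cause,
                    deaths = base * m$rate / 1e5 * m$paf,
                    deaths_lo = base * m$rate_lo / 1e5 * m$paf,
                    deaths_hi = base * m$rate_hi / 1e5 * m$paf,
                    stringsAsFactors = FALSE)
  out <- out[order(out$country, out$year, match(out$age_band, sch$label)), ]
  rownames(out) <- NULL
  structure(out, age_schema = sch, class = c("burden_panel", "data.frame"))
}

# wide population panel -> long (country, year, age_band, age_share, ...)
population_long <- function(population, schema = attr(population, "age_schema")) {
  if (is.null(schema)) schema <- default_age_schema()
  cols <- share_cols(schema)
  df <- as.data.frame(population)
  out <- do.call(rbind, lapply(seq_len(nrow(schema)), function(i) {
    data.frame(country = df$country, year = df$year,
               total_population = df$total_population,
               rural_share = df$rural_share,
               age_band = schema$label[i], age_share = df[[cols[i]]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Standard population weights over an age schema
#'
#' Aggregates the WHO World Standard Population (Ahmad et al. 2001;
#' 18 five-year groups) onto `schema` by age-range overlap, then
#' renormalizes to sum to 1. Pass explicit `weights` to override.
#'
#' @param schema an [age_schema()]
#' @param weights optional named numeric vector (names = band labels);
#'   renormalized to 1
#' @return a named weight vector summing to 1 (class `standard_population`)
#' @export
standard_population <- function(schema = default_age_schema(), weights = NULL) {
  if (!is.null(weights)) {
    stopifnot(setequal(names(weights), schema$label))
    w <- weights[schema$label] / sum(weights)
    return(structure(w, class = "standard_population"))
  }
  # WHO World Standard percentages, ages 0-4 through 85+
  who <- c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59,
           6.04, 5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.63)
  lo5 <- seq(0, 85, by = 5)
  hi5 <- c(seq(4, 84, by = 5), Inf)
  w <- numeric(nrow(schema))
  for (i in seq_len(nrow(schema))) {
    for (j in seq_along(who)) {
      # overlap of [lower, upper] with the 5-year group, in years of age
      ov_lo <- max(schema$lower[i], lo5[j])
      ov_hi <- min(schema$upper[i], hi5[j])
      if (ov_hi >= ov_lo) {
        width <- if (is.infinite(hi5[j])) 1 else
          (ov_hi - ov_lo + 1) / (hi5[j] - lo5[j] + 1)
        if (is.infinite(ov_hi) && !is.infinite(hi5[j])) width <- 1
        w[i] <- w[i] + who[j] * min(width, 1)
      }
    }
  }
  w <- w / sum(w)
  structure(stats::setNames(w, schema$label), class = "standard_population")
}

#' Directly age-standardized attributable death rate
#'
#' `ASR = sum_a w_a * (deaths_a / rural population_a) * 100000` with
#' weights `w` from a [standard_population()]. Invariant to a common
#' scaling of all age-band populations when age-specific rates are fixed.
#'
#' @param burden a `burden_panel` from [attributable_deaths()]
#' @param population a `population_panel`
#' @param std a [standard_population()] over the same schema
#' @param rural if `FALSE`, denominators use the whole population
#' @return data frame: country, year, asr, asr_lo, asr_hi (per 100,000)
#' @export
age_standardized_rate <- function(burden, population,
                                  std = standard_population(attr(burden, "age_schema")),
                                  rural = TRUE) {
  sch <- attr(burden, "age_schema")
  if (is.null(sch)) sch <- default_age_schema()
  popl <- population_long(population, sch)
  m <- merge(as.data.frame(burden), popl, by = c("country", "year", "age_band"))
  denom <- m$total_population * (if (rural) m$rural_share else 1) * m$age_share
  if (any(denom == 0 & m$deaths > 0))
    stop("age_standardized_rate: zero population in a band with nonzero deaths")
  w <- unname(std[m$age_band])
  m$contrib <- w * ifelse(denom == 0, 0, m$deaths / denom) * 1e5
  m$contrib_lo <- w * ifelse(denom == 0, 0, m$deaths_lo / denom) * 1e5
  m$contrib_hi <- w * ifelse(denom == 0, 0, m$deaths_hi / denom) * 1e5
  agg <- stats::aggregate(cbind(asr = contrib, asr_lo = contrib_lo,
                                asr_hi = contrib_hi) ~ country + year,
                          data = m, FUN = sum)
  agg[order(agg$country, agg$year), ]
}
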