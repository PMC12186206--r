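# a small end-to-end run used by several blocks: 4 countries, observed
# 2000-2020, population through 2025, 5-year projection
pipeline_fixture <- function() cached("pipeline_fixture", {
  w <- generate_world(world_config(n_countries = 4, year_start = 2000,
                                   year_end = 2025, seed = 7))
  san_hist <- sanitation_shares(
    as.data.frame(w$sanitation)[w$sanitation$year <= 2020, ])
  mort_hist <- mortality_panel(
    as.data.frame(w$mortality)[w$mortality$year <= 2020, ],
    schema = attr(w$mortality, "age_schema"))
  cfg <- pipeline_config(year_start = 2000, year_end = 2020, horizon = 5,
                         apc = quick_apc_config(1), seed = 3,
                         breakpoints = c(2000, 2010, 2020, 2025))
  list(w = w, san_hist = san_hist, mort_hist = mort_hist, cfg = cfg,
       rep = run_pipeline(w$population, san_hist, mort_hist, w$rr, cfg))
})

single_cell_inputs <- function(u_lo = 0.3, u_hi = 0.5) {
  sch <- default_age_schema()
  pop <- data.frame(country = "SAA", year = 2000, total_population = 1e6,
                    rural_share = 1)
  shares <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  for (i in seq_along(share_cols(sch))) pop[[share_cols(sch)[i]]] <- shares[i]
  sh <- data.frame(country = "SAA", year = 2000,
                   sewer = 0.2, improved = 0.4, unimproved = 0.4,
                   sewer_lo = 0.1, sewer_hi = 0.3,
                   improved_lo = 0.35, improved_hi = 0.45,
                   unimproved_lo = u_lo, unimproved_hi = u_hi)
  mor <- data.frame(country = "SAA", year = 2000, age_band = sch$label,
                    cause = "diarrhea",
                    rate = c(50, 0, 0, 0, 0), rate_lo = c(40, 0, 0, 0, 0),
                    rate_hi = c(60, 0, 0, 0, 0))
  list(pop = population_panel(pop, sch), sh = sanitation_shares(sh),
       mor = mortality_panel(mor, sch))
}

test_that("degenerate input intervals collapse the death bounds to the point", {
  w <- small_world()
  rr_deg <- rr_records(data.frame(
    exposure_category = c("unimproved", "improved"), cause = "diarrhea",
    rr = c(2.5, 1.3), rr_lo = c(2.5, 1.3), rr_hi = c(2.5, 1.3)))
  mor <- as.data.frame(w$mortality)
  mor$rate_lo <- mor$rate; mor$rate_hi <- mor$rate
  mor <- mortality_panel(mor, attr(w$mortality, "age_schema"))
  b <- propagate_bounds(w$population, w$sanitation, mor, rr_deg)
  expect_equal(b$deaths_lo, b$deaths, tolerance = 1e-12)
  expect_equal(b$deaths_hi, b$deaths, tolerance = 1e-12)
})

test_that("endpoint substitution reproduces the single-cell closed form", {
  inp <- single_cell_inputs()
  b <- propagate_bounds(inp$pop, inp$sh, inp$mor, default_rr())
  cell <- b[b$age_band == "<5", ]
  paf_pt <- paf_combined(c(paf_single(0.4, 2.5), paf_single(0.4, 1.3)))
  paf_lo <- paf_combined(c(paf_single(0.3, 1.8), paf_single(0.35, 1.1)))
  paf_hi <- paf_combined(c(paf_single(0.5, 3.3), paf_single(0.45, 1.6)))
  base <- 1e6 * 0.1 / 1e5
  expect_equal(cell$deaths, base * 50 * paf_pt)
  expect_equal(cell$deaths_lo, base * 40 * paf_lo)
  expect_equal(cell$deaths_hi, base * 60 * paf_hi)
  expect_true(all(b$deaths_lo <= b$deaths & b$deaths <= b$deaths_hi))

  # switching off the RR bounds narrows (never widens) the interval
  b2 <- propagate_bounds(inp$pop, inp$sh, inp$mor, default_rr(),
                         use_rr_bounds = FALSE)
  expect_true(all(b2$deaths_lo >= b$deaths_lo - 1e-12))
  expect_true(all(b2$deaths_hi <= b$deaths_hi + 1e-12))
  expect_equal(b2$deaths, b$deaths)
})

test_that("widening a share interval widens the death interval; crossed bounds error", {
  inp <- single_cell_inputs()
  wide <- single_cell_inputs(u_lo = 0.2, u_hi = 0.6)
  b <- propagate_bounds(inp$pop, inp$sh, inp$mor, default_rr())
  bw <- propagate_bounds(wide$pop, wide$sh, wide$mor, default_rr())
  i <- b$age_band == "<5"
  expect_lt(bw$deaths_lo[i], b$deaths_lo[i])
  expect_gt(bw$deaths_hi[i], b$deaths_hi[i])

  bad <- single_cell_inputs()
  sh_bad <- as.data.frame(bad$sh)
  sh_bad$unimproved_lo <- 0.45   # above the 0.4 point estimate
  expect_error(propagate_bounds(bad$pop, sh_bad, bad$mor, default_rr()),
               "crossed share bounds")
})

test_that("group aggregation preserves totals and recomputes pooled rates", {
  w <- small_world()
  b <- propagate_bounds(w$population, w$sanitation, w$mortality, w$rr)
  countries <- unique(b$country)

  # singleton groups reproduce each country's own series
  singleton <- data.frame(country = countries, group = countries)
  agg1 <- aggregate_burden(b, w$population, singleton)
  by_country <- stats::aggregate(deaths ~ country + year, data = b, FUN = sum)
  m <- merge(agg1$deaths, by_country, by.x = c("group", "year"),
             by.y = c("country", "year"))
  expect_equal(m$deaths.x, m$deaths.y)
  asr_direct <- age_standardized_rate(b, w$population)
  m2 <- merge(agg1$asr, asr_direct, by.x = c("group", "year"),
              by.y = c("country", "year"))
  expect_equal(m2$asr.x, m2$asr.y, tolerance = 1e-12)

  # one all-encompassing group conserves the global total
  all_one <- data.frame(country = countries, group = "ALL")
  agg2 <- aggregate_burden(b, w$population, all_one)
  glob <- stats::aggregate(deaths ~ year, data = b, FUN = sum)
  m3 <- merge(agg2$deaths, glob, by = "year")
  expect_equal(m3$deaths.x, m3$deaths.y)
  # pooled ASR is bracketed by the member ASRs
  for (yy in c(2000, 2020)) {
    members <- asr_direct$asr[asr_direct$year == yy]
    pooled <- agg2$asr$asr[agg2$asr$year == yy]
    expect_gte(pooled, min(members) - 1e-9)
    expect_lte(pooled, max(members) + 1e-9)
  }

  expect_error(aggregate_burden(b, w$population, singleton[-1, ]),
               "unmapped")
})

test_that("the full run covers history plus horizon with ordered intervals", {
  fx <- pipeline_fixture()
  rep <- fx$rep
  expect_s3_class(rep, "run_report")
  expect_equal(sort(unique(rep$dausr$year)), 2000:2025)
  expect_equal(sort(unique(rep$burden$country)), paste0("SA", LETTERS[1:4]))
  expect_true(all(rep$burden$deaths_lo <= rep$burden$deaths + 1e-9))
  expect_true(all(rep$burden$deaths <= rep$burden$deaths_hi + 1e-9))
  expect_true(all(rep$dausr$deaths >= 0))
  expect_true(all(rep$asr$asr_lo <= rep$asr$asr & rep$asr$asr <= rep$asr$asr_hi))
  # projected sanitation stays on the simplex
  san_proj <- rep$sanitation_all[rep$sanitation_all$source == "projected", ]
  expect_equal(nrow(san_proj), 4 * 5)
  tot <- rowSums(san_proj[c("sewer", "improved", "unimproved")])
  expect_true(all(abs(tot - 1) < 1e-9))
  # projected mortality rates positive and bounded
  mp <- rep$mortality_all[rep$mortality_all$source == "projected", ]
  expect_true(all(mp$rate_lo > 0 & mp$rate_lo <= mp$rate & mp$rate <= mp$rate_hi))
  expect_true(all(vapply(rep$apc_diagnostics, `[[`, logical(1), "converged")))
})

test_that("global, per-country and per-cell series are mutually consistent", {
  rep <- pipeline_fixture()$rep
  by_c <- stats::aggregate(deaths ~ year, data = rep$dausr_by_country, FUN = sum)
  m <- merge(by_c, rep$dausr, by = "year")
  expect_equal(m$deaths.x, m$deaths.y, tolerance = 1e-9)
  cells <- stats::aggregate(deaths ~ year, data = rep$burden, FUN = sum)
  m2 <- merge(cells, rep$dausr, by = "year")
  expect_equal(m2$deaths.x, m2$deaths.y, tolerance = 1e-9)
  # decomposition intervals sum to the change of the global series
  dec <- rep$decomposition
  tot <- dec[dec$country == "TOTAL", ]
  for (iv in unique(tot$interval)) {
    yrs <- as.integer(strsplit(iv, "-")[[1]])
    delta <- rep$dausr$deaths[rep$dausr$year == yrs[2]] -
      rep$dausr$deaths[rep$dausr$year == yrs[1]]
    expect_equal(sum(tot$contribution_deaths[tot$interval == iv]), delta,
                 tolerance = 1e-6 * max(1, abs(delta)))
  }
})

test_that("the pipeline is deterministic under a fixed seed", {
  fx <- pipeline_fixture()
  rep2 <- run_pipeline(fx$w$population, fx$san_hist, fx$mort_hist, fx$w$rr,
                       fx$cfg)
  expect_identical(fx$rep$dausr, rep2$dausr)
  expect_identical(fx$rep$burden$deaths, rep2$burden$deaths)
  expect_identical(fx$rep$sanitation_all, rep2$sanitation_all)
})

test_that("unit relative risks give zero attributable burden everywhere", {
  w <- small_world()
  rr1 <- rr_records(data.frame(
    exposure_category = c("unimproved", "improved"), cause = "diarrhea",
    rr = 1, rr_lo = 1, rr_hi = 1))
  cfg <- pipeline_config(year_start = 2000, year_end = 2020, horizon = 0,
                         breakpoints = c(2000, 2010, 2020), seed = 2)
  rep <- run_pipeline(w$population, w$sanitation, w$mortality, rr1, cfg)
  expect_equal(max(abs(rep$burden$deaths)), 0)
  expect_equal(max(abs(rep$burden$deaths_hi)), 0)
  expect_equal(max(abs(rep$dausr$deaths)), 0)
  expect_equal(max(abs(rep$asr$asr)), 0)
})

test_that("countries with incomplete panels are excluded with a recorded reason", {
  w <- small_world()
  mor <- as.data.frame(w$mortality)
  mor <- mor[!(mor$country == "SAB" & mor$year >= 2015), ]  # break coverage
  cfg <- pipeline_config(year_start = 2000, year_end = 2020, horizon = 0,
                         breakpoints = c(2000, 2020), seed = 2)
  rep <- run_pipeline(w$population, w$sanitation,
                      mortality_panel(mor, attr(w$mortality, "age_schema")),
                      w$rr, cfg)
  expect_true("SAB" %in% rep$exclusions$country)
  expect_false("SAB" %in% rep$burden$country)
  expect_true(all(c("SAA", "SAC") %in% rep$burden$country))
})

test_that("output files round-trip the headline global series", {
  fx <- pipeline_fixture()
  out <- withr::local_tempdir()
  rep <- run_pipeline(fx$w$population, fx$san_hist, fx$mort_hist, fx$w$rr,
                      fx$cfg, out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("burden.csv", "asr.csv", "decomposition.csv", "exclusions.csv",
           "run_report.json")))))
  burden <- utils::read.csv(file.path(out, "burden.csv"))
  glob <- stats::aggregate(deaths ~ year, data = burden, FUN = sum)
  m <- merge(glob, rep$dausr, by = "year")
  expect_equal(m$deaths.x, m$deaths.y, tolerance = 1e-8)
  meta <- jsonlite::read_json(file.path(out, "run_report.json"))
  expect_equal(meta$seed, 3)
  expect_equal(meta$horizon, 5)
})
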