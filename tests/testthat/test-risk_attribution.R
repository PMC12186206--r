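test_that("PAF closed forms match hand arithmetic", {
  expect_equal(mean_relative_risk(0, 10), 1)
  expect_equal(mean_relative_risk(1, 2), 2)
  expect_equal(mean_relative_risk(0.5, 3), 2)
  expect_equal(paf_single(1, 2), 0.5)
  expect_equal(paf_single(0, 10), 0)
  expect_equal(paf_single(0.5, 3), 0.5)
  expect_equal(paf_combined(c(0.5, 0.5)), 0.75)
  expect_equal(paf_combined(0.37), 0.37)
  expect_equal(paf_combined(c(0.2, 0.3, 0.5)), 0.72)
  expect_error(paf_single(1.2, 2), "\\[0, 1\\]")
  expect_error(paf_single(0.5, -1), ">= 0")
  expect_error(paf_single(0.5, 0.8), "protective")
  expect_equal(paf_single(0.5, 0.8, protective = "clamp"), 0)
  expect_error(paf_combined(c(0.5, 1)), "\\[0, 1\\)")
})

test_that("PAF properties hold over random draws", {
  set.seed(30)
  p <- runif(1000); rr <- 1 + rexp(1000)
  paf <- paf_single(p, rr)
  expect_true(all(paf >= 0 & paf < 1))
  # strictly increasing in p (rr > 1) and in rr (p > 0)
  eps <- 1e-6
  inc_p <- paf_single(pmin(p + eps, 1), rr) - paf
  expect_true(all(inc_p[p + eps <= 1] > 0))
  inc_rr <- paf_single(p, rr + eps) - paf
  expect_true(all(inc_rr[p > 0] > 0))
  # combined: commutative, >= max component, equals it when others are 0
  for (i in 1:200) {
    k <- sample(2:5, 1)
    x <- runif(k, 0, 0.99)
    expect_equal(paf_combined(x), paf_combined(sample(x)))
    expect_gte(paf_combined(x) + 1e-12, max(x))
    expect_equal(paf_combined(c(x[1], rep(0, 4))), x[1])
  }
})

test_that("compute_paf_table applies the per-category scheme and combines factors", {
  sh <- sanitation_shares(data.frame(country = "SAA", year = 2000,
                                     sewer = 0.2, improved = 0.4,
                                     unimproved = 0.4))
  rr_one <- rr_records(data.frame(exposure_category = c("unimproved", "improved"),
                                  cause = "diarrhea",
                                  rr = c(2.5, 1.0), rr_lo = c(2.5, 1.0),
                                  rr_hi = c(2.5, 1.0)))
  paf <- compute_paf_table(sh, rr_one)
  expect_equal(paf$paf, 0.6 / 1.6)  # single active factor

  # two active categories: equals the directly enumerated combination
  rr2 <- default_rr()
  paf2 <- compute_paf_table(sh, rr2)
  p_u <- paf_single(0.4, 2.5); p_i <- paf_single(0.4, 1.3)
  expect_equal(paf2$paf, 1 - (1 - p_u) * (1 - p_i))
})

test_that("attributable deaths follow the cell formula and are linear", {
  sch <- default_age_schema()
  pop <- data.frame(country = "SAA", year = 2000, total_population = 1e6,
                    rural_share = 1)
  shares <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  for (i in seq_along(share_cols(sch))) pop[[share_cols(sch)[i]]] <- shares[i]
  pop <- population_panel(pop, sch)
  mor <- mortality_panel(data.frame(
    country = "SAA", year = 2000, age_band = sch$label, cause = "diarrhea",
    rate = c(50, 0, 0, 0, 100), rate_lo = c(50, 0, 0, 0, 100),
    rate_hi = c(50, 0, 0, 0, 100)), sch)
  paf <- data.frame(country = "SAA", year = 2000, cause = "diarrhea",
                    age_band = NA_character_, paf = 0.5)
  b <- attributable_deaths(pop, mor, paf)
  expect_equal(b$deaths[b$age_band == "<5"], 1e6 * 0.1 * 50 / 1e5 * 0.5)  # 25
  expect_equal(sum(b$deaths), 25 + 1e6 * 0.1 * 100 / 1e5 * 0.5)          # 75

  # PAF = 0 -> zero everywhere
  paf0 <- paf; paf0$paf <- 0
  expect_equal(sum(attributable_deaths(pop, mor, paf0)$deaths), 0)

  # halving rural share halves every cell
  pop_half <- as.data.frame(pop); pop_half$rural_share <- 0.5
  b2 <- attributable_deaths(population_panel(pop_half, sch), mor, paf)
  expect_equal(b2$deaths, b$deaths / 2)
})

test_that("cell-wise totals match pre-aggregated panels under uniform rates and PAFs", {
  sch <- default_age_schema()
  mk_pop <- function(country, popn) {
    d <- data.frame(country = country, year = 2000, total_population = popn,
                    rural_share = 1)
    shares <- c(0.2, 0.2, 0.2, 0.2, 0.2)
    for (i in seq_along(share_cols(sch))) d[[share_cols(sch)[i]]] <- shares[i]
    d
  }
  pop2 <- population_panel(rbind(mk_pop("SAA", 1e6), mk_pop("SAB", 3e6)), sch)
  mor2 <- mortality_panel(do.call(rbind, lapply(c("SAA", "SAB"), function(cc)
    data.frame(country = cc, year = 2000, age_band = sch$label,
               cause = "diarrhea", rate = 80, rate_lo = 80, rate_hi = 80))), sch)
  paf2 <- data.frame(country = c("SAA", "SAB"), year = 2000,
                     cause = "diarrhea", age_band = NA_character_, paf = 0.3)
  cellwise <- sum(attributable_deaths(pop2, mor2, paf2)$deaths)
  pooled <- attributable_deaths(
    population_panel(mk_pop("SAA", 4e6), sch),
    mortality_panel(mor2[mor2$country == "SAA", ], sch),
    paf2[paf2$country == "SAA", ])
  expect_equal(cellwise, sum(pooled$deaths), tolerance = 1e-12)
})

test_that("misaligned panels produce a join error", {
  sch <- default_age_schema()
  pop <- data.frame(country = "SAA", year = 2000, total_population = 1e6,
                    rural_share = 1)
  for (col in share_cols(sch)) pop[[col]] <- 0.2
  pop <- population_panel(pop, sch)
  mor <- mortality_panel(data.frame(
    country = "SAA", year = 2001, age_band = sch$label, cause = "diarrhea",
    rate = 50, rate_lo = 50, rate_hi = 50), sch)
  paf <- data.frame(country = "SAA", year = 2001, cause = "diarrhea",
                    age_band = NA_character_, paf = 0.5)
  expect_error(attributable_deaths(pop, mor, paf), "matching population")
})

test_that("standard population weights aggregate the WHO standard and renormalize", {
  std <- standard_population()
  expect_equal(sum(std), 1)
  expect_equal(unname(std["<5"]), 8.86 / 100.03, tolerance = 1e-3)
  expect_equal(unname(std["65+"]), 8.23 / 100.03, tolerance = 1e-3)
  custom <- standard_population(weights = setNames(c(2, 1, 1, 1, 1),
                                                   default_age_schema()$label))
  expect_equal(unname(custom["<5"]), 2 / 6)
})

test_that("ASR reduces to the weighted mean of crude rates and scales correctly", {
  sch <- age_schema(c("<5", "5+"), c(0, 5), c(4, Inf))
  mk <- function(popn) {
    d <- data.frame(country = "SAA", year = 2000, total_population = popn,
                    rural_share = 1)
    d[[share_cols(sch)[1]]] <- 0.5
    d[[share_cols(sch)[2]]] <- 0.5
    population_panel(d, sch)
  }
  pop <- mk(1e6)
  burden <- structure(data.frame(
    country = "SAA", year = 2000, age_band = sch$label, cause = "diarrhea",
    deaths = c(0.5e6 * 10 / 1e5, 0.5e6 * 30 / 1e5),
    deaths_lo = 0, deaths_hi = 1),
    age_schema = sch, class = c("burden_panel", "data.frame"))
  asr <- age_standardized_rate(burden, pop,
                               std = standard_population(sch, weights = c("<5" = 0.25, "5+" = 0.75)))
  expect_equal(asr$asr, 0.25 * 10 + 0.75 * 30)  # 25 per 100k

  # constant rates: ASR equals the common rate for any weights
  burden2 <- burden; burden2$deaths <- c(0.5e6, 0.5e6) * 20 / 1e5
  asr2 <- age_standardized_rate(burden2, pop, std = standard_population(sch))
  expect_equal(asr2$asr, 20)

  # weight 1 on one band gives that band's crude rate
  asr3 <- age_standardized_rate(burden, pop,
                                std = standard_population(sch, weights = c("<5" = 1, "5+" = 1e-12)))
  expect_equal(asr3$asr, 10, tolerance = 1e-9)

  # invariant under uniform population scaling at fixed rates
  pop10 <- mk(1e7)
  burden10 <- burden; burden10$deaths <- burden$deaths * 10
  asr4 <- age_standardized_rate(burden10, pop10,
                                std = standard_population(sch, weights = c("<5" = 0.25, "5+" = 0.75)))
  expect_equal(asr4$asr, asr$asr)
})
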