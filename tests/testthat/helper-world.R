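# Shared fixtures, built once per test run and cached.

share_cols <- sanburden:::share_cols   # internal column-name helper

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_world <- function() cached("small_world", {
  generate_world(world_config(n_countries = 3, year_start = 2000,
                              year_end = 2020, seed = 42))
})

# world with population through 2030 and observed panels through 2020,
# as the pipeline consumes it
projection_world <- function() cached("projection_world", {
  w <- generate_world(world_config(n_countries = 10, year_start = 2000,
                                   year_end = 2030, seed = 11))
  w$sanitation_hist <- sanitation_shares(
    as.data.frame(w$sanitation)[w$sanitation$year <= 2020, ])
  w$mortality_hist <- mortality_panel(
    as.data.frame(w$mortality)[w$mortality$year <= 2020, ],
    schema = attr(w$mortality, "age_schema"))
  w
})

quick_apc_config <- function(seed = 1L)
  apc_config(chains = 2, iter = 800, warmup = 300, seed = seed)

one_country_mortality <- function(world, code) {
  m <- world$mortality
  mortality_panel(as.data.frame(m)[m$country == code, ],
                  schema = attr(m, "age_schema"))
}

# a single-country noise-free mortality surface with chosen effects
flat_world_config <- function(seed = 1L, age_effects = c(2, 0, -0.5, 0.3, 1.8),
                              period_slope = 0, cohort_sd = 0, noise_sd = 0)
  world_config(n_countries = 1, year_start = 2000, year_end = 2020,
               seed = seed,
               mortality_effects = list(
                 base_log_rate_range = log(c(50, 50)),
                 age_effects = age_effects, period_slope = period_slope,
                 cohort_sd = cohort_sd, noise_sd = noise_sd,
                 ci_sigma = 0.10))

# random factor-state pair whose middle-band age profile is shared between
# t0 and t1 (the regime the aging mechanism produces), so the factor set
# covers every changed component exactly
random_state_pair <- function(seed) {
  set.seed(seed)
  labs <- default_age_schema()$label
  mk_shares <- function(s5, s65, profile) {
    mids <- profile / sum(profile) * (1 - s5 - s65)
    stats::setNames(c(s5, mids, s65), labs)
  }
  profile <- runif(3, 0.5, 1.5)
  s0 <- factor_state(
    population = runif(1, 1e6, 5e7),
    age_shares = mk_shares(runif(1, 0.08, 0.15), runif(1, 0.05, 0.10), profile),
    sanitation = { x <- runif(3); stats::setNames(x / sum(x),
                                                  c("sewer", "improved", "unimproved")) },
    rates = stats::setNames(runif(5, 5, 300), labs))
  s1 <- factor_state(
    population = s0$population * runif(1, 0.8, 1.3),
    age_shares = mk_shares(runif(1, 0.06, 0.13), runif(1, 0.06, 0.13), profile),
    sanitation = { x <- runif(3); stats::setNames(x / sum(x),
                                                  c("sewer", "improved", "unimproved")) },
    rates = stats::setNames(runif(5, 5, 300), labs))
  list(t0 = s0, t1 = s1)
}

default_rr <- function() rr_records(data.frame(
  exposure_category = c("unimproved", "improved"), cause = "diarrhea",
  rr = c(2.5, 1.3), rr_lo = c(1.8, 1.1), rr_hi = c(3.3, 1.6)))
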