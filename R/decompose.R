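#' Factor state: one time point's snapshot for the decomposition
#'
#' @param population total rural population (persons)
#' @param age_shares named fraction vector over the age schema (sums to 1)
#' @param sanitation named share triple `c(sewer, improved, unimproved)`
#' @param rates named age-specific cause death rates per 100,000
#' @return a `factor_state` list
#' @export
factor_state <- function(population, age_shares, sanitation, rates) {
  stopifnot(population >= 0, all(age_shares >= 0), all(rates >= 0))
  if (abs(sum(age_shares) - 1) > 1e-9) stop("age_shares must sum to 1")
  if (abs(sum(sanitation[SAN_CATEGORIES]) - 1) > 1e-9)
    stop("sanitation shares must sum to 1")
  stopifnot(setequal(names(age_shares), names(rates)))
  structure(list(population = population, age_shares = age_shares,
                 sanitation = sanitation[SAN_CATEGORIES],
                 rates = rates[names(age_shares)]),
            class = "factor_state")
}

#' Attributable deaths of a factor state
#'
#' Applies the attributable-fraction machinery to a single snapshot:
#' `deaths = POP * sum_a AgeP_a * (rate_a / 1e5) * PAF`, with the PAF
#' combined over the exposure categories carrying relative-risk records.
#' Deterministic; linear in the population and in the PAF.
#'
#' @param state a [factor_state()]
#' @param rr `rr_records` (held fixed across states)
#' @return attributable deaths (scalar)
#' @export
evaluate_deaths <- function(state, rr) {
  if (!inherits(rr, "rr_records")) rr <- rr_records(rr)
  pafs <- vapply(seq_len(nrow(rr)), function(i) {
    paf_single(unname(state$sanitation[rr$exposure_category[i]]), rr$rr[i])
  }, numeric(1))
  paf <- paf_combined(pafs)
  unname(state$population * sum(state$age_shares * state$rates / 1e5) * paf)
}

# ---- factor sets ------------------------------------------------------------

# A factor is a named list(get(state), set(state, value)). Swap operators
# must commute so the subset value function is well defined: the 65+ and <5
# swaps rescale only the untracked middle bands, never each other.

swap_age_share <- function(state, band, value) {
  sh <- state$age_shares
  tracked <- attr(value, "tracked")
  others <- setdiff(names(sh), tracked)
  rest_mass <- 1 - sum(sh[setdiff(tracked, band)]) - value
  if (rest_mass < -1e-12)
    stop(sprintf("age-share swap of %s to %.4f leaves no mass for other bands",
                 band, value))
  rest_mass <- max(rest_mass, 0)
  cur <- sum(sh[others])
  sh[band] <- value
  sh[others] <- if (cur > 0) sh[others] * rest_mass / cur
                else rep(rest_mass / length(others), length(others))
  state$age_shares <- sh / sum(sh)
  state
}

#' Default factor sets for the decomposition
#'
#' `factor_set_five()` returns the five-factor set: total population,
#' 65+ share, <5 share, sanitation shares, mortality rates. Swapping the
#' 65+ (or <5) share rescales only the untracked middle bands so the age
#' vector stays on the simplex and the two age swaps commute.
#' `factor_set_four()` groups the age structure into one factor (the whole
#' age-share vector swaps at once).
#'
#' @param band_under5,band_65plus labels of the young / old bands in the
#'   age schema
#' @return a named list of factors usable by [decompose()]
#' @export
factor_set_five <- function(band_under5 = "<5", band_65plus = "65+") {
  tracked <- c(band_under5, band_65plus)
  mk_age <- function(band) list(
    get = function(s) {
      v <- unname(s$age_shares[band]); attr(v, "tracked") <- tracked; v
    },
    set = function(s, v) swap_age_share(s, band, v))
  list(
    total_population = list(get = function(s) s$population,
                            set = function(s, v) { s$population <- v; s }),
    share_65plus = mk_age(band_65plus),
    share_under5 = mk_age(band_under5),
    sanitation = list(get = function(s) s$sanitation,
                      set = function(s, v) { s$sanitation <- v; s }),
    mortality = list(get = function(s) s$rates,
                     set = function(s, v) { s$rates <- v; s }))
}

#' @rdname factor_set_five
#' @export
factor_set_four <- function() {
  list(
    total_population = list(get = function(s) s$population,
                            set = function(s, v) { s$population <- v; s }),
    age_structure = list(get = function(s) s$age_shares,
                         set = function(s, v) { s$age_shares <- v; s }),
    sanitation = list(get = function(s) s$sanitation,
                      set = function(s, v) { s$sanitation <- v; s }),
    mortality = list(get = function(s) s$rates,
                     set = function(s, v) { s$rates <- v; s }))
}

apply_subset <- function(state_t0, state_t1, factors, members) {
  s <- state_t0
  for (nm in members) s <- factors[[nm]]$set(s, factors[[nm]]$get(state_t1))
  s
}

#' Marginal contributions along one ordering of factor introduction
#'
#' Walks the ordering, swapping one factor at a time from its t0 to its t1
#' value and recording the change in the value function at each step. The
#' deltas telescope: they sum exactly to `v(all swapped) - v(t0)`.
#'
#' @param ordering character permutation of the factor names
#' @param state_t0,state_t1 [factor_state()]s (or arbitrary lists when a
#'   custom `factors`/`value_fun` pair is used)
#' @param factors a factor set ([factor_set_five()] by default)
#' @param value_fun function of a state returning the decomposed scalar;
#'   defaults to [evaluate_deaths()] with `rr`
#' @param rr `rr_records` for the default value function
#' @return named numeric vector of per-factor deltas, in ordering order
#' @export
marginal_contribution <- function(ordering, state_t0, state_t1,
                                  factors = factor_set_five(),
                                  value_fun = NULL, rr = NULL) {
  if (!setequal(ordering, names(factors)) ||
      length(ordering) != length(factors))
    stop("ordering must be a permutation of the factor names")
  if (is.null(value_fun)) {
    if (is.null(rr)) stop("supply rr for the default deaths value function")
    value_fun <- function(s) evaluate_deaths(s, rr)
  }
  s <- state_t0
  prev <- value_fun(s)
  deltas <- stats::setNames(numeric(length(ordering)), ordering)
  for (nm in ordering) {
    s <- factors[[nm]]$set(s, factors[[nm]]$get(state_t1))
    cur <- value_fun(s)
    deltas[nm] <- cur - prev
    prev <- cur
  }
  deltas
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in all_permutations(x[-i]))
      out[[length(out) + 1]] <- c(x[i], p)
  out
}

#' Decompose a change in attributable deaths into factor contributions
#'
#' The contribution of each factor is its marginal effect averaged over
#' all `|F|!` orderings of factor introduction — the Shapley value of the
#' coalitional game whose value function is the attributable-death count
#' of the partially swapped state. Contributions sum exactly to the total
#' change. The default method evaluates the `2^|F|` factor subsets once
#' each and combines them with the exact Shapley weights; `method =
#' "orderings"` enumerates all orderings naively (the test oracle) and
#' gives identical results.
#'
#' @param state_t0,state_t1 start and end [factor_state()]s
#' @param factors a factor set (default [factor_set_five()])
#' @param value_fun optional custom scalar value function of a state
#' @param rr `rr_records` for the default deaths value function
#' @param method `"subsets"` (memoized, default) or `"orderings"` (naive)
#' @return a `decomposition_result`: `contributions` (named, in deaths,
#'   signed), `total_change`, `orderings` (count averaged over), `method`
#' @export
decompose <- function(state_t0, state_t1, factors = factor_set_five(),
                      value_fun = NULL, rr = NULL,
                      method = c("subsets", "orderings")) {
  method <- match.arg(method)
  nf <- length(factors)
  if (nf > 8) stop("more than 8 factors: exhaustive enumeration refused")
  if (is.null(value_fun)) {
    if (is.null(rr)) stop("supply rr for the default deaths value function")
    value_fun <- function(s) evaluate_deaths(s, rr)
  }
  nms <- names(factors)
  if (method == "orderings") {
    perms <- all_permutations(nms)
    contrib <- stats::setNames(numeric(nf), nms)
    for (p in perms)
      contrib <- contrib + marginal_contribution(p, state_t0, state_t1,
                                                 factors, value_fun)[nms]
    contrib <- contrib / length(perms)
    total <- sum(contrib)
  } else {
    # value of every subset, indexed by bitmask
    v <- numeric(2^nf)
    for (mask in 0:(2^nf - 1)) {
      members <- nms[bitwAnd(mask, 2^(seq_len(nf) - 1)) > 0]
      v[mask + 1] <- value_fun(apply_subset(state_t0, state_t1, factors, members))
    }
    fact <- factorial(0:nf)
    contrib <- stats::setNames(numeric(nf), nms)
    for (i in seq_len(nf)) {
      bit <- 2^(i - 1)
      for (mask in 0:(2^nf - 1)) {
        if (bitwAnd(mask, bit) > 0) next
        s <- sum(bitwAnd(mask, 2^(seq_len(nf) - 1)) > 0)
        w <- fact[s + 1] * fact[nf - s] / fact[nf + 1]
        contrib[i] <- contrib[i] + w * (v[mask + bit + 1] - v[mask + 1])
      }
    }
    total <- v[2^nf] - v[1]
  }
  end_state <- apply_subset(state_t0, state_t1, factors, nms)
  v_t1 <- value_fun(state_t1)
  v_end <- value_fun(end_state)
  if (abs(v_end - v_t1) > 1e-6 * max(1, abs(v_t1)))
    warning(sprintf(paste("decompose: fully swapped state differs from the",
                          "t1 state (%.6g vs %.6g); a state component not",
                          "covered by the factor set changed between t0 and t1"),
                    v_end, v_t1))
  structure(list(contributions = contrib, total_change = total,
                 orderings = factorial(nf), method = method),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("decomposition over %d orderings (%s method)\n",
              x$orderings, x$method))
  for (nm in names(x$contributions))
    cat(sprintf("  %-18s %12.2f deaths\n", nm, x$contributions[nm]))
  cat(sprintf("  %-18s %12.2f deaths\n", "total change", x$total_change))
  invisible(x)
}

# Build the factor state of one country at one breakpoint year from the
# pipeline's panels. Rates: the cause-specific mortality column for that
# year (observed or projected).
build_factor_state <- function(country, year, population, sanitation,
                               mortality, schema) {
  p <- population[population$country == country & population$year == year, ]
  s <- sanitation[sanitation$country == country & sanitation$year == year, ]
  m <- mortality[mortality$country == country & mortality$year == year, ]
  if (!nrow(p) || !nrow(s) || nrow(m) < nrow(schema))
    stop(sprintf("missing breakpoint data for %s in %d", country, year))
  shares <- stats::setNames(as.numeric(p[1, share_cols(schema)]), schema$label)
  rates <- stats::setNames(m$rate[match(schema$label, m$age_band)], schema$label)
  factor_state(population = p$total_population[1] * p$rural_share[1],
               age_shares = shares,
               sanitation = stats::setNames(
                 as.numeric(s[1, SAN_CATEGORIES]), SAN_CATEGORIES),
               rates = rates)
}

#' Decompose attributable-death changes over a timeline of breakpoints
#'
#' Builds per-country factor states at each breakpoint year from the
#' supplied panels (observed or projected) and runs [decompose()] on each
#' consecutive pair. Aggregated contributions are the sums over countries
#' (the value function is additive across countries, so the Shapley
#' decomposition is too). Interval totals telescope across consecutive
#' intervals.
#'
#' @param population a `population_panel` covering the breakpoints
#' @param sanitation a `sanitation_shares` panel covering the breakpoints
#'   (projected rows included)
#' @param mortality a `mortality_panel` covering the breakpoints
#' @param rr `rr_records`
#' @param breakpoints increasing vector of breakpoint years
#' @param factors factor set (default [factor_set_five()] with the
#'   schema's first and last band labels)
#' @return data frame: country (or `"TOTAL"`), interval, factor,
#'   contribution_deaths, total_change_deaths
#' @export
decompose_timeline <- function(population, sanitation, mortality, rr,
                               breakpoints, factors = NULL) {
  stopifnot(length(breakpoints) >= 2, !is.unsorted(breakpoints))
  schema <- attr(mortality, "age_schema")
  if (is.null(schema)) schema <- default_age_schema()
  if (is.null(factors))
    factors <- factor_set_five(band_under5 = schema$label[1],
                               band_65plus = schema$label[nrow(schema)])
  countries <- sort(Reduce(intersect, list(unique(population$country),
                                           unique(sanitation$country),
                                           unique(mortality$country))))
  rows <- list()
  for (bi in seq_len(length(breakpoints) - 1)) {
    y0 <- breakpoints[bi]; y1 <- breakpoints[bi + 1]
    interval <- sprintf("%d-%d", y0, y1)
    tot <- NULL
    for (cc in countries) {
      s0 <- build_factor_state(cc, y0, population, sanitation, mortality, schema)
      s1 <- build_factor_state(cc, y1, population, sanitation, mortality, schema)
      dc <- decompose(s0, s1, factors = factors, rr = rr)
      rows[[length(rows) + 1]] <- data.frame(
        country = cc, interval = interval,
        factor = names(dc$contributions),
        contribution_deaths = unname(dc$contributions),
        total_change_deaths = dc$total_change,
        stringsAsFactors = FALSE)
      tot <- if (is.null(tot)) dc$contributions else tot + dc$contributions
    }
    rows[[length(rows) + 1]] <- data.frame(
      country = "TOTAL", interval = interval, factor = names(tot),
      contribution_deaths = unname(tot), total_change_deaths = sum(tot),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
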