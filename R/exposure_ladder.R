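#' Sanitation-ladder normalization
#'
#' Normalizes raw facility responses into the three-rung exposure
#' distribution. With `n` non-missing respondents, `s` of whom report a
#' sewer/septic connection and `m` of the remaining `n - s` an improved
#' facility:
#' \deqn{sewer = s / n}
#' \deqn{improved = (m / (n - s)) (1 - sewer)}
#' \deqn{unimproved = 1 - sewer - improved}
#' When `n = s` (fully sewered), `improved` is 0 by the limit of the second
#' expression, not a 0/0 error.
#'
#' @param raw a `sanitation_raw_panel` (any number of rows)
#' @return a `sanitation_shares` panel, each triple exactly on the simplex
#' @examples
#' raw <- sanitation_raw_panel(data.frame(
#'   country = "SAA", year = 2000, nonmissing_respondents = 100,
#'   sewer_respondents = 20, improved_respondents_among_nonsewer = 40))
#' normalize_ladder(raw)  # shares (0.20, 0.40, 0.40)
#' @export
normalize_ladder <- function(raw) {
  if (!inherits(raw, "sanitation_raw_panel")) raw <- sanitation_raw_panel(raw)
  n <- raw$nonmissing_respondents
  s <- raw$sewer_respondents
  m <- raw$improved_respondents_among_nonsewer
  if (any(n == 0)) {
    i <- which(n == 0)[1]
    stop(sprintf("undefined exposure: zero nonmissing respondents for (%s, %d)",
                 raw$country[i], raw$year[i]))
  }
  sewer <- s / n
  improved <- ifelse(n == s, 0, (m / (n - s)) * (1 - sewer))
  sanitation_shares(data.frame(country = raw$country, year = raw$year,
                               sewer = sewer, improved = improved,
                               unimproved = 1 - (sewer + improved),
                               stringsAsFactors = FALSE))
}

#' Exposed fraction under a configurable unsafe-sanitation definition
#'
#' Sums the shares of the categories counted as exposed. Under the default
#' per-category relative-risk scheme each non-referent category enters the
#' attributable-fraction computation with its own share; this helper serves
#' the dichotomous "unsafe sanitation" definition where one PAF factor
#' covers a set of rungs.
#'
#' @param shares a `sanitation_shares` panel or a single named share triple
#' @param definition character subset of `c("unimproved", "improved")`
#' @return numeric vector of exposed fractions (one per row)
#' @export
unsafe_fraction <- function(shares, definition = "unimproved") {
  bad <- setdiff(definition, c("unimproved", "improved"))
  if (length(bad))
    stop(sprintf("unknown exposure category: %s", paste(bad, collapse = ", ")))
  if (length(definition) == 0) {
    n <- if (is.data.frame(shares)) nrow(shares) else 1L
    return(rep(0, n))
  }
  if (is.data.frame(shares))
    rowSums(as.data.frame(shares)[, definition, drop = FALSE])
  else
    sum(unlist(shares[definition]))
}
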