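#' Age-band schemas
#'
#' An age schema is a data frame with one row per band and columns
#' `label` (character), `lower` (integer years, >= 0) and `upper`
#' (integer years; `Inf` marks the open-ended terminal band). Bands must be
#' non-overlapping, ordered by `lower`, and jointly cover `[0, Inf)`:
#' each band spans ages `lower` to `upper` inclusive, and the next band
#' starts at `upper + 1`.
#'
#' @param labels character vector of band labels
#' @param lower integer vector of lower bounds (years)
#' @param upper numeric vector of upper bounds (years; `Inf` for the last)
#' @return a validated `age_schema` data frame
#' @examples
#' age_schema(c("<5", "5+"), c(0, 5), c(4, Inf))
#' @export
age_schema <- function(labels, lower, upper) {
  stopifnot(length(labels) == length(lower), length(lower) == length(upper))
  sch <- data.frame(label = as.character(labels),
                    lower = as.numeric(lower),
                    upper = as.numeric(upper),
                    stringsAsFactors = FALSE)
  validate_age_schema(sch)
  class(sch) <- c("age_schema", "data.frame")
  sch
}

validate_age_schema <- function(sch) {
  if (any(duplicated(sch$label)))
    stop("age schema labels must be unique")
  if (is.unsorted(sch$lower, strictly = TRUE))
    stop("age schema bands must be ordered by lower bound")
  if (sch$lower[1] != 0)
    stop("age schema must start at age 0")
  n <- nrow(sch)
  if (!is.infinite(sch$upper[n]))
    stop("terminal age band must be open-ended (upper = Inf)")
  if (any(sch$upper[-n] < sch$lower[-n]))
    stop("age band upper bounds must be >= lower bounds")
  gaps <- sch$lower[-1] - (sch$upper[-n] + 1)
  if (any(gaps != 0))
    stop("age bands must be contiguous (next lower = previous upper + 1)")
  invisible(sch)
}

#' Default five-band age schema
#'
#' `{<5, 5-14, 15-49, 50-64, 65+}`: the smallest schema that keeps the
#' under-five and over-65 risk groups (where diarrhea mortality concentrates)
#' as separate bands. All panel constructors accept any [age_schema()].
#'
#' @return an `age_schema` data frame with five bands
#' @export
default_age_schema <- function() {
  age_schema(labels = c("<5", "5-14", "15-49", "50-64", "65+"),
             lower  = c(0, 5, 15, 50, 65),
             upper  = c(4, 14, 49, 64, Inf))
}

#' Age-band midpoints in years
#'
#' Midpoint of `[lower, upper + 1)`; the open-ended terminal band uses
#' `lower + 10` (a pragmatic central age for a 65+ band). Midpoints anchor
#' the cohort mapping `cohort = period - midpoint`.
#'
#' @param schema an [age_schema()]
#' @return numeric vector of midpoints, one per band
#' @export
age_band_midpoints <- function(schema) {
  mid <- (schema$lower + schema$upper + 1) / 2
  open <- is.infinite(schema$upper)
  mid[open] <- schema$lower[open] + 10
  stats::setNames(mid, schema$label)
}

# Sanitize a band label into a CSV column suffix: "<5" -> "lt5",
# "65+" -> "65plus", "5-14" -> "5_14".
san_label <- function(label) {
  x <- gsub("<", "lt", label, fixed = TRUE)
  x <- gsub("+", "plus", x, fixed = TRUE)
  gsub("[^A-Za-z0-9]", "_", x)
}

share_cols <- function(schema) paste0("share_", san_label(schema$label))
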