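#' KPSS level-stationarity statistic
#'
#' Test statistic of the null "the series is level-stationary": partial
#' sums of demeaned values scaled by a Bartlett-window long-run variance.
#' The 5% critical value is 0.463; values above it indicate a unit root.
#' Used internally to pick the differencing degree.
#'
#' @param x numeric series
#' @param lags Bartlett truncation lag (default `trunc(4 (n/100)^0.25)`)
#' @return the KPSS statistic (scalar)
#' @export
kpss_statistic <- function(x, lags = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(lags)) lags <- trunc(4 * (n / 100)^0.25)
  e <- x - mean(x)
  S <- cumsum(e)
  s2 <- sum(e^2) / n
  if (lags > 0) {
    for (l in seq_len(lags)) {
      w <- 1 - l / (lags + 1)
      s2 <- s2 + 2 * w * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  if (s2 <= 0) return(0)
  sum(S^2) / (n^2 * s2)
}

aicc_of <- function(fit, n_eff) {
  k <- length(fit$coef) + 1   # + innovation variance
  if (n_eff - k - 1 <= 0) return(Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n_eff - k - 1)
}

is_constant <- function(x, tol = 1e-12) stats::sd(x) < tol * (1 + abs(mean(x)))

#' Automatic ARIMA order selection
#'
#' The differencing degree `d` is chosen first by repeated KPSS testing
#' (difference while the statistic exceeds the 5% critical value 0.463, up
#' to `max_d`); `p` and `q` are then selected by grid search minimizing the
#' small-sample-corrected information criterion (AICc) at that `d`, with
#' ties broken toward the smallest `p + q`, then the smallest `p`.
#' Information criteria are not comparable across differencing degrees
#' (the data change), so `d` is not revisited inside the grid. A constant
#' series selects `(0, 0, 0)` (fitted with an intercept).
#'
#' @param series numeric series, length >= 10
#' @param max_p,max_d,max_q grid bounds
#' @return an `arima_order`: list `(p, d, q)`
#' @export
select_order <- function(series, max_p = 3, max_d = 2, max_q = 3) {
  x <- as.numeric(series)
  if (length(x) < 10) stop("select_order: series must have >= 10 points")
  if (is_constant(x)) return(arima_order(0, 0, 0))
  d <- 0
  xd <- x
  while (d < max_d && !is_constant(xd) && kpss_statistic(xd) > 0.463) {
    xd <- diff(xd); d <- d + 1
  }
  n_eff <- length(x) - d
  best <- NULL; best_ic <- Inf
  for (s in 0:(max_p + max_q)) {          # visit parsimonious orders first
    for (p in 0:min(s, max_p)) {
      q <- s - p
      if (q > max_q) next
      fit <- try(suppressWarnings(
        stats::arima(x, order = c(p, d, q), include.mean = (d == 0),
                     method = "ML")), silent = TRUE)
      if (inherits(fit, "try-error")) next
      ic <- aicc_of(fit, n_eff)
      if (ic < best_ic - 1e-8) { best_ic <- ic; best <- c(p, d, q) }
    }
  }
  if (is.null(best)) stop("select_order: no candidate order could be fitted")
  arima_order(best[1], best[2], best[3])
}

#' ARIMA order triple
#'
#' @param p,d,q non-negative integer AR, differencing and MA orders
#' @return an `arima_order` list
#' @export
arima_order <- function(p, d, q) {
  stopifnot(p >= 0, d >= 0, q >= 0,
            p == round(p), d == round(d), q == round(q))
  structure(list(p = as.integer(p), d = as.integer(d), q = as.integer(q)),
            class = "arima_order")
}

#' Fit an ARIMA model by maximum likelihood
#'
#' Wraps `stats::arima` (exact Kalman-filter likelihood) with stationarity
#' of the AR polynomial enforced; a failed ML fit is retried with CSS
#' initialization. Constant series with `d >= 1` yield a degenerate fit
#' with (near) zero innovation variance and a flat forecast.
#'
#' @param series numeric series
#' @param order an [arima_order()] or length-3 integer vector `(p, d, q)`
#' @param include_mean include an intercept when `d = 0`
#' @return an `arima_fit`: the order, `phi` and `theta` coefficients,
#'   `sigma2`, AICc, and the underlying `stats::arima` model
#' @export
fit_arima <- function(series, order, include_mean = TRUE) {
  x <- as.numeric(series)
  if (!inherits(order, "arima_order")) order <- arima_order(order[1], order[2], order[3])
  ovec <- c(order$p, order$d, order$q)
  im <- include_mean && order$d == 0
  if (is_constant(x)) {
    # degenerate series: zero innovation variance, flat forecast
    return(structure(list(order = order, phi = numeric(), theta = numeric(),
                          mean = mean(x), sigma2 = 0, aicc = -Inf,
                          model = NULL, n = length(x), last = x[length(x)],
                          series_id = attr(series, "series_id")),
                     class = "arima_fit"))
  }
  fit <- try(suppressWarnings(
    stats::arima(x, order = ovec, include.mean = im, method = "ML")),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    fit <- try(suppressWarnings(
      stats::arima(x, order = ovec, include.mean = im, method = "CSS-ML")),
      silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("fit_arima: maximum-likelihood fit failed for order (",
         paste(ovec, collapse = ","), ")")
  phi <- if (order$p) unname(fit$coef[paste0("ar", seq_len(order$p))]) else numeric()
  theta <- if (order$q) unname(fit$coef[paste0("ma", seq_len(order$q))]) else numeric()
  if (length(phi) && min(Mod(polyroot(c(1, -phi)))) < 1 - 1e-6)
    stop("fit_arima: non-stationary AR polynomial at the optimum")
  structure(list(order = order, phi = phi, theta = theta,
                 mean = if (im) unname(fit$coef["intercept"]) else NA_real_,
                 sigma2 = fit$sigma2,
                 aicc = aicc_of(fit, length(x) - order$d),
                 model = fit, n = length(x),
                 series_id = attr(series, "series_id")),
            class = "arima_fit")
}

#' Forecast from a fitted ARIMA model
#'
#' h-step point forecasts with Gaussian 95% prediction intervals built from
#' the innovation variance through the psi-weights (via the exact Kalman
#' prediction of `stats::predict.Arima`). Interval width is weakly
#' increasing in the horizon.
#'
#' @param fit an `arima_fit`
#' @param horizon number of steps ahead (>= 1)
#' @param level interval coverage (default 0.95)
#' @return data frame: `h`, `mean`, `lo`, `hi`
#' @export
forecast_series <- function(fit, horizon, level = 0.95) {
  stopifnot(inherits(fit, "arima_fit"))
  if (horizon < 1) stop("forecast_series: horizon must be >= 1")
  if (is.null(fit$model)) {           # degenerate constant-series fit
    flat <- if (fit$order$d >= 1) fit$last else fit$mean
    return(data.frame(h = seq_len(horizon), mean = rep(flat, horizon),
                      lo = rep(flat, horizon), hi = rep(flat, horizon)))
  }
  pr <- stats::predict(fit$model, n.ahead = horizon)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(h = seq_len(horizon),
             mean = as.numeric(pr$pred),
             lo = as.numeric(pr$pred) - z * as.numeric(pr$se),
             hi = as.numeric(pr$pred) + z * as.numeric(pr$se))
}

#' Forecast a sanitation-share composition for one country
#'
#' Default (`mode = "alr"`): the share triple is mapped to two additive
#' log-ratio coordinates (reference category: sewer), each coordinate is
#' forecast by [select_order()] + [fit_arima()] + [forecast_series()], and
#' forecasts are back-transformed so every point triple lies exactly on
#' the simplex. Component-wise 95% bounds are the extremes of the
#' back-transformed corners of the two coordinates' interval box.
#' `mode = "independent"` instead forecasts each share separately, clips
#' to `[0, 1]` and renormalizes the point forecasts (flagged in the
#' output), mirroring a forecast run without the simplex constraint.
#'
#' Historical zeros are floored at `epsilon` (with a warning) before the
#' log-ratio transform.
#'
#' @param shares a `sanitation_shares` panel for a single country with at
#'   least 10 years of history
#' @param horizon years ahead to forecast
#' @param mode `"alr"` (default) or `"independent"`
#' @param epsilon floor applied to zero shares in transform mode
#' @param max_p,max_d,max_q order-selection grid bounds
#' @return a `sanitation_shares`-shaped data frame for the forecast years
#'   with `<cat>_lo` / `<cat>_hi` columns and columns `source = "projected"`
#'   and `mode`
#' @export
forecast_composition <- function(shares, horizon, mode = c("alr", "independent"),
                                 epsilon = 1e-6, max_p = 2, max_d = 2, max_q = 2) {
  mode <- match.arg(mode)
  df <- as.data.frame(shares)
  if (length(unique(df$country)) != 1)
    stop("forecast_composition: supply a single country's history")
  df <- df[order(df$year), ]
  if (nrow(df) < 10) stop("forecast_composition: need >= 10 years of history")
  years_new <- max(df$year) + seq_len(horizon)
  S <- as.matrix(df[SAN_CATEGORIES])
  if (mode == "alr") {
    if (any(S == 0)) {
      warning("forecast_composition: zero share(s) floored at epsilon")
      S <- pmax(S, epsilon)
      S <- S / rowSums(S)
    }
    y1 <- log(S[, "improved"] / S[, "sewer"])
    y2 <- log(S[, "unimproved"] / S[, "sewer"])
    fc <- lapply(list(y1, y2), function(y) {
      ord <- select_order(y, max_p = max_p, max_d = max_d, max_q = max_q)
      forecast_series(fit_arima(y, ord), horizon)
    })
    back <- function(a, b) {           # alr^{-1}: coords -> simplex triple
      e <- cbind(1, exp(a), exp(b))
      e / rowSums(e)
    }
    pt <- back(fc[[1]]$mean, fc[[2]]$mean)
    corners <- list(back(fc[[1]]$lo, fc[[2]]$lo), back(fc[[1]]$lo, fc[[2]]$hi),
                    back(fc[[1]]$hi, fc[[2]]$lo), back(fc[[1]]$hi, fc[[2]]$hi))
    lo <- pmin(pt, Reduce(pmin, corners))
    hi <- pmax(pt, Reduce(pmax, corners))
  } else {
    per <- lapply(SAN_CATEGORIES, function(cat) {
      y <- S[, cat]
      ord <- select_order(y, max_p = max_p, max_d = max_d, max_q = max_q)
      forecast_series(fit_arima(y, ord), horizon)
    })
    clip <- function(v) pmin(pmax(v, 0), 1)
    ptm <- clip(sapply(per, `[[`, "mean"))
    ptm <- matrix(ptm, nrow = horizon)
    pt <- ptm / rowSums(ptm)
    lo <- clip(matrix(sapply(per, `[[`, "lo"), nrow = horizon))
    hi <- clip(matrix(sapply(per, `[[`, "hi"), nrow = horizon))
  }
  colnames(pt) <- SAN_CATEGORIES
  out <- data.frame(country = unique(df$country), year = years_new,
                    stringsAsFactors = FALSE)
  for (ci in seq_along(SAN_CATEGORIES)) {
    cat <- SAN_CATEGORIES[ci]
    out[[cat]] <- pt[, ci]
    out[[paste0(cat, "_lo")]] <- pmin(lo[, ci], pt[, ci])
    out[[paste0(cat, "_hi")]] <- pmax(hi[, ci], pt[, ci])
  }
  out$source <- "projected"
  out$mode <- mode
  out
}
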