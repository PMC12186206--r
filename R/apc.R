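#' Settings for the Bayesian age-period-cohort fit
#'
#' The model for one country's mortality surface is
#' `log(rate_ij) = alpha + A_i + P_j + C_k + eps_ij`, with `i` the age
#' band, `j` the period (calendar year) and `k` the 5-year cohort bin of
#' `period - age-band midpoint`. `A`, `P`, `C` carry second-order
#' random-walk (RW2) smoothing priors with Gamma precision hyperpriors
#' (the standard Bayesian APC construction); `eps` is iid Gaussian on the
#' log scale. All full conditionals are closed-form, so the posterior is
#' sampled by a blocked conjugate Gibbs sampler: the whole coefficient
#' vector jointly given the precisions, then each precision given the
#' coefficients.
#'
#' @param chains number of MCMC chains
#' @param iter iterations per chain (including warm-up)
#' @param warmup warm-up iterations discarded per chain
#' @param seed integer seed; chain `c` uses `seed + c`
#' @param rw_prior_shape,rw_prior_rate Gamma hyperprior on each RW2
#'   precision (shape 1, rate 0.01: weakly informative, favours smoothness
#'   only mildly)
#' @param noise_prior_shape,noise_prior_rate Gamma hyperprior on the
#'   residual precision
#' @param cohort_bin_width width of cohort bins in years
#' @param rhat_max convergence threshold on the split-chain statistic
#' @return an `apc_config` list
#' @export
apc_config <- function(chains = 2, iter = 1500, warmup = 500, seed = 1L,
                       rw_prior_shape = 1, rw_prior_rate = 0.01,
                       noise_prior_shape = 0.01, noise_prior_rate = 0.01,
                       cohort_bin_width = 5, rhat_max = 1.05) {
  stopifnot(chains >= 1, iter > warmup, iter - warmup >= 100)
  structure(list(chains = chains, iter = iter, warmup = warmup,
                 seed = as.integer(seed),
                 rw_prior_shape = rw_prior_shape,
                 rw_prior_rate = rw_prior_rate,
                 noise_prior_shape = noise_prior_shape,
                 noise_prior_rate = noise_prior_rate,
                 cohort_bin_width = cohort_bin_width,
                 rhat_max = rhat_max),
            class = "apc_config")
}

# second-difference penalty matrix D'D for an RW2 prior of length n
rw2_penalty <- function(n) {
  if (n < 3) return(diag(0, n))
  D <- diff(diag(n), differences = 2)
  crossprod(D)
}

split_rhat <- function(mat) {
  # mat: iterations x chains; split each chain in half
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mu <- colMeans(sub)
  W <- mean(apply(sub, 2, stats::var))
  B <- nn * stats::var(mu)
  if (W < 1e-300) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Fit the Bayesian age-period-cohort model to one country's surface
#'
#' Requires a complete age x period grid for a single country and cause,
#' with at least 3 age bands and 5 periods. Zero rates are replaced by half
#' the smallest positive rate in the surface before taking logs (with a
#' warning). The exact linear dependence `cohort = period - age` leaves the
#' model unidentified; raw draws are therefore post-processed for
#' reporting: cohort effects are detrended (level and slope reassigned to
#' the intercept, period and age effects, leaving every fitted cell
#' unchanged), and `A`, `P`, `C` are centered to sum to zero with the
#' levels absorbed into `alpha`. The constraint record documents this.
#'
#' @param mortality a `mortality_panel` restricted to one country
#' @param config an [apc_config()]
#' @param cause cause to model (default: the panel's single cause)
#' @return an `apc_posterior`: posterior summaries (`summary`), raw draws,
#'   split-chain convergence diagnostics (`diagnostics`, `converged`), the
#'   constraint record, and the cell mapping needed for projection
#' @export
fit_apc <- function(mortality, config = apc_config(), cause = NULL) {
  df <- as.data.frame(mortality)
  if (length(unique(df$country)) != 1)
    stop("fit_apc: supply a single country's surface")
  if (is.null(cause)) {
    cause <- unique(df$cause)
    if (length(cause) != 1) stop("fit_apc: specify the cause to model")
  }
  df <- df[df$cause == cause, ]
  sch <- attr(mortality, "age_schema")
  if (is.null(sch)) sch <- default_age_schema()
  years <- sort(unique(df$year))
  I <- nrow(sch); J <- length(years)
  if (I < 3) stop("fit_apc: need at least 3 age bands")
  if (J < 5) stop("fit_apc: need at least 5 periods")
  if (nrow(df) != I * J) stop("fit_apc: incomplete age x period grid")
  df$age_idx <- match(df$age_band, sch$label)
  df$per_idx <- match(df$year, years)
  mids <- age_band_midpoints(sch)
  bins <- cohort_bin_grid(years, mids, width = config$cohort_bin_width)
  K <- length(bins$grid)
  df$coh_idx <- bins$index[cbind(df$age_idx, df$per_idx)]

  rate <- df$rate
  if (any(rate == 0)) {
    repl <- min(rate[rate > 0]) / 2
    if (!is.finite(repl)) stop("fit_apc: all rates are zero")
    warning(sprintf("fit_apc: %d zero rate(s) replaced by %.4g before log",
                    sum(rate == 0), repl))
    rate[rate == 0] <- repl
  }
  y <- log(rate)
  n <- length(y)

  # design: [alpha | A (I) | P (J) | C (K)]
  p <- 1 + I + J + K
  X <- matrix(0, n, p)
  X[, 1] <- 1
  X[cbind(seq_len(n), 1 + df$age_idx)] <- 1
  X[cbind(seq_len(n), 1 + I + df$per_idx)] <- 1
  X[cbind(seq_len(n), 1 + I + J + df$coh_idx)] <- 1
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)

  KA <- rw2_penalty(I); KP <- rw2_penalty(J); KC <- rw2_penalty(K)
  iA <- 1 + seq_len(I); iP <- 1 + I + seq_len(J); iC <- 1 + I + J + seq_len(K)
  ridge <- diag(c(1 / 100, rep(0.01, I + J + K)))  # proper N(0,100) backdrop

  n_save <- config$iter - config$warmup
  draws <- list(alpha = matrix(NA_real_, n_save, config$chains),
                A = array(NA_real_, c(n_save, I, config$chains)),
                P = array(NA_real_, c(n_save, J, config$chains)),
                C = array(NA_real_, c(n_save, K, config$chains)),
                tau = array(NA_real_, c(n_save, 4, config$chains),
                            dimnames = list(NULL, c("A", "P", "C", "eps"), NULL)))
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch)
    tau <- c(A = 10, P = 10, C = 10, eps = 10)
    beta <- rep(0, p)
    for (it in seq_len(config$iter)) {
      Q <- tau["eps"] * XtX + ridge
      Q[iA, iA] <- Q[iA, iA] + tau["A"] * KA
      Q[iP, iP] <- Q[iP, iP] + tau["P"] * KP
      Q[iC, iC] <- Q[iC, iC] + tau["C"] * KC
      R <- chol(Q)
      mu <- backsolve(R, backsolve(R, tau["eps"] * Xty, transpose = TRUE))
      beta <- mu + backsolve(R, stats::rnorm(p))
      res <- y - X %*% beta
      tau["eps"] <- stats::rgamma(1, config$noise_prior_shape + n / 2,
                                  config$noise_prior_rate + sum(res^2) / 2)
      qa <- drop(crossprod(beta[iA], KA %*% beta[iA]))
      qp <- drop(crossprod(beta[iP], KP %*% beta[iP]))
      qc <- drop(crossprod(beta[iC], KC %*% beta[iC]))
      tau["A"] <- stats::rgamma(1, config$rw_prior_shape + (I - 2) / 2,
                                config$rw_prior_rate + qa / 2)
      tau["P"] <- stats::rgamma(1, config$rw_prior_shape + (J - 2) / 2,
                                config$rw_prior_rate + qp / 2)
      tau["C"] <- stats::rgamma(1, config$rw_prior_shape + (K - 2) / 2,
                                config$rw_prior_rate + qc / 2)
      if (it > config$warmup) {
        s <- it - config$warmup
        draws$alpha[s, ch] <- beta[1]
        draws$A[s, , ch] <- beta[iA]
        draws$P[s, , ch] <- beta[iP]
        draws$C[s, , ch] <- beta[iC]
        draws$tau[s, , ch] <- tau
      }
    }
  }

  proj <- project_apc_draws(draws, years = years, mids = mids,
                            cohort_grid = bins$grid)
  diag_par <- cbind(alpha = c(proj$alpha),
                    log_tau_eps = c(log(draws$tau[, "eps", ])))
  rhats <- c(alpha = split_rhat(matrix(proj$alpha, ncol = config$chains)),
             log_tau_eps = split_rhat(matrix(log(draws$tau[, "eps", ]),
                                             ncol = config$chains)),
             A_first = split_rhat(matrix(proj$A[, 1, ], ncol = config$chains)),
             P_last = split_rhat(matrix(proj$P[, J, ], ncol = config$chains)))
  converged <- all(rhats <= config$rhat_max)

  qs <- function(m) {  # draws (n_save*chains) x dim -> summary data frame
    m <- if (length(dim(m)) == 3) apply(m, 2, c) else matrix(c(m), ncol = 1)
    data.frame(mean = colMeans(m),
               lo = apply(m, 2, stats::quantile, 0.025),
               hi = apply(m, 2, stats::quantile, 0.975))
  }
  summary <- list(alpha = qs(proj$alpha),
                  A = cbind(age_band = sch$label, qs(proj$A)),
                  P = cbind(year = years, qs(proj$P)),
                  C = cbind(cohort = bins$grid, qs(proj$C)),
                  sigma = qs(1 / sqrt(draws$tau[, "eps", ])))
  structure(list(
    summary = summary, draws = draws, diagnostics = rhats,
    converged = converged,
    constraints = paste("A, P, C sum to zero; C detrended (zero slope),",
                        "drift assigned to the period effects;",
                        "levels absorbed into alpha"),
    country = unique(df$country), cause = cause, years = years,
    schema = sch, mids = mids, cohort_grid = bins$grid,
    cohort_index = bins$index, config = config, y = y,
    cells = df[c("age_idx", "per_idx", "coh_idx")]),
    class = "apc_posterior")
}

# Identifiability post-processing of raw draws. For each draw:
# 1) fit a line to C over the cohort-bin centers and remove it, adding the
#    slope times the year to P, minus the slope times the band midpoint to
#    A, and the level to alpha (every fitted cell is unchanged up to the
#    cohort binning error);
# 2) center A, P and C, absorbing their means into alpha.
project_apc_draws <- function(draws, years, mids, cohort_grid) {
  nch <- dim(draws$A)[3]; ns <- dim(draws$A)[1]
  A <- draws$A; P <- draws$P; C <- draws$C; alpha <- draws$alpha
  v <- cohort_grid
  vc <- v - mean(v); svv <- sum(vc^2)
  for (ch in seq_len(nch)) {
    Cc <- C[, , ch, drop = FALSE][, , 1]
    c1 <- (Cc %*% vc) / svv               # per-draw slope
    c0 <- rowMeans(Cc) - c1 * mean(v)     # per-draw intercept
    C[, , ch] <- Cc - outer(c(c0), rep(1, length(v))) - outer(c(c1), v)
    P[, , ch] <- P[, , ch, drop = FALSE][, , 1] + outer(c(c1), years)
    A[, , ch] <- A[, , ch, drop = FALSE][, , 1] - outer(c(c1), unname(mids))
    alpha[, ch] <- alpha[, ch] + c0
    mA <- rowMeans(A[, , ch, drop = FALSE][, , 1])
    mP <- rowMeans(P[, , ch, drop = FALSE][, , 1])
    A[, , ch] <- A[, , ch, drop = FALSE][, , 1] - mA
    P[, , ch] <- P[, , ch, drop = FALSE][, , 1] - mP
    alpha[, ch] <- alpha[, ch] + mA + mP
  }
  list(alpha = alpha, A = A, P = P, C = C)
}

#' @export
print.apc_posterior <- function(x, ...) {
  cat(sprintf("Bayesian APC posterior: %s, %s, %d ages x %d periods\n",
              x$country, x$cause, nrow(x$schema), length(x$years)))
  cat(sprintf("  chains: %d, saved draws: %d, converged: %s (max Rhat %.3f)\n",
              x$config$chains, dim(x$draws$A)[1] * x$config$chains,
              x$converged, max(x$diagnostics)))
  cat(sprintf("  constraints: %s\n", x$constraints))
  invisible(x)
}

#' Project mortality rates from a fitted APC posterior
#'
#' Extends, per posterior draw, the period effects (and the cohort effects
#' for newly entered cohorts) forward under their RW2 dynamics —
#' `P_{j+1} = 2 P_j - P_{j-1} + N(0, 1/tau_P)` — so the recent trend
#' continues and uncertainty grows with the horizon. Per-draw cell log
#' rates are exponentiated and summarized: the point projection is the
#' posterior median (robust to the right skew of the log-normal draws at
#' long horizons), the interval the 2.5% and 97.5% quantiles.
#'
#' @param posterior an `apc_posterior` from [fit_apc()]
#' @param horizon number of years beyond the fitted range (>= 1)
#' @param force project even if the sampler did not converge
#' @param seed seed for the forward simulation
#' @return data frame: country, age_band, year, rate, rate_lo, rate_hi
#'   (per 100,000), for the `horizon` projected years
#' @export
project_rates <- function(posterior, horizon, force = FALSE, seed = 1L) {
  stopifnot(inherits(posterior, "apc_posterior"))
  if (horizon < 1) stop("project_rates: horizon must be >= 1")
  if (!posterior$converged && !force)
    stop("project_rates: sampler did not converge (use force = TRUE to override)")
  set.seed(seed)
  d <- posterior$draws
  ns <- dim(d$A)[1]; nch <- dim(d$A)[3]
  I <- dim(d$A)[2]; J <- dim(d$P)[2]; K <- dim(d$C)[2]
  years_new <- max(posterior$years) + seq_len(horizon)
  mids <- posterior$mids
  w <- posterior$config$cohort_bin_width
  # cohort bins needed for future cells
  fut_bins <- cohort_bin_grid(c(posterior$years, years_new), mids, width = w)
  K_all <- length(fut_bins$grid)
  n_new_bins <- K_all - K
  stopifnot(all(fut_bins$grid[seq_len(K)] == posterior$cohort_grid))

  flat <- function(a) apply(a, 2, c)  # (ns*nch) x dim
  alpha <- c(d$alpha); A <- flat(d$A); P <- flat(d$P); C <- flat(d$C)
  tauP <- c(d$tau[, "P", ]); tauC <- c(d$tau[, "C", ])
  M <- length(alpha)
  Pext <- matrix(NA_real_, M, horizon)
  p1 <- P[, J - 1]; p2 <- P[, J]
  for (h in seq_len(horizon)) {
    nxt <- 2 * p2 - p1 + stats::rnorm(M, 0, 1 / sqrt(tauP))
    Pext[, h] <- nxt; p1 <- p2; p2 <- nxt
  }
  Cext <- if (n_new_bins > 0) {
    ce <- matrix(NA_real_, M, n_new_bins)
    c1 <- C[, K - 1]; c2 <- C[, K]
    for (h in seq_len(n_new_bins)) {
      nxt <- 2 * c2 - c1 + stats::rnorm(M, 0, 1 / sqrt(tauC))
      ce[, h] <- nxt; c1 <- c2; c2 <- nxt
    }
    cbind(C, ce)
  } else C

  sch <- posterior$schema
  out <- list()
  for (i in seq_len(I)) {
    for (h in seq_len(horizon)) {
      j_new <- J + h
      kk <- fut_bins$index[i, j_new]
      lr <- alpha + A[, i] + Pext[, h] + Cext[, kk]
      r <- exp(lr)
      out[[length(out) + 1]] <- data.frame(
        country = posterior$country, age_band = sch$label[i],
        year = years_new[h], rate = unname(stats::median(r)),
        rate_lo = unname(stats::quantile(r, 0.025)),
        rate_hi = unname(stats::quantile(r, 0.975)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(match(res$age_band, sch$label), res$year), ]
}

#' In-sample fitted rates with posterior (or predictive) intervals
#'
#' @param posterior an `apc_posterior`
#' @param predictive include the residual noise in the intervals (posterior
#'   predictive; use this when checking coverage of observed rates)
#' @param seed seed for the predictive noise
#' @return data frame: country, age_band, year, rate, rate_lo, rate_hi
#' @export
fitted_rates <- function(posterior, predictive = FALSE, seed = 1L) {
  stopifnot(inherits(posterior, "apc_posterior"))
  set.seed(seed)
  d <- posterior$draws
  flat <- function(a) apply(a, 2, c)
  alpha <- c(d$alpha); A <- flat(d$A); P <- flat(d$P); C <- flat(d$C)
  sig <- 1 / sqrt(c(d$tau[, "eps", ]))
  cells <- posterior$cells
  sch <- posterior$schema
  out <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    lr <- alpha + A[, cells$age_idx[r]] + P[, cells$per_idx[r]] +
      C[, cells$coh_idx[r]]
    if (predictive) lr <- lr + stats::rnorm(length(lr), 0, sig)
    rr <- exp(lr)
    out[[r]] <- data.frame(
      country = posterior$country, age_band = sch$label[cells$age_idx[r]],
      year = posterior$years[cells$per_idx[r]], rate = unname(stats::median(rr)),
      rate_lo = unname(stats::quantile(rr, 0.025)),
      rate_hi = unname(stats::quantile(rr, 0.975)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
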