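# Panel and time-series unit-root machinery: augmented Dickey-Fuller
# regressions with MacKinnon (1994) response-surface p values, the Fisher
# combination, the Levin-Lin-Chu pooled test, the Im-Pesaran-Shin
# mean-group test, and a residual-based panel cointegration check.

# MacKinnon (1994) response-surface coefficients for the Dickey-Fuller t
# distribution, constant-only case, indexed by the number of I(1)
# variables (1 = plain unit-root test, >1 = cointegration residuals).
.mackinnon_c <- list(
  tau_star = c(-1.61, -2.62, -3.13, -3.47, -3.78, -3.93),
  tau_min = c(-18.83, -18.86, -23.48, -28.07, -25.96, -23.27),
  tau_max = c(2.74, 0.92, 0.55, 0.61, 0.79, 1.00),
  small = list(
    c(2.1659, 1.4412, 0.038269),
    c(2.92, 1.5012, 0.039796),
    c(3.4699, 1.4856, 0.03164),
    c(3.9673, 1.4777, 0.026315),
    c(4.5509, 1.5338, 0.029545),
    c(5.1399, 1.6036, 0.034445)
  ),
  large = list(
    c(1.7339, 0.93202, -0.12745, -0.010368),
    c(2.1945, 0.64695, -0.29198, -0.042377),
    c(2.5893, 0.45168, -0.36529, -0.050074),
    c(3.0387, 0.45452, -0.33666, -0.041921),
    c(3.5049, 0.52098, -0.29158, -0.033468),
    c(3.9489, 0.58933, -0.25359, -0.02721)
  )
)

# Constant-plus-trend case (single series only).
.mackinnon_ct <- list(
  tau_star = -2.89, tau_min = -16.18, tau_max = 0.70,
  small = c(3.2512, 1.6047, 0.049588),
  large = c(2.5261, 0.61654, -0.37956, -0.060285)
)

#' @keywords internal
mackinnon_pvalue <- function(tau, trend = "constant", n_vars = 1) {
  if (trend == "constant_trend") {
    tab <- .mackinnon_ct
    star <- tab$tau_star
    lo <- tab$tau_min
    hi <- tab$tau_max
    coefs <- if (tau <= star) tab$small else tab$large
  } else {
    i <- min(n_vars, 6L)
    star <- .mackinnon_c$tau_star[i]
    lo <- .mackinnon_c$tau_min[i]
    hi <- .mackinnon_c$tau_max[i]
    coefs <- if (tau <= star) .mackinnon_c$small[[i]] else
      .mackinnon_c$large[[i]]
  }
  if (tau > hi) {
    return(1)
  }
  if (tau < lo) {
    return(1e-16)
  }
  stats::pnorm(sum(coefs * tau^(seq_along(coefs) - 1)))
}

# Fit one ADF regression at a given lag order; returns the t statistic of
# the lagged level and the residual sum of squares / sample size for AIC.
adf_regression <- function(x, lag, trend) {
  n <- length(x)
  dx <- diff(x)
  y <- dx[(lag + 1):(n - 1)]
  xm <- cbind(level = x[(lag + 1):(n - 1)])
  if (lag > 0) {
    for (j in seq_len(lag)) {
      xm <- cbind(xm, dx[(lag + 1 - j):(n - 1 - j)])
    }
  }
  xm <- cbind(xm, intercept = 1)
  if (trend == "constant_trend") {
    xm <- cbind(xm, trend = seq_len(nrow(xm)))
  }
  fit <- stats::lm.fit(xm, y)
  res <- fit$residuals
  k <- ncol(xm)
  nn <- length(y)
  sigma2 <- sum(res^2) / (nn - k)
  xtx_inv <- chol2inv(chol(crossprod(xm)))
  list(
    tstat = fit$coefficients[1] / sqrt(sigma2 * xtx_inv[1, 1]),
    rho = fit$coefficients[1],
    aic = nn * log(sum(res^2) / nn) + 2 * k,
    residuals = res, sigma2 = sigma2,
    n_used = nn
  )
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Tests the null of a unit root in a single series with the augmented
#' Dickey-Fuller regression. The lag order of the differenced terms is
#' chosen by AIC on a common estimation sample, up to `max_lag`; the
#' p value comes from the MacKinnon (1994) response-surface approximation
#' to the Dickey-Fuller t distribution.
#'
#' @param x Numeric series.
#' @param max_lag Maximum augmentation lag (default
#'   `floor(4 * (n / 100)^0.25)`, capped so the regression keeps degrees
#'   of freedom).
#' @param trend Deterministic component: `"constant"` or
#'   `"constant_trend"`.
#' @return A one-row tibble `statistic, lag, p_value, n`.
#' @export
#' @examples
#' set.seed(1)
#' adf_test(cumsum(rnorm(100)))
adf_test <- function(x, max_lag = NULL,
                     trend = c("constant", "constant_trend")) {
  trend <- match.arg(trend)
  x <- as.numeric(x)
  n <- length(x)
  if (stats::sd(x) == 0) {
    stop("constant series: unit-root test undefined", call. = FALSE)
  }
  if (is.null(max_lag)) {
    max_lag <- max(0L, min(
      floor(4 * (n / 100)^0.25),
      (n - 7L) %/% 2L
    ))
  }
  if (n < max_lag + 4) {
    stop("too short: need length >= max_lag + 4", call. = FALSE)
  }
  # lag selection on the common sample implied by max_lag
  aics <- vapply(0:max_lag, function(p) {
    xx <- x[(max_lag - p + 1):n]
    adf_regression(xx, p, trend)$aic
  }, numeric(1))
  best <- (0:max_lag)[which.min(aics)]
  fit <- adf_regression(x, best, trend)
  tibble::tibble(
    statistic = unname(fit$tstat),
    lag = best,
    p_value = mackinnon_pvalue(fit$tstat, trend),
    n = n
  )
}

#' Fisher combination of independent unit-root p values
#'
#' Combines per-unit test p values with the Fisher statistic
#' `-2 * sum(log(p))`, referred to a chi-square distribution with `2N`
#' degrees of freedom. This is the combination rule behind Fisher-type
#' panel unit-root tests; any per-unit test producing valid p values can
#' feed it.
#'
#' @param p Vector of per-unit p values in `(0, 1]`.
#' @return A one-row tibble `statistic, df, p_value`.
#' @export
#' @examples
#' fisher_unit_root(c(0.5, 0.5))
fisher_unit_root <- function(p) {
  if (length(p) < 1) {
    stop("need at least one p value", call. = FALSE)
  }
  if (any(p <= 0) || any(p > 1)) {
    stop("p values must lie in (0, 1]; floor zero p values at machine ",
      "epsilon upstream",
      call. = FALSE
    )
  }
  stat <- -2 * sum(log(p))
  df <- 2L * length(p)
  tibble::tibble(
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE)
  )
}

# Reshape a long balanced panel into a time-by-unit matrix, erroring if
# any unit-time cell is absent.
panel_matrix <- function(data, value = "value", unit = "region",
                         time = "year") {
  cols <- c(unit, time, value)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop("panel is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  units <- sort(unique(data[[unit]]))
  times <- sort(unique(data[[time]]))
  counts <- table(data[[unit]], data[[time]])
  if (any(counts != 1)) {
    stop("unbalanced panel: every unit must be observed once per period",
      call. = FALSE
    )
  }
  m <- matrix(NA_real_, length(times), length(units),
    dimnames = list(NULL, units)
  )
  idx <- cbind(match(data[[time]], times), match(data[[unit]], units))
  m[idx] <- data[[value]]
  m
}

# Bartlett-kernel long-run variance of a (demeaned) series.
long_run_variance <- function(u, bandwidth = NULL) {
  T_n <- length(u)
  if (is.null(bandwidth)) bandwidth <- floor(3.21 * T_n^(1 / 3))
  u <- u - mean(u)
  g0 <- sum(u^2) / T_n
  s <- g0
  for (l in seq_len(min(bandwidth, T_n - 1))) {
    gl <- sum(u[(l + 1):T_n] * u[1:(T_n - l)]) / T_n
    s <- s + 2 * (1 - l / (bandwidth + 1)) * gl
  }
  s
}

# Mean/variance adjustment factors for the pooled statistic, model with
# intercept, indexed by the effective per-unit sample length T-tilde.
# Simulated (100,000 replicates per cell) for exactly the construction
# used below, in the spirit of the Levin-Lin-Chu tabulation; the values
# approach the theoretical asymptote (-0.5, 0.707) as T-tilde grows.
.llc_adjust <- list(
  T = c(9, 11, 14, 19, 24, 29, 39, 49, 59, 79, 99, 149, 199, 1e6),
  mu = c(
    -0.8203, -0.7919, -0.7178, -0.6779, -0.6544, -0.6263, -0.5998,
    -0.5882, -0.5789, -0.5606, -0.5515, -0.5409, -0.5323, -0.500
  ),
  sigma = c(
    1.3103, 1.1364, 0.9935, 0.9007, 0.8450, 0.8187, 0.7852,
    0.7660, 0.7571, 0.7427, 0.7328, 0.7213, 0.7217, 0.707
  )
)

#' Levin-Lin-Chu pooled panel unit-root test
#'
#' Pooled panel extension of the Dickey-Fuller test assuming a common
#' autoregressive root: each unit's series is prewhitened by its own ADF
#' lag regressions, the components are normalized by the unit regression
#' standard error and by the ratio of long-run to innovation standard
#' deviations, and the pooled t statistic is centered and scaled with the
#' Levin-Lin-Chu mean/variance adjustments, giving an asymptotically
#' standard-normal statistic. Left-tail rejections indicate
#' stationarity.
#'
#' @param data Long data frame with unit, time and value columns.
#' @param value,unit,time Column names (defaults `"value"`, `"region"`,
#'   `"year"`).
#' @param max_lag Common augmentation lag per unit (default 0 for short
#'   panels, AIC up to this order otherwise is not attempted — the lag is
#'   fixed so the pooled statistic stays comparable across units).
#' @return A one-row tibble `statistic, p_value, n_units, n_periods`.
#' @export
llc_test <- function(data, value = "value", unit = "region",
                     time = "year", max_lag = 0L) {
  m <- panel_matrix(data, value, unit, time)
  T_n <- nrow(m)
  N <- ncol(m)
  p <- as.integer(max_lag)
  if (T_n < p + 8) {
    stop("too short: LLC needs at least max_lag + 8 periods",
      call. = FALSE
    )
  }
  t_tilde <- T_n - p - 1
  num <- 0
  den <- 0
  s_ratios <- numeric(N)
  e_all <- list()
  v_all <- list()
  for (i in seq_len(N)) {
    x <- m[, i]
    dx <- diff(x)
    y <- dx[(p + 1):(T_n - 1)]
    lev <- x[(p + 1):(T_n - 1)]
    z <- matrix(1, length(y), 1)
    if (p > 0) {
      for (j in seq_len(p)) {
        z <- cbind(z, dx[(p + 1 - j):(T_n - 1 - j)])
      }
    }
    # partial out the deterministic/lag terms from both sides
    e <- stats::lm.fit(z, y)$residuals
    v <- stats::lm.fit(z, lev)$residuals
    full <- stats::lm.fit(cbind(v, z), y)
    s_i <- sqrt(sum(full$residuals^2) /
      (length(y) - ncol(z) - 1))
    e_all[[i]] <- e / s_i
    v_all[[i]] <- v / s_i
    s_ratios[i] <- sqrt(long_run_variance(dx)) /
      sqrt(sum(full$residuals^2) / length(y))
  }
  e <- unlist(e_all)
  v <- unlist(v_all)
  delta <- sum(e * v) / sum(v^2)
  resid <- e - delta * v
  sigma_tilde2 <- sum(resid^2) / (N * t_tilde)
  se_delta <- sqrt(sigma_tilde2 / sum(v^2))
  t_delta <- delta / se_delta
  s_bar <- mean(s_ratios)
  mu <- stats::approx(.llc_adjust$T, .llc_adjust$mu, xout = t_tilde,
    rule = 2
  )$y
  sig <- stats::approx(.llc_adjust$T, .llc_adjust$sigma, xout = t_tilde,
    rule = 2
  )$y
  t_star <- (t_delta - N * t_tilde * s_bar / sigma_tilde2 *
    se_delta * mu) / sig
  tibble::tibble(
    statistic = t_star,
    p_value = stats::pnorm(t_star),
    n_units = N, n_periods = T_n
  )
}

# Simulated moments of the Dickey-Fuller t statistic (intercept case),
# 200,000 replicates per cell, indexed by augmentation lag p and series
# length T. Used to standardize the Im-Pesaran-Shin mean-group statistic.
.df_t_moments <- list(
  p0 = list(
    T = c(6, 7, 8, 9, 10, 12, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90,
      100, 150, 200, 500),
    mean = c(-1.5644, -1.5194, -1.5072, -1.5118, -1.5097, -1.5082,
      -1.5129, -1.5183, -1.5163, -1.5232, -1.5223, -1.5289, -1.5288,
      -1.5345, -1.5288, -1.5322, -1.5276, -1.5265, -1.5293, -1.5355),
    var = c(2.6515, 1.7230, 1.4055, 1.2416, 1.1424, 1.0212, 0.9355,
      0.8643, 0.8270, 0.8044, 0.7727, 0.7534, 0.7511, 0.7424, 0.7409,
      0.7305, 0.7347, 0.7233, 0.7158, 0.7096)
  ),
  p1 = list(
    T = c(8, 9, 10, 12, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90, 100,
      150, 200, 500),
    mean = c(-1.5560, -1.5151, -1.4947, -1.4916, -1.4982, -1.5078,
      -1.5122, -1.5139, -1.5186, -1.5213, -1.5238, -1.5261, -1.5261,
      -1.5270, -1.5261, -1.5285, -1.5324, -1.5307),
    var = c(3.1449, 1.9700, 1.5760, 1.2500, 1.0707, 0.9403, 0.8804,
      0.8403, 0.8039, 0.7863, 0.7686, 0.7576, 0.7508, 0.7471, 0.7400,
      0.7338, 0.7252, 0.7119)
  )
)

df_t_moments <- function(T_n, lag) {
  tab <- if (lag == 0) .df_t_moments$p0 else .df_t_moments$p1
  list(
    mean = stats::approx(1 / tab$T, tab$mean, xout = 1 / T_n, rule = 2)$y,
    var = stats::approx(1 / tab$T, tab$var, xout = 1 / T_n, rule = 2)$y
  )
}

#' Im-Pesaran-Shin mean-group panel unit-root test
#'
#' Averages individual ADF t statistics (intercept case, fixed
#' augmentation lag) across units and standardizes the mean with
#' simulated finite-sample moments of the Dickey-Fuller t distribution,
#' giving an asymptotically standard-normal statistic. Unlike the pooled
#' Levin-Lin-Chu test, each unit may have its own autoregressive root
#' under the alternative. With a single unit the statistic reduces to the
#' standardized ADF t of that series.
#'
#' @inheritParams llc_test
#' @param max_lag Fixed augmentation lag per unit (0 or 1; the simulated
#'   moment tables cover these orders).
#' @return A one-row tibble
#'   `statistic, p_value, t_bar, n_units, n_periods`.
#' @export
ips_test <- function(data, value = "value", unit = "region",
                     time = "year", max_lag = 0L) {
  m <- panel_matrix(data, value, unit, time)
  T_n <- nrow(m)
  N <- ncol(m)
  p <- as.integer(max_lag)
  if (!p %in% c(0L, 1L)) {
    stop("ips_test: moment tables cover max_lag 0 or 1", call. = FALSE)
  }
  if (T_n - p - 1 < 6) {
    stop("too short: IPS needs at least max_lag + 7 periods",
      call. = FALSE
    )
  }
  tstats <- vapply(seq_len(N), function(i) {
    adf_regression(m[, i], p, "constant")$tstat
  }, numeric(1))
  mom <- df_t_moments(T_n, p)
  t_bar <- mean(tstats)
  w <- sqrt(N) * (t_bar - mom$mean) / sqrt(mom$var)
  tibble::tibble(
    statistic = w,
    p_value = stats::pnorm(w),
    t_bar = t_bar,
    n_units = N, n_periods = T_n
  )
}

#' Residual-based panel cointegration test
#'
#' Tests for a long-run equilibrium relation between a dependent panel
#' series and a set of regressors: the within (unit fixed-effects)
#' regression is estimated by pooled OLS on demeaned data, the residuals
#' are split by unit, each unit's residual series gets an ADF t statistic
#' whose p value uses the MacKinnon response surface for cointegration
#' residuals (accounting for the estimated regression), and the per-unit
#' p values are pooled with the Fisher combination. The null hypothesis
#' is no cointegration.
#'
#' @param data Long data frame containing the unit, time, dependent and
#'   regressor columns.
#' @param y Name of the dependent column.
#' @param x Character vector of regressor column names.
#' @param unit,time Column names (defaults `"region"`, `"year"`).
#' @param max_lag Augmentation lag for the per-unit residual ADF
#'   (default 0).
#' @return A one-row tibble `statistic, df, p_value, n_units`.
#' @export
residual_cointegration <- function(data, y, x, unit = "region",
                                   time = "year", max_lag = 0L) {
  ym <- panel_matrix(data, y, unit, time)
  T_n <- nrow(ym)
  N <- ncol(ym)
  if (T_n < max(6, max_lag + 6)) {
    stop("too short: need at least 6 periods", call. = FALSE)
  }
  xm <- lapply(x, function(v) panel_matrix(data, v, unit, time))
  demean <- function(m) sweep(m, 2, colMeans(m))
  yd <- as.vector(demean(ym))
  xd <- do.call(cbind, lapply(xm, function(m) as.vector(demean(m))))
  if (qr(xd)$rank < ncol(xd)) {
    stop("degenerate regressors in cointegrating regression",
      call. = FALSE
    )
  }
  beta <- stats::lm.fit(xd, yd)$coefficients
  resid <- matrix(yd - xd %*% beta, T_n, N)
  if (all(abs(resid) < 1e-12)) {
    stop("perfect fit: residual cointegration test undefined",
      call. = FALSE
    )
  }
  n_vars <- length(x) + 1
  pvals <- vapply(seq_len(N), function(i) {
    t_i <- adf_regression(resid[, i], as.integer(max_lag),
      "constant"
    )$tstat
    max(mackinnon_pvalue(t_i, "constant", n_vars), 1e-16)
  }, numeric(1))
  out <- fisher_unit_root(pvals)
  out$n_units <- N
  out
}
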