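# Two-way fixed-effects (within) estimation and the model-selection
# battery: poolability F, Breusch-Pagan LM, and a robust regression-based
# Hausman test, with a Swamy-Arora random-effects fit behind the latter.

# Align a balanced panel into sorted vectors/matrices; shared by all
# estimators below.
panel_design <- function(data, dependent, regressors, unit, time) {
  for (v in c(dependent, regressors)) {
    if (!v %in% names(data)) {
      stop("column not found: ", v, call. = FALSE)
    }
    if (!is.numeric(data[[v]])) {
      stop("column is not numeric: ", v, call. = FALSE)
    }
    if (any(!is.finite(data[[v]]))) {
      stop("non-finite values in column: ", v, call. = FALSE)
    }
  }
  units <- sort(unique(data[[unit]]))
  times <- sort(unique(data[[time]]))
  counts <- table(data[[unit]], data[[time]])
  if (any(counts != 1)) {
    stop("unbalanced panel: every unit must be observed once per period",
      call. = FALSE
    )
  }
  ord <- order(match(data[[unit]], units), match(data[[time]], times))
  d <- data[ord, , drop = FALSE]
  list(
    y = d[[dependent]],
    X = as.matrix(d[, regressors, drop = FALSE]),
    unit_f = factor(d[[unit]], levels = units),
    time_f = factor(d[[time]], levels = times),
    units = units, times = times,
    N = length(units), T = length(times)
  )
}

demean_panel <- function(z, unit_f, time_f, effects) {
  z <- as.matrix(z)
  out <- z - apply(z, 2, function(col) ave(col, unit_f))
  if (effects == "twoways") {
    out <- out - apply(z, 2, function(col) ave(col, time_f)) +
      matrix(colMeans(z), nrow(z), ncol(z), byrow = TRUE)
  }
  out
}

cluster_vcov <- function(Xd, resid, cluster_f, bread, df_model) {
  n <- nrow(Xd)
  G <- nlevels(cluster_f)
  meat <- matrix(0, ncol(Xd), ncol(Xd))
  for (g in levels(cluster_f)) {
    i <- cluster_f == g
    s <- crossprod(Xd[i, , drop = FALSE], resid[i])
    meat <- meat + tcrossprod(s)
  }
  adj <- (G / (G - 1)) * ((n - 1) / (n - df_model))
  adj * bread %*% meat %*% bread
}

#' Fit a fixed-effects (within) panel regression
#'
#' Estimates `y_it = a + x_it' b + delta_i + eta_t + e_it` by the within
#' estimator: every variable is demeaned by unit means (and, for two-way
#' effects, by time means with the grand mean added back) and the slopes
#' come from OLS on the demeaned data. The unit effects `delta_i`, time
#' effects `eta_t` and the grand intercept are recovered afterwards from
#' the group means. Standard errors are cluster-robust by unit by
#' default, which guards inference against heteroscedasticity and serial
#' correlation within units.
#'
#' @param data Balanced panel data frame.
#' @param dependent Name of the dependent column (default `"lnD"`).
#' @param regressors Character vector of regressor columns; by default
#'   every numeric column except the dependent, unit and time columns.
#' @param unit,time Column names identifying the panel dimensions
#'   (defaults `"region"`, `"year"`).
#' @param effects `"twoways"` (unit and time effects, the default) or
#'   `"individual"` (unit effects only).
#' @param vcov `"cluster"` (by unit, default) or `"iid"`.
#' @return An object of class `fem_fit`; see [tidy.fem_fit()] and
#'   [glance.fem_fit()] for tidy accessors.
#' @export
fit_fem <- function(data, dependent = "lnD", regressors = NULL,
                    unit = "region", time = "year",
                    effects = c("twoways", "individual"),
                    vcov = c("cluster", "iid")) {
  effects <- match.arg(effects)
  vcov <- match.arg(vcov)
  if (is.null(regressors)) {
    regressors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(dependent, unit, time)
    )
  }
  pd <- panel_design(data, dependent, regressors, unit, time)
  if (pd$N < 2 || pd$T < 2) {
    stop("need at least 2 units and 2 periods", call. = FALSE)
  }
  yd <- demean_panel(pd$y, pd$unit_f, pd$time_f, effects)[, 1]
  Xd <- demean_panel(pd$X, pd$unit_f, pd$time_f, effects)

  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) {
    dropped <- regressors[qr_x$pivot[(qr_x$rank + 1):ncol(Xd)]]
    stop("rank error: regressor(s) collinear after demeaning: ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  beta <- qr.coef(qr_x, yd)
  resid <- yd - Xd %*% beta
  n <- length(yd)
  k <- ncol(Xd)
  absorbed <- if (effects == "twoways") pd$N + pd$T - 1 else pd$N
  df_res <- n - k - absorbed
  sigma2 <- sum(resid^2) / df_res
  bread <- chol2inv(chol(crossprod(Xd)))
  V <- if (vcov == "cluster") {
    cluster_vcov(Xd, resid, pd$unit_f, bread, k + absorbed)
  } else {
    sigma2 * bread
  }
  dimnames(V) <- list(regressors, regressors)
  se <- sqrt(diag(V))
  tval <- beta / se
  df_t <- if (vcov == "cluster") pd$N - 1 else df_res
  pval <- 2 * stats::pt(abs(tval), df_t, lower.tail = FALSE)

  xbar <- colMeans(pd$X)
  ybar <- mean(pd$y)
  intercept <- ybar - sum(xbar * beta)
  unit_means_y <- tapply(pd$y, pd$unit_f, mean)
  unit_means_x <- apply(pd$X, 2, function(c) tapply(c, pd$unit_f, mean))
  delta <- as.vector(unit_means_y) - ybar -
    (unit_means_x - matrix(xbar, pd$N, k, byrow = TRUE)) %*% beta
  eta <- NULL
  if (effects == "twoways") {
    time_means_y <- tapply(pd$y, pd$time_f, mean)
    time_means_x <- apply(pd$X, 2, function(c) tapply(c, pd$time_f, mean))
    eta <- as.vector(time_means_y) - ybar -
      (time_means_x - matrix(xbar, pd$T, k, byrow = TRUE)) %*% beta
    eta <- stats::setNames(as.vector(eta), pd$times)
  }
  ss_y <- sum(yd^2)
  structure(
    list(
      coefficients = stats::setNames(as.vector(beta), regressors),
      std_error = stats::setNames(as.vector(se), regressors),
      t_value = stats::setNames(as.vector(tval), regressors),
      p_value = stats::setNames(as.vector(pval), regressors),
      vcov = V,
      intercept = intercept,
      effects = list(
        unit = stats::setNames(as.vector(delta), pd$units),
        time = eta
      ),
      residuals = as.vector(resid),
      sigma2 = sigma2,
      r_squared = if (ss_y > 0) 1 - sum(resid^2) / ss_y else NA_real_,
      df_residual = df_res,
      nobs = n,
      n_units = pd$N,
      n_periods = pd$T,
      unit_f = pd$unit_f,
      time_f = pd$time_f,
      effects_type = effects,
      vcov_type = vcov,
      dependent = dependent,
      regressors = regressors
    ),
    class = "fem_fit"
  )
}

#' @export
print.fem_fit <- function(x, ...) {
  cat(sprintf(
    "Fixed-effects (%s) panel regression of %s\n%d obs (%d units x %d periods), %s SEs\n\n",
    x$effects_type, x$dependent, x$nobs, x$n_units, x$n_periods,
    x$vcov_type
  ))
  print(as.data.frame(tidy(x)), digits = 4, row.names = FALSE)
  cat(sprintf(
    "\nIntercept %.4f | within R-squared %.4f | sigma %.4f\n",
    x$intercept, x$r_squared, sqrt(x$sigma2)
  ))
  invisible(x)
}

#' Tidy a fixed-effects fit
#'
#' @param x A `fem_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.fem_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_error),
    statistic = unname(x$t_value),
    p.value = unname(x$p_value)
  )
}

#' One-row model summary of a fixed-effects fit
#'
#' @inheritParams tidy.fem_fit
#' @return A one-row tibble with the within R-squared, residual sigma,
#'   sample sizes and residual degrees of freedom.
#' @export
glance.fem_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = sqrt(x$sigma2),
    nobs = x$nobs,
    n_units = x$n_units,
    n_periods = x$n_periods,
    df.residual = x$df_residual
  )
}

# Swamy-Arora one-way random-effects GLS, used by the Hausman and model
# selection machinery.
fit_random_effects <- function(data, dependent, regressors, unit, time) {
  pd <- panel_design(data, dependent, regressors, unit, time)
  yd <- demean_panel(pd$y, pd$unit_f, pd$time_f, "individual")[, 1]
  Xd <- demean_panel(pd$X, pd$unit_f, pd$time_f, "individual")
  k <- ncol(Xd)
  n <- length(yd)
  beta_w <- qr.coef(qr(Xd), yd)
  ssr_w <- sum((yd - Xd %*% beta_w)^2)
  sigma2_e <- ssr_w / (n - pd$N - k)

  # unit-level variance component from the unit means of pooled OLS
  # residuals (works for any N >= 2, unlike a between regression)
  e_pooled <- stats::lm.fit(cbind(1, pd$X), pd$y)$residuals
  ebar <- as.vector(tapply(e_pooled, pd$unit_f, mean))
  s_means2 <- sum(ebar^2) / (pd$N - 1)
  sigma2_u <- max(s_means2 - sigma2_e / pd$T, 0)
  theta <- 1 - sqrt(sigma2_e / (sigma2_e + pd$T * sigma2_u))

  qd <- function(z) {
    z <- as.matrix(z)
    z - theta * apply(z, 2, function(col) ave(col, pd$unit_f))
  }
  ys <- qd(pd$y)[, 1]
  Xs <- cbind(`(Intercept)` = 1 - theta, qd(pd$X))
  fit <- stats::lm.fit(Xs, ys)
  resid <- fit$residuals
  bread <- chol2inv(chol(crossprod(Xs)))
  V_iid <- sum(resid^2) / (n - ncol(Xs)) * bread
  dimnames(V_iid) <- list(colnames(Xs), colnames(Xs))
  list(
    coefficients = stats::setNames(fit$coefficients, colnames(Xs)),
    vcov = V_iid, theta = theta,
    sigma2_e = sigma2_e, sigma2_u = sigma2_u,
    design = pd, quasi = list(y = ys, X = Xs)
  )
}

#' Poolability F test for unit fixed effects
#'
#' Compares the pooled OLS fit (common intercept) against the unit
#' fixed-effects fit; the null is that all unit intercepts are equal, so
#' rejection supports panel-specific effects.
#'
#' @inheritParams fit_fem
#' @return A one-row tibble `statistic, df1, df2, p_value`.
#' @export
poolability_f_test <- function(data, dependent = "lnD",
                               regressors = NULL, unit = "region",
                               time = "year") {
  if (is.null(regressors)) {
    regressors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(dependent, unit, time)
    )
  }
  pd <- panel_design(data, dependent, regressors, unit, time)
  k <- length(regressors)
  Xp <- cbind(1, pd$X)
  ssr_pool <- sum(stats::lm.fit(Xp, pd$y)$residuals^2)
  yd <- demean_panel(pd$y, pd$unit_f, pd$time_f, "individual")[, 1]
  Xd <- demean_panel(pd$X, pd$unit_f, pd$time_f, "individual")
  ssr_fe <- sum((yd - Xd %*% qr.coef(qr(Xd), yd))^2)
  df1 <- pd$N - 1
  df2 <- pd$N * pd$T - pd$N - k
  f <- if (ssr_pool < 1e-12) 0 else {
    ((ssr_pool - ssr_fe) / df1) / (ssr_fe / df2)
  }
  tibble::tibble(
    statistic = f, df1 = df1, df2 = df2,
    p_value = stats::pf(f, df1, df2, lower.tail = FALSE)
  )
}

#' Breusch-Pagan LM test for random effects
#'
#' Tests the null of no unit-level variance component (pooled OLS
#' adequate) against the random-effects alternative, using the pooled
#' OLS residuals.
#'
#' @inheritParams poolability_f_test
#' @return A one-row tibble `statistic, df, p_value`.
#' @export
breusch_pagan_lm <- function(data, dependent = "lnD", regressors = NULL,
                             unit = "region", time = "year") {
  if (is.null(regressors)) {
    regressors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(dependent, unit, time)
    )
  }
  pd <- panel_design(data, dependent, regressors, unit, time)
  e <- stats::lm.fit(cbind(1, pd$X), pd$y)$residuals
  sum_by_unit <- tapply(e, pd$unit_f, sum)
  denom <- sum(e^2)
  lm_stat <- if (denom < 1e-300) 0 else {
    (pd$N * pd$T) / (2 * (pd$T - 1)) *
      (sum(sum_by_unit^2) / denom - 1)^2
  }
  tibble::tibble(
    statistic = lm_stat, df = 1L,
    p_value = stats::pchisq(lm_stat, 1, lower.tail = FALSE)
  )
}

#' Robust (regression-based) Hausman test
#'
#' Tests whether unit effects are correlated with the regressors — the
#' case where random-effects GLS is inconsistent and fixed effects must
#' be used. The classical Hausman contrast can be invalid under
#' heteroscedasticity, so the robust regression-based form is used: the
#' quasi-demeaned (random-effects) regression is augmented with the unit
#' means of the regressors (the Mundlak form) and the added coefficients
#' are tested jointly with a cluster-robust Wald statistic. With fewer
#' units than regressors only an identifiable subset of mean contrasts
#' can be tested; `df` reports how many were. Because the
#' cluster-robust Wald over-rejects badly when the number of
#' restrictions is non-trivial relative to the number of clusters, the
#' p value is computed by a null-imposed wild cluster bootstrap
#' (Rademacher weights, or the six-point Webb distribution when there
#' are fewer than 10 clusters) by default; the asymptotic chi-square
#' p value is available via `method = "asymptotic"`.
#'
#' @inheritParams poolability_f_test
#' @param method `"bootstrap"` (wild cluster bootstrap, default) or
#'   `"asymptotic"` (chi-square reference).
#' @param n_boot Number of bootstrap draws (default 399). Draws come
#'   from the current RNG stream; set a seed for reproducibility.
#' @return A one-row tibble `statistic, df, p_value, method`.
#' @export
hausman_test <- function(data, dependent = "lnD", regressors = NULL,
                         unit = "region", time = "year",
                         method = c("bootstrap", "asymptotic"),
                         n_boot = 399L) {
  method <- match.arg(method)
  if (is.null(regressors)) {
    regressors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(dependent, unit, time)
    )
  }
  re <- fit_random_effects(data, dependent, regressors, unit, time)
  pd <- re$design
  # Mundlak augmentation: unit means of the regressors. The unit-mean
  # columns live in an (N-1)-dimensional space beyond the intercept, so
  # with fewer units than regressors only some contrasts are
  # identifiable; keep a maximal identifiable subset (greedy by rank).
  M <- apply(pd$X, 2, function(c) ave(c, pd$unit_f))
  colnames(M) <- paste0(".mean_", regressors)
  X0 <- re$quasi$X
  keep <- integer(0)
  cur_rank <- qr(X0)$rank
  for (j in seq_len(ncol(M))) {
    cand_rank <- qr(cbind(X0, M[, c(keep, j), drop = FALSE]))$rank
    if (cand_rank > cur_rank) {
      keep <- c(keep, j)
      cur_rank <- cand_rank
    }
  }
  if (length(keep) == 0) {
    stop("non-invertible augmented design; no testable between ",
      "variation (drop near-collinear regressors)",
      call. = FALSE
    )
  }
  Z <- cbind(X0, M[, keep, drop = FALSE])
  qr_z <- qr(Z)
  idx <- seq(ncol(X0) + 1, ncol(Z))
  bread <- chol2inv(chol(crossprod(Z)))
  wald_of <- function(yv) {
    coefs <- qr.coef(qr_z, yv)
    resid <- drop(yv - Z %*% coefs)
    V <- cluster_vcov(Z, resid, pd$unit_f, bread, ncol(Z))
    b <- coefs[idx]
    Vb <- V[idx, idx, drop = FALSE]
    ev <- eigen(Vb, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-12 * max(ev)) {
      stop("non-invertible difference covariance; drop near-collinear ",
        "regressors",
        call. = FALSE
      )
    }
    drop(t(b) %*% solve(Vb, b))
  }
  stat <- wald_of(re$quasi$y)
  k <- length(idx)
  if (method == "asymptotic") {
    p <- stats::pchisq(stat, k, lower.tail = FALSE)
  } else {
    # wild cluster bootstrap with the null (no added regressors) imposed
    X0 <- re$quasi$X
    cf0 <- qr.coef(qr(X0), re$quasi$y)
    fit0 <- drop(X0 %*% cf0)
    r0 <- re$quasi$y - fit0
    G <- pd$N
    gi <- as.integer(pd$unit_f)
    webb <- c(-sqrt(1.5), -1, -sqrt(0.5), sqrt(0.5), 1, sqrt(1.5))
    draws <- vapply(seq_len(n_boot), function(b) {
      s <- if (G < 10) {
        sample(webb, G, replace = TRUE)
      } else {
        sample(c(-1, 1), G, replace = TRUE)
      }
      wald_of(fit0 + s[gi] * r0)
    }, numeric(1))
    p <- (1 + sum(draws >= stat)) / (n_boot + 1)
  }
  tibble::tibble(statistic = stat, df = k, p_value = p, method = method)
}

#' Choose between pooled, random-effects and fixed-effects models
#'
#' Runs the poolability F test, the Breusch-Pagan LM test and the robust
#' Hausman test at the given significance level and applies the standard
#' decision rule: fixed effects when F rejects pooling and Hausman
#' rejects random effects; random effects when LM rejects pooling and
#' Hausman does not; pooled otherwise.
#'
#' @inheritParams poolability_f_test
#' @inheritParams hausman_test
#' @param level Significance level for the decisions (default 0.05).
#' @return A list with the three test tibbles and `chosen`, one of
#'   `"pooled"`, `"random_effects"`, `"fixed_effects"`.
#' @export
select_panel_model <- function(data, dependent = "lnD",
                               regressors = NULL, unit = "region",
                               time = "year", level = 0.05,
                               method = "bootstrap", n_boot = 399L) {
  f <- poolability_f_test(data, dependent, regressors, unit, time)
  lm_t <- breusch_pagan_lm(data, dependent, regressors, unit, time)
  h <- hausman_test(data, dependent, regressors, unit, time,
    method = method, n_boot = n_boot
  )
  chosen <- if (f$p_value < level && h$p_value < level) {
    "fixed_effects"
  } else if (lm_t$p_value < level && h$p_value >= level) {
    "random_effects"
  } else {
    "pooled"
  }
  list(f_test = f, lm_test = lm_t, hausman = h, chosen = chosen)
}
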