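test_that("the within estimator recovers a noise-free model exactly", {
  cfg <- synthetic_config(seed = 7, fem = list(sigma = 0))
  sim <- simulate_fem_panel(cfg)
  fit <- fit_fem(sim$data)
  expect_equal(fit$coefficients, sim$truth$beta, tolerance = 1e-10)
  expect_equal(fit$intercept, sim$truth$intercept, tolerance = 1e-10)
  expect_equal(fit$effects$unit, sim$truth$delta, tolerance = 1e-10)
  expect_equal(fit$effects$time, sim$truth$eta, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("demeaning and the dummy-variable regression agree", {
  cfg <- synthetic_config(seed = 8, n_regions = 6, n_years = 8,
    fem = list(sigma = 0.1)
  )
  d <- simulate_fem_panel(cfg)$data
  fit <- fit_fem(d)
  lsdv <- stats::lm(
    lnD ~ . - region - year + factor(region) + factor(year),
    data = d
  )
  expect_equal(
    fit$coefficients,
    coef(lsdv)[names(fit$coefficients)],
    tolerance = 1e-8
  )
  # one-way variant against one-way dummies
  fit1 <- fit_fem(d, effects = "individual")
  lsdv1 <- stats::lm(lnD ~ . - region - year + factor(region), data = d)
  expect_equal(
    fit1$coefficients,
    coef(lsdv1)[names(fit1$coefficients)],
    tolerance = 1e-8
  )
})

test_that("within residuals are centered within units and periods and orthogonal to regressors", {
  cfg <- synthetic_config(seed = 9, n_regions = 8, n_years = 12,
    fem = list(sigma = 0.2)
  )
  d <- dplyr::arrange(simulate_fem_panel(cfg)$data, region, year)
  fit <- fit_fem(d)
  expect_lt(max(abs(tapply(fit$residuals, fit$unit_f, sum))), 1e-8)
  expect_lt(max(abs(tapply(fit$residuals, fit$time_f, sum))), 1e-8)
  Xd <- ccdm:::demean_panel(
    as.matrix(d[, names(fit$coefficients)]),
    fit$unit_f, fit$time_f, "twoways"
  )
  expect_lt(max(abs(crossprod(Xd, fit$residuals))), 1e-8)
})

test_that("collinear-after-demeaning regressors raise a rank error naming them", {
  cfg <- synthetic_config(seed = 10, fem = list(sigma = 0.1))
  d <- simulate_fem_panel(cfg)$data
  d$year_shock <- as.numeric(d$year %% 3) # constant within each year
  expect_error(fit_fem(d), "rank error.*year_shock")
})

test_that("tidy and glance expose the fit in broom shape", {
  cfg <- synthetic_config(seed = 12, n_regions = 10, n_years = 8,
    fem = list(sigma = 0.1)
  )
  fit <- fit_fem(simulate_fem_panel(cfg)$data)
  td <- tidy(fit)
  expect_named(
    td,
    c("term", "estimate", "std.error", "statistic", "p.value")
  )
  expect_equal(nrow(td), 6)
  expect_equal(td$statistic, td$estimate / td$std.error)
  expect_true(all(td$p.value >= 0 & td$p.value <= 1))
  gl <- glance(fit)
  expect_equal(gl$nobs, 80)
  expect_equal(gl$n_units, 10)
  expect_true(gl$r.squared > 0 && gl$r.squared <= 1)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "Fixed-effects")
})

test_that("poolability F is zero without effects or noise and rejects strong effects", {
  cfg0 <- synthetic_config(seed = 14, n_regions = 6, n_years = 8,
    fem = list(sigma = 0, delta_sd = 0, eta_sd = 0)
  )
  d0 <- simulate_fem_panel(cfg0)$data
  expect_equal(poolability_f_test(d0)$statistic, 0)

  cfg1 <- synthetic_config(seed = 15, n_regions = 6, n_years = 8,
    fem = list(sigma = 0.05, delta_sd = 1, eta_sd = 0)
  )
  d1 <- simulate_fem_panel(cfg1)$data
  expect_lt(poolability_f_test(d1)$p_value, 1e-6)
})

test_that("Breusch-Pagan LM flags a unit variance component", {
  cfg1 <- synthetic_config(seed = 16, n_regions = 12, n_years = 8,
    fem = list(sigma = 0.1, delta_sd = 0.5, eta_sd = 0)
  )
  expect_lt(breusch_pagan_lm(simulate_fem_panel(cfg1)$data)$p_value, 1e-4)
})

test_that("the robust Hausman test distinguishes exogenous from correlated effects", {
  set.seed(101)
  cfg_re <- synthetic_config(seed = 200, n_regions = 30, n_years = 10,
    fem = list(sigma = 0.1, delta_sd = 0.3, eta_sd = 0)
  )
  h_re <- hausman_test(simulate_fem_panel(cfg_re)$data, n_boot = 199)
  expect_gt(h_re$p_value, 0.05)
  expect_equal(h_re$df, 6L)

  cfg_fe <- synthetic_config(seed = 201, n_regions = 30, n_years = 10,
    fem = list(
      sigma = 0.1, delta_sd = 0.3, eta_sd = 0,
      correlated_effects = TRUE
    )
  )
  d_fe <- simulate_fem_panel(cfg_fe)$data
  h_fe <- hausman_test(d_fe, n_boot = 199)
  expect_lt(h_fe$p_value, 0.05)
  h_asy <- hausman_test(d_fe, method = "asymptotic")
  expect_lt(h_asy$p_value, 0.05)

  sel <- select_panel_model(d_fe, n_boot = 199)
  expect_equal(sel$chosen, "fixed_effects")
})

test_that("the regression panel builder logs, aligns and validates inputs", {
  rec <- tibble::tibble(
    region = rep(c("a", "b", "c", "d", "e"), each = 10),
    year = rep(2011:2020, 5),
    D = seq(0.3, 0.9, length.out = 50)
  )
  drv <- tidyr::expand_grid(region = c("a", "b", "c", "d", "e"), year = 2011:2020)
  set.seed(30)
  for (v in driver_variables()) drv[[v]] <- runif(50, 1, 100)
  rp <- build_regression_panel(rec, drv)
  expect_equal(dim(rp), c(50, 2 + 7))
  expect_equal(rp$lnD, log(rec$D))
  expect_equal(sum(vapply(rp, is.numeric, logical(1))), 8)

  one <- build_regression_panel(rec[1, ] |> dplyr::mutate(D = 1), drv)
  expect_equal(one$lnD, 0)

  drv_bad <- drv
  drv_bad$gdp_per_capita[3] <- 0
  expect_error(build_regression_panel(rec, drv_bad), "non-positive value")

  expect_error(
    build_regression_panel(rec, drv[drv$region != "c", ]),
    "alignment error.*c"
  )
})

test_that("the diagnostic battery runs at provincial panel scale and flags small samples", {
  sim <- simulate_fem_panel(synthetic_config(seed = 11))
  set.seed(77)
  diag <- panel_diagnostics(sim$data)
  expect_s3_class(diag, "panel_diagnostics")
  expect_true(diag$small_sample)
  expect_equal(nrow(diag$stationarity), 7 * 3 * 2)
  expect_true(all(diag$stationarity$p_value >= 0 &
    diag$stationarity$p_value <= 1))
  expect_true(diag$chosen_model %in%
    c("pooled", "random_effects", "fixed_effects"))
  lst <- diagnostics_as_list(diag)
  expect_true(jsonlite::validate(jsonlite::toJSON(lst, auto_unbox = TRUE)))
  expect_output(print(diag), "small panel")
})
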