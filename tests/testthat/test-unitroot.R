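test_that("ADF statistics and p values match an independent reference implementation", {
  # reference values computed once with an established Python
  # implementation (statsmodels.tsa.stattools.adfuller) on the same
  # deterministic series, fixed lag, and frozen here
  set.seed(20260921)
  x <- cumsum(rnorm(120))
  r0 <- adf_test(x, max_lag = 0)
  expect_equal(r0$statistic, -1.1052733880, tolerance = 1e-8)
  expect_equal(r0$p_value, 0.7129643637, tolerance = 1e-6)

  r2 <- ccdm:::adf_regression(x, 2, "constant")
  expect_equal(unname(r2$tstat), -1.0831840840, tolerance = 1e-8)

  rt <- ccdm:::adf_regression(x, 2, "constant_trend")
  expect_equal(unname(rt$tstat), -1.5926925043, tolerance = 1e-8)
  expect_equal(
    ccdm:::mackinnon_pvalue(rt$tstat, "constant_trend"),
    0.7952808830,
    tolerance = 1e-6
  )

  set.seed(8)
  y <- as.numeric(arima.sim(list(ar = 0.5), 80))
  r1 <- ccdm:::adf_regression(y, 1, "constant")
  expect_equal(unname(r1$tstat), -6.2325615302, tolerance = 1e-8)
  expect_equal(
    ccdm:::mackinnon_pvalue(r1$tstat, "constant"),
    0.0000000491,
    tolerance = 1e-7
  )
})

test_that("ADF rejects degenerate inputs", {
  expect_error(adf_test(rep(3, 50)), "constant series")
  expect_error(adf_test(rnorm(6), max_lag = 4), "too short")
})

test_that("the Fisher combination follows the chi-square tail exactly", {
  f <- fisher_unit_root(c(0.5, 0.5))
  expect_equal(f$statistic, 2.772589, tolerance = 1e-6)
  expect_equal(f$df, 4L)
  expect_equal(f$p_value, 0.5965736, tolerance = 1e-6)

  f1 <- fisher_unit_root(0.05)
  expect_equal(f1$statistic, 5.991465, tolerance = 1e-6)
  expect_equal(f1$df, 2L)
  expect_equal(f1$p_value, 0.05, tolerance = 1e-10)

  fa <- fisher_unit_root(rep(1, 4))
  expect_equal(fa$statistic, 0)
  expect_equal(fa$p_value, 1)

  expect_error(fisher_unit_root(c(0.5, 0)), "machine")
  expect_error(fisher_unit_root(1.2), "machine")
  expect_error(fisher_unit_root(numeric(0)), "at least one")
})

test_that("the Fisher statistic is additive over independent blocks with df = 2N", {
  set.seed(4)
  p1 <- runif(5)
  p2 <- runif(7)
  a <- fisher_unit_root(p1)
  b <- fisher_unit_root(p2)
  ab <- fisher_unit_root(c(p1, p2))
  expect_equal(ab$statistic, a$statistic + b$statistic, tolerance = 1e-12)
  expect_equal(ab$df, 2L * (5L + 7L))
})

test_that("panel unit-root tests reject unbalanced panels and short series", {
  set.seed(2)
  p <- rw_panel(4, 30)
  expect_error(llc_test(p[-5, ]), "unbalanced")
  expect_error(ips_test(p[-5, ]), "unbalanced")
  expect_error(llc_test(rw_panel(3, 6)), "too short")
  expect_error(ips_test(rw_panel(3, 5)), "too short")
  expect_error(ips_test(p, max_lag = 3), "moment tables")
})

test_that("with one unit IPS reduces to the standardized single-series ADF t", {
  set.seed(6)
  p <- rw_panel(1, 40)
  r <- ips_test(p, max_lag = 0)
  t_single <- ccdm:::adf_regression(p$value, 0, "constant")$tstat
  mom <- ccdm:::df_t_moments(40, 0)
  expect_equal(r$statistic, unname((t_single - mom$mean) / sqrt(mom$var)),
    tolerance = 1e-12
  )
  expect_equal(r$t_bar, unname(t_single))
})

test_that("panel tests separate unit roots from stationarity on single draws", {
  set.seed(31)
  walk <- rw_panel(10, 50)
  noise <- rw_panel(10, 50, random_walk = FALSE)
  expect_gt(llc_test(walk)$p_value, 0.05)
  expect_lt(llc_test(noise)$p_value, 1e-4)
  expect_gt(ips_test(walk)$p_value, 0.05)
  expect_lt(ips_test(noise)$p_value, 1e-4)
})

test_that("residual cointegration detects a shared stochastic trend", {
  mk <- function(N, T, coint) {
    do.call(rbind, lapply(seq_len(N), function(i) {
      x <- cumsum(rnorm(T))
      data.frame(
        region = sprintf("r%02d", i), year = seq_len(T),
        y = if (coint) 2 * x + rnorm(T, 0, 0.5) else cumsum(rnorm(T)),
        x = x
      )
    }))
  }
  set.seed(17)
  strong <- mk(5, 50, coint = TRUE)
  expect_lt(residual_cointegration(strong, "y", "x")$p_value, 0.01)

  set.seed(18)
  indep <- mk(5, 50, coint = FALSE)
  expect_gt(residual_cointegration(indep, "y", "x")$p_value, 0.05)

  short <- mk(3, 4, coint = TRUE)
  expect_error(residual_cointegration(short, "y", "x"), "too short")

  perfect <- mk(3, 20, coint = TRUE)
  perfect$y <- perfect$x
  expect_error(residual_cointegration(perfect, "y", "x"), "perfect fit")
})
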