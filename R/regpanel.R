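# Assembling the log-log regression panel and its diagnostic battery.

#' Default driver-variable column names
#'
#' The six drivers of coordinated development used in the log-log
#' regression: per-capita GDP, secondary-plus-tertiary industry share of
#' GDP, science-and-technology share of fiscal expenditure, per-capita
#' health expenditure, physicians-plus-nurses share of health
#' technicians, and sickbeds per 1,000 residents.
#'
#' @return Character vector of the six column names.
#' @export
driver_variables <- function() {
  c(
    "gdp_per_capita", "industry_share", "tech_fiscal_share",
    "health_exp_per_capita", "physician_nurse_share", "beds_per_1000"
  )
}

#' Build the log-log regression panel
#'
#' Joins coordination records (region, year, `D`) with a wide table of
#' driver variables and takes natural logs of the coupling coordination
#' degree and every driver, producing the estimation panel for
#' [fit_fem()].
#'
#' @param records Coordination records with columns `region`, `year`,
#'   `D` (e.g. from [run_coordination()]).
#' @param drivers Wide data frame with columns `region`, `year` and one
#'   column per driver variable.
#' @param driver_cols Driver column names (default: every numeric column
#'   of `drivers` other than `year`).
#' @return A tibble `region, year, lnD, ln_<driver>...`.
#' @export
build_regression_panel <- function(records, drivers,
                                   driver_cols = NULL) {
  if (is.null(driver_cols)) {
    driver_cols <- setdiff(
      names(drivers)[vapply(drivers, is.numeric, logical(1))],
      c("year")
    )
  }
  missing_cols <- setdiff(driver_cols, names(drivers))
  if (length(missing_cols) > 0) {
    stop("drivers are missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  recs <- dplyr::select(records, "region", "year", "D")
  joined <- dplyr::inner_join(recs, drivers[c("region", "year", driver_cols)],
    by = c("region", "year")
  )
  if (nrow(joined) < nrow(recs)) {
    lost <- dplyr::anti_join(recs, joined, by = c("region", "year"))
    stop("alignment error: drivers missing (", lost$region[1], ", ",
      lost$year[1], ")",
      call. = FALSE
    )
  }
  for (v in c("D", driver_cols)) {
    bad <- which(joined[[v]] <= 0)
    if (length(bad) > 0) {
      stop("non-positive value for '", v, "' at (",
        joined$region[bad[1]], ", ", joined$year[bad[1]],
        "); logs require strictly positive inputs",
        call. = FALSE
      )
    }
  }
  out <- tibble::tibble(
    region = joined$region,
    year = joined$year,
    lnD = log(joined$D)
  )
  for (v in driver_cols) {
    out[[paste0("ln_", v)]] <- log(joined[[v]])
  }
  out
}

first_difference_panel <- function(data, vars, unit, time) {
  data |>
    dplyr::arrange(.data[[unit]], .data[[time]]) |>
    dplyr::group_by(.data[[unit]]) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vars), ~ .x - dplyr::lag(.x))) |>
    dplyr::ungroup() |>
    tidyr::drop_na(dplyr::all_of(vars))
}

fisher_adf_panel <- function(data, value, unit, time, max_lag) {
  m <- panel_matrix(data, value, unit, time)
  pvals <- apply(m, 2, function(x) {
    max(adf_test(x, max_lag = max_lag)$p_value, 1e-16)
  })
  fisher_unit_root(pvals)
}

#' Diagnostic battery for the panel regression
#'
#' Runs, for the dependent variable and every regressor, the
#' Levin-Lin-Chu, Im-Pesaran-Shin and Fisher-combined ADF panel
#' unit-root tests at level and first difference; a residual-based panel
#' cointegration test of the regression relation; and the model-selection
#' trio (poolability F, Breusch-Pagan LM, robust Hausman) with the
#' resulting model choice. At the typical scale of provincial panels
#' (a handful of units, around ten periods) the asymptotic p values are
#' coarse, so a `small_sample` flag is raised whenever the panel has
#' fewer than 10 units or 15 periods.
#'
#' @inheritParams fit_fem
#' @param max_lag Augmentation lag for the unit-root machinery
#'   (default 1, appropriate for short panels).
#' @param level Significance level for model selection (default 0.05).
#' @return An object of class `panel_diagnostics`: a list with elements
#'   `stationarity` (tibble of tests by variable and differencing),
#'   `cointegration`, `model_selection`, `chosen_model` and
#'   `small_sample`.
#' @export
panel_diagnostics <- function(data, dependent = "lnD",
                              regressors = NULL, unit = "region",
                              time = "year", max_lag = 1L,
                              level = 0.05) {
  if (is.null(regressors)) {
    regressors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(dependent, unit, time)
    )
  }
  vars <- c(dependent, regressors)
  n_periods <- dplyr::n_distinct(data[[time]])
  n_units <- dplyr::n_distinct(data[[unit]])
  small <- n_units < 10 || n_periods < 15
  diff_data <- first_difference_panel(data, vars, unit, time)

  one_var <- function(d, v, differenced) {
    lag_use <- min(max_lag, 1L)
    res <- list(
      llc = llc_test(d, v, unit, time, max_lag = 0L),
      ips = ips_test(d, v, unit, time, max_lag = lag_use),
      fisher_adf = fisher_adf_panel(d, v, unit, time, max_lag = lag_use)
    )
    tibble::tibble(
      variable = v,
      differenced = differenced,
      test = c("LLC", "IPS", "Fisher-ADF"),
      statistic = c(
        res$llc$statistic, res$ips$statistic,
        res$fisher_adf$statistic
      ),
      p_value = c(
        res$llc$p_value, res$ips$p_value,
        res$fisher_adf$p_value
      )
    )
  }
  stationarity <- dplyr::bind_rows(
    purrr::map(vars, ~ one_var(data, .x, FALSE)),
    purrr::map(vars, ~ one_var(diff_data, .x, TRUE))
  )
  stationarity$stationary <- stationarity$p_value < level

  coint <- residual_cointegration(data, dependent, regressors,
    unit, time,
    max_lag = 0L
  )
  sel <- select_panel_model(data, dependent, regressors, unit, time,
    level = level
  )
  structure(
    list(
      stationarity = stationarity,
      cointegration = coint,
      model_selection = sel[c("f_test", "lm_test", "hausman")],
      chosen_model = sel$chosen,
      small_sample = small,
      n_units = n_units,
      n_periods = n_periods
    ),
    class = "panel_diagnostics"
  )
}

#' @export
print.panel_diagnostics <- function(x, ...) {
  cat("Panel regression diagnostics (", x$n_units, " units x ",
    x$n_periods, " periods)\n",
    sep = ""
  )
  if (x$small_sample) {
    cat("Note: small panel; asymptotic p values are approximate.\n")
  }
  cat("\nStationarity (p values):\n")
  wide <- tidyr::pivot_wider(
    x$stationarity[c("variable", "differenced", "test", "p_value")],
    names_from = "test", values_from = "p_value"
  )
  print(as.data.frame(wide), digits = 3, row.names = FALSE)
  cat(sprintf(
    "\nCointegration (Fisher): stat %.3f, p %.4g\n",
    x$cointegration$statistic, x$cointegration$p_value
  ))
  ms <- x$model_selection
  cat(sprintf(
    "F test p %.4g | LM test p %.4g | Hausman p %.4g -> %s\n",
    ms$f_test$p_value, ms$lm_test$p_value, ms$hausman$p_value,
    x$chosen_model
  ))
  invisible(x)
}

#' Serialize diagnostics to a JSON-ready list
#'
#' @param x A `panel_diagnostics` object.
#' @return A plain list mirroring the object, suitable for
#'   [jsonlite::write_json()].
#' @export
diagnostics_as_list <- function(x) {
  stopifnot(inherits(x, "panel_diagnostics"))
  list(
    stationarity = as.data.frame(x$stationarity),
    cointegration = as.list(x$cointegration),
    f_test = as.list(x$model_selection$f_test),
    lm_test = as.list(x$model_selection$lm_test),
    hausman_test = as.list(x$model_selection$hausman),
    chosen_model = x$chosen_model,
    small_sample = x$small_sample,
    n_units = x$n_units,
    n_periods = x$n_periods
  )
}
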