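#' Relative development degree
#'
#' The relative development degree `S = U_h / U_e` compares the health
#' resource allocation level with the economic development level.
#' Following the conventional thresholds, `S <= 0.8` means health
#' resource allocation lags behind the economy (`health_lagging`),
#' `0.8 < S < 1.2` means the two subsystems are in dynamic equilibrium,
#' and `S >= 1.2` means economic development is the lagging side
#' (`economy_lagging`).
#'
#' @param u_h,u_e Comprehensive evaluation indices of the health and
#'   economy subsystems (non-negative; `u_e` strictly positive).
#' @return A tibble with columns `S` and `category` (factor with levels
#'   `health_lagging`, `dynamic_equilibrium`, `economy_lagging`).
#' @export
#' @examples
#' relative_development(0.0754, 0.1974)
relative_development <- function(u_h, u_e) {
  if (any(u_h < 0) || any(u_e < 0)) {
    stop("domain error: indices must be non-negative", call. = FALSE)
  }
  if (any(u_e == 0)) {
    stop("undefined ratio: U_e is zero", call. = FALSE)
  }
  s <- u_h / u_e
  category <- factor(
    dplyr::case_when(
      s <= 0.8 ~ "health_lagging",
      s >= 1.2 ~ "economy_lagging",
      .default = "dynamic_equilibrium"
    ),
    levels = c("health_lagging", "dynamic_equilibrium", "economy_lagging")
  )
  tibble::tibble(S = s, category = category)
}

#' Coupling degree of two subsystems
#'
#' `C = 2 * sqrt(U_h * U_e) / (U_h + U_e)` measures how balanced the two
#' subsystem levels are: it is symmetric, scale-invariant, lies in
#' \[0, 1\], and equals 1 exactly when the two levels are equal and
#' positive.
#'
#' @inheritParams relative_development
#' @return Numeric vector of coupling degrees in \[0, 1\].
#' @export
coupling_degree <- function(u_h, u_e) {
  if (any(u_h < 0) || any(u_e < 0)) {
    stop("domain error: indices must be non-negative", call. = FALSE)
  }
  if (any(u_h + u_e == 0)) {
    stop("undefined coupling: both indices are zero", call. = FALSE)
  }
  2 * sqrt(u_h * u_e) / (u_h + u_e)
}

#' Coordination index of two subsystems
#'
#' `T = alpha * U_h + beta * U_e` is the weighted overall development
#' level of the pair. The contribution coefficients must be non-negative
#' and sum to one; the default `alpha = beta = 0.5` treats the two
#' subsystems as equally important.
#'
#' @inheritParams relative_development
#' @param alpha,beta Contribution coefficients (non-negative, summing
#'   to 1).
#' @return Numeric vector of coordination indices.
#' @export
coordination_index <- function(u_h, u_e, alpha = 0.5, beta = 0.5) {
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-12) {
    stop("configuration error: alpha and beta must be non-negative and ",
      "sum to 1",
      call. = FALSE
    )
  }
  alpha * u_h + beta * u_e
}

#' Coupling coordination degree
#'
#' `D = sqrt(C * T)` combines balance (coupling degree `C`) and overall
#' level (coordination index `T`) into a single degree in \[0, 1\]; the
#' closer `D` is to 1 the better the coordinated development. With
#' `alpha = beta = 0.5`, `D` reduces analytically to
#' `(U_h * U_e)^(1/4)`.
#'
#' @param c_value Coupling degree in \[0, 1\].
#' @param t_value Coordination index (non-negative).
#' @return Numeric vector of coupling coordination degrees.
#' @export
coupling_coordination <- function(c_value, t_value) {
  if (any(c_value < 0) || any(c_value > 1) || any(t_value < 0)) {
    stop("domain error: need C in [0, 1] and T >= 0", call. = FALSE)
  }
  sqrt(c_value * t_value)
}

#' Ten-grade classification scheme for the coupling coordination degree
#'
#' The default scheme partitions \[0, 1\] into ten width-0.1 bins grouped
#' into three stages: low-level coordination (antagonistic period, grades
#' I-IV from extreme to mild disorder), medium-level coordination
#' (breaking-in period, grades V-VI), and high-level coordination
#' (coordination period, grades VII-X from primary to high-quality
#' coordination).
#'
#' @return A tibble with columns `lower`, `upper`, `stage`, `type`,
#'   `grade`; bins are half-open `[lower, upper)` and `D = 1` belongs to
#'   the top bin.
#' @export
grade_scheme <- function() {
  tibble::tibble(
    lower = seq(0, 0.9, by = 0.1),
    upper = seq(0.1, 1, by = 0.1),
    stage = c(
      rep("low-level coordination", 4),
      rep("medium-level coordination", 2),
      rep("high-level coordination", 4)
    ),
    type = c(
      "extreme disorder", "severe disorder", "moderate disorder",
      "mild disorder", "endangered disorder", "some coordination",
      "primary coordination", "moderate coordination",
      "good coordination", "high-quality coordination"
    ),
    grade = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")
  )
}

#' Classify a coupling coordination degree
#'
#' Assigns each `D` value to the half-open bin `[lower, upper)` of the
#' scheme containing it; `D = 1` maps to the top bin.
#'
#' @param d Coupling coordination degrees in \[0, 1\].
#' @param scheme A grade scheme tibble (default [grade_scheme()]).
#' @return A tibble with columns `stage`, `type`, `grade`.
#' @export
#' @examples
#' classify_grade(c(0.3499, 0.9001))
classify_grade <- function(d, scheme = grade_scheme()) {
  if (any(d < 0) || any(d > 1)) {
    stop("domain error: D must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(scheme$lower) <= 0) ||
    !isTRUE(all.equal(scheme$lower[-1], scheme$upper[-nrow(scheme)]))) {
    stop("invalid grade scheme: bins must be increasing and contiguous",
      call. = FALSE
    )
  }
  idx <- findInterval(d, scheme$lower, rightmost.closed = FALSE)
  idx[d >= scheme$upper[nrow(scheme)]] <- nrow(scheme)
  tibble::tibble(
    stage = scheme$stage[idx],
    type = scheme$type[idx],
    grade = scheme$grade[idx]
  )
}

#' Recover subsystem indices from their difference and ratio
#'
#' Published comparative tables often report only the index gap
#' `U_h - U_e` and the relative development degree `S = U_h / U_e`.
#' Given those two numbers the underlying indices are recovered
#' algebraically: `U_e = gap / (S - 1)` and `U_h = S * U_e`. This is the
#' standard way to cross-check printed coupling coordination degrees
#' against such tables.
#'
#' @param gap Difference `U_h - U_e`.
#' @param ratio Relative development degree `S` (must differ from 1).
#' @return A tibble with columns `U_h`, `U_e` and a logical
#'   `out_of_range` flag set when a recovered index falls outside
#'   \[0, 1.5\] (a sign of heavily rounded inputs); a warning is raised
#'   in that case.
#' @export
#' @examples
#' recover_indices(-0.122, 0.382)
recover_indices <- function(gap, ratio) {
  if (any(ratio == 1)) {
    stop("non-invertible: S = 1 leaves the indices undetermined",
      call. = FALSE
    )
  }
  u_e <- gap / (ratio - 1)
  u_h <- ratio * u_e
  flag <- u_h < 0 | u_h > 1.5 | u_e < 0 | u_e > 1.5
  if (any(flag)) {
    warning("recovered index outside [0, 1.5]; inputs may be too ",
      "coarsely rounded",
      call. = FALSE
    )
  }
  tibble::tibble(U_h = u_h, U_e = u_e, out_of_range = flag)
}

#' Run the full coupling coordination pipeline on an indicator panel
#'
#' Standardizes the panel, computes entropy weights per subsystem,
#' aggregates the comprehensive evaluation indices `U_h` and `U_e`, and
#' derives the relative development degree, coupling degree, coordination
#' index, coupling coordination degree and grade labels for every
#' region-year.
#'
#' @inheritParams validate_panel
#' @inheritParams coordination_index
#' @param epsilon Positivity shift for standardization (default `1e-4`).
#' @param scheme Grade scheme (default [grade_scheme()]).
#' @param weights Optional externally supplied weight tibble
#'   (`system, indicator, weight`); by default entropy weights are
#'   computed from the panel.
#' @return A tibble with one row per region-year and columns `region`,
#'   `year`, `U_h`, `U_e`, `S`, `S_category`, `C`, `T`, `D`, `stage`,
#'   `type`, `grade`. The weight tibble and the configuration used are
#'   attached as attributes `"weights"` and `"config"`.
#' @export
run_coordination <- function(panel, schema = indicator_schema(),
                             epsilon = 1e-4, alpha = 0.5, beta = 0.5,
                             scheme = grade_scheme(), weights = NULL) {
  schema <- validate_schema(schema)
  normalized <- normalize_indicators(panel, schema, epsilon)
  if (is.null(weights)) {
    weights <- entropy_weights(normalized, schema)
  }
  idx <- composite_index(normalized, weights, schema)
  wide <- tidyr::pivot_wider(idx,
    names_from = "system", values_from = "index"
  )
  rd <- relative_development(wide$health, wide$economy)
  out <- tibble::tibble(
    region = wide$region,
    year = wide$year,
    U_h = wide$health,
    U_e = wide$economy,
    S = rd$S,
    S_category = as.character(rd$category),
    C = coupling_degree(wide$health, wide$economy),
    T = coordination_index(wide$health, wide$economy, alpha, beta)
  )
  out$D <- coupling_coordination(out$C, out$T)
  out <- dplyr::bind_cols(out, classify_grade(pmin(out$D, 1), scheme))
  out <- dplyr::arrange(out, .data$region, .data$year)
  attr(out, "weights") <- weights
  attr(out, "config") <- list(epsilon = epsilon, alpha = alpha, beta = beta)
  out
}
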