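#' Min-max standardization with direction handling
#'
#' Standardizes every indicator to \[0, 1\] by pooled min-max scaling over
#' all region-years, so that composite indices are comparable across
#' years. Positive-direction indicators map `x -> (x - min) / (max - min)`;
#' negative-direction indicators (cost-type, e.g. CPI) are reversed,
#' `x -> (max - x) / (max - min)`. A small positive shift `epsilon` is
#' then added to every value so that the entropy weights' `log` terms are
#' defined at the sample extremes.
#'
#' @inheritParams validate_panel
#' @param epsilon Positive shift applied after scaling (default `1e-4`).
#' @return A tibble `region, year, indicator, value` with standardized
#'   values in `(0, 1 + epsilon]`.
#' @export
normalize_indicators <- function(panel, schema = indicator_schema(),
                                 epsilon = 1e-4) {
  schema <- validate_schema(schema)
  panel <- validate_panel(panel, schema)
  stopifnot(is.numeric(epsilon), epsilon > 0)
  dir <- stats::setNames(schema$direction, schema$id)

  out <- panel |>
    dplyr::group_by(.data$indicator) |>
    dplyr::mutate(
      .min = min(.data$value),
      .max = max(.data$value)
    ) |>
    dplyr::ungroup()
  degenerate <- unique(out$indicator[out$.max == out$.min])
  if (length(degenerate) > 0) {
    stop("degenerate indicator (constant over the panel): ",
      paste(degenerate, collapse = ", "),
      call. = FALSE
    )
  }
  out$value <- unname(ifelse(dir[out$indicator] > 0,
    (out$value - out$.min) / (out$.max - out$.min),
    (out$.max - out$value) / (out$.max - out$.min)
  ) + epsilon)
  dplyr::select(out, -".min", -".max")
}

#' Entropy weights for one or both subsystems
#'
#' Computes objective indicator weights by the entropy method: indicators
#' whose standardized values are more dispersed across region-years carry
#' more information and receive larger weights. For indicator `j` with
#' standardized values `x_ij` over the `n` region-year observations,
#' `p_ij = x_ij / sum_i(x_ij)`, the normalized Shannon entropy is
#' `e_j = -sum_i(p_ij log p_ij) / log(n)`, the divergence is
#' `d_j = 1 - e_j`, and `w_j = d_j / sum_j(d_j)` within each subsystem, so
#' the health and economy weight sets each sum to one.
#'
#' @param normalized Standardized panel from [normalize_indicators()].
#' @inheritParams validate_panel
#' @param systems Which subsystems to weight (default both).
#' @return A tibble `system, indicator, weight`.
#' @export
entropy_weights <- function(normalized, schema = indicator_schema(),
                            systems = c("health", "economy")) {
  schema <- validate_schema(schema)
  systems <- match.arg(systems, c("health", "economy"), several.ok = TRUE)
  if (any(normalized$value <= 0)) {
    stop("entropy weights need strictly positive standardized values; ",
      "use normalize_indicators() with a positive epsilon",
      call. = FALSE
    )
  }
  n_obs <- dplyr::n_distinct(normalized$region, normalized$year)
  if (n_obs < 2) {
    stop("entropy weights need at least 2 region-year observations",
      call. = FALSE
    )
  }
  sys_of <- stats::setNames(schema$system, schema$id)
  df <- normalized[sys_of[normalized$indicator] %in% systems, ]
  df$system <- sys_of[df$indicator]

  w <- df |>
    dplyr::group_by(.data$system, .data$indicator) |>
    dplyr::summarise(
      d = {
        p <- .data$value / sum(.data$value)
        1 - (-sum(p * log(p)) / log(dplyr::n()))
      },
      .groups = "drop_last"
    )
  no_info <- dplyr::summarise(w, tot = sum(.data$d))
  if (any(no_info$tot <= 0)) {
    stop("no information: all indicators in system '",
      no_info$system[no_info$tot <= 0][1],
      "' are perfectly uniform",
      call. = FALSE
    )
  }
  w |>
    dplyr::mutate(weight = .data$d / sum(.data$d)) |>
    dplyr::ungroup() |>
    dplyr::select("system", "indicator", "weight")
}

#' Comprehensive evaluation index by linear weighting
#'
#' Aggregates standardized indicator values into the per-subsystem
#' comprehensive evaluation index `U = sum_j(w_j * x_ij)` for every
#' region-year. With entropy weights summing to one and standardized
#' values in `(0, 1 + epsilon]`, `U` lies in `(0, 1 + epsilon]`.
#'
#' @param normalized Standardized panel from [normalize_indicators()].
#' @param weights Weight tibble from [entropy_weights()] (or externally
#'   supplied weights with the same columns).
#' @inheritParams validate_panel
#' @return A tibble `region, year, system, index`.
#' @export
composite_index <- function(normalized, weights,
                            schema = indicator_schema()) {
  schema <- validate_schema(schema)
  sys_of <- stats::setNames(schema$system, schema$id)
  for (s in unique(weights$system)) {
    want <- sort(weights$indicator[weights$system == s])
    have <- sort(unique(normalized$indicator[
      sys_of[normalized$indicator] == s
    ]))
    if (!identical(want, have)) {
      stop("configuration error: weights for system '", s,
        "' do not match the panel's indicator set",
        call. = FALSE
      )
    }
    tot <- sum(weights$weight[weights$system == s])
    if (abs(tot - 1) > 1e-10 || any(weights$weight < 0)) {
      stop("configuration error: weights for system '", s,
        "' must be non-negative and sum to 1",
        call. = FALSE
      )
    }
  }
  normalized |>
    dplyr::inner_join(weights, by = "indicator") |>
    dplyr::group_by(.data$region, .data$year, .data$system) |>
    dplyr::summarise(
      index = sum(.data$weight * .data$value),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$system, .data$region, .data$year)
}

#' Write entropy weights to CSV
#'
#' @param weights Weight tibble from [entropy_weights()].
#' @param path Output file path.
#' @param digits Decimal places (default 6).
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path, digits = 6) {
  out <- dplyr::mutate(weights, weight = round(.data$weight, digits))
  readr::write_csv(out, path)
  invisible(path)
}
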