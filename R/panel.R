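#' Validate a long-format indicator panel
#'
#' Checks that a long table of indicator observations forms a balanced
#' region x year x indicator panel over the given schema: every
#' combination present exactly once, all values numeric and non-missing,
#' and every indicator id known to the schema. Regions are ordered
#' lexicographically and years ascending so downstream results do not
#' depend on input row order.
#'
#' @param panel A data frame with columns `region`, `year`, `indicator`,
#'   `value`.
#' @param schema Indicator schema tibble (default [indicator_schema()]).
#' @return The canonically ordered panel as a tibble.
#' @export
validate_panel <- function(panel, schema = indicator_schema()) {
  schema <- validate_schema(schema)
  needed <- c("region", "year", "indicator", "value")
  missing <- setdiff(needed, names(panel))
  if (length(missing) > 0) {
    stop("panel is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  panel <- tibble::tibble(
    region = as.character(panel$region),
    year = as.integer(panel$year),
    indicator = as.character(panel$indicator),
    value = panel$value
  )

  unknown <- setdiff(unique(panel$indicator), schema$id)
  if (length(unknown) > 0) {
    stop("schema error: unknown indicator id(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.numeric(panel$value) || anyNA(panel$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(panel$value))))[1]
    stop("parse error: non-numeric or missing value at row ", bad,
      call. = FALSE
    )
  }

  regions <- sort(unique(panel$region))
  years <- sort(unique(panel$year))
  full <- tidyr::expand_grid(
    region = regions, year = years, indicator = schema$id
  )
  counts <- dplyr::count(panel, .data$region, .data$year, .data$indicator)
  dup <- counts[counts$n > 1, ]
  if (nrow(dup) > 0) {
    stop("duplicate observation for (", dup$region[1], ", ", dup$year[1],
      ", ", dup$indicator[1], ")",
      call. = FALSE
    )
  }
  miss <- dplyr::anti_join(full, panel,
    by = c("region", "year", "indicator")
  )
  if (nrow(miss) > 0) {
    stop("incomplete panel: missing (", miss$region[1], ", ", miss$year[1],
      ", ", miss$indicator[1], ")",
      call. = FALSE
    )
  }
  dplyr::arrange(panel, .data$region, .data$year,
    match(.data$indicator, schema$id)
  )
}

#' Read an indicator panel from a long-format CSV
#'
#' The file must be a delimited table with a header row
#' `region,year,indicator,value`. The panel is validated with
#' [validate_panel()] and returned in canonical order.
#'
#' @inheritParams validate_panel
#' @param path Path to the CSV file.
#' @return A validated panel tibble.
#' @export
read_panel <- function(path, schema = indicator_schema()) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  raw <- suppressWarnings(readr::read_csv(path,
    col_types = readr::cols(
      region = readr::col_character(),
      year = readr::col_integer(),
      indicator = readr::col_character(),
      value = readr::col_double()
    )
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("parse error in ", path, " at row ", probs$row[1], ": ",
      probs$expected[1], " but got '", probs$actual[1], "'",
      call. = FALSE
    )
  }
  validate_panel(raw, schema)
}

#' Write coordination records to CSV
#'
#' Writes the per-region-year output of [run_coordination()] — composite
#' indices, relative development degree, coupling degree, coordination
#' index, coupling coordination degree and classification labels — as a
#' delimited table, rounding numeric columns to a configurable number of
#' decimals.
#'
#' @param records Coordination records tibble from [run_coordination()].
#' @param path Output file path.
#' @param digits Decimal places for numeric columns (default 4).
#' @return `path`, invisibly.
#' @export
write_coordination <- function(records, path, digits = 4) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("no coordination records to write", call. = FALSE)
  }
  cols <- c(
    "region", "year", "U_h", "U_e", "S", "S_category", "C", "T", "D",
    "stage", "type", "grade"
  )
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    stop("records are missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- dplyr::mutate(records[cols],
    dplyr::across(dplyr::where(is.numeric) & !dplyr::all_of("year"),
      ~ round(.x, digits)
    )
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read coordination records written by [write_coordination()]
#'
#' @param path Path to a coordination CSV.
#' @return A tibble of coordination records.
#' @export
read_coordination <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  readr::read_csv(path,
    col_types = readr::cols(
      region = readr::col_character(),
      year = readr::col_integer(),
      S_category = readr::col_character(),
      stage = readr::col_character(),
      type = readr::col_character(),
      grade = readr::col_character(),
      .default = readr::col_double()
    )
  )
}

#' Read an indicator panel from a wide-format CSV
#'
#' Convenience wrapper for files with columns `region`, `year` and one
#' column per indicator id; the table is pivoted to the canonical long
#' form and validated with [validate_panel()].
#'
#' @inheritParams read_panel
#' @return A validated long panel tibble.
#' @export
read_panel_wide <- function(path, schema = indicator_schema()) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(raw, -c("region", "year"),
    names_to = "indicator", values_to = "value"
  )
  validate_panel(long, schema)
}

#' Pivot a long indicator panel to wide form
#'
#' Convenience wrapper returning one row per region-year with one column
#' per indicator.
#'
#' @inheritParams validate_panel
#' @return A wide tibble with columns `region`, `year` and one column per
#'   indicator id.
#' @export
pivot_panel_wide <- function(panel, schema = indicator_schema()) {
  panel <- validate_panel(panel, schema)
  tidyr::pivot_wider(panel,
    names_from = "indicator", values_from = "value"
  )
}
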