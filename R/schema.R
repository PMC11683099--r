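#' Default evaluation indicator schema
#'
#' Returns the bundled two-subsystem indicator schema used to evaluate
#' coordinated development of health resource allocation and regional
#' economic development: 14 health-resource indicators (aggregate,
#' per-capita and per-land-area allocation of financial, material and
#' human resources) and 14 economic-development indicators (scale,
#' structure, dynamics and benefits). Two economic indicators enter with
#' negative direction — the consumer price index and the urban registered
#' unemployed population — because larger values indicate worse
#' development; all other indicators are positive-direction.
#'
#' @return A tibble with one row per indicator and columns
#'   \describe{
#'     \item{id}{short unique indicator key}
#'     \item{name}{indicator name}
#'     \item{system}{`"health"` or `"economy"`}
#'     \item{layer}{system-layer label the indicator belongs to}
#'     \item{direction}{`+1` (benefit) or `-1` (cost) orientation}
#'   }
#' @seealso [read_indicator_schema()] to load a user-supplied schema.
#' @export
#' @examples
#' indicator_schema()
indicator_schema <- function() {
  h <- tibble::tribble(
    ~id, ~name, ~layer,
    "h_total_health_exp", "Total health expenditure", "Aggregate allocation: financial",
    "h_total_institutions", "Total number of medical institutions", "Aggregate allocation: material",
    "h_total_beds", "Total number of beds in medical institutions", "Aggregate allocation: material",
    "h_total_physicians", "Total number of practicing (assistant) physicians", "Aggregate allocation: human",
    "h_total_nurses", "Total number of registered nurses", "Aggregate allocation: human",
    "h_pc_health_exp", "Per capita health expenditure", "Per capita allocation: financial",
    "h_institutions_per_1000", "Medical institutions per 1,000 population", "Per capita allocation: material",
    "h_beds_per_1000", "Beds in medical institutions per 1,000 population", "Per capita allocation: material",
    "h_physicians_per_1000", "Practicing (assistant) physicians per 1,000 population", "Per capita allocation: human",
    "h_nurses_per_1000", "Registered nurses per 1,000 population", "Per capita allocation: human",
    "h_institution_density", "Distribution density of medical institutions", "Per land allocation: material",
    "h_bed_density", "Distribution density of beds in medical institutions", "Per land allocation: material",
    "h_physician_density", "Distribution density of practicing (assistant) physicians", "Per land allocation: human",
    "h_nurse_density", "Distribution density of registered nurses", "Per land allocation: human"
  )
  e <- tibble::tribble(
    ~id, ~name, ~layer,
    "e_gdp", "GDP", "Economic scale: productivity",
    "e_retail_sales", "Total retail sales of social consumer goods", "Economic scale: consumption",
    "e_trade_volume", "Total volume of imports and exports", "Economic scale: trade",
    "e_secondary_share", "Proportion of secondary industry to GDP", "Economic structure: industrial",
    "e_tertiary_share", "Proportion of tertiary industry to GDP", "Economic structure: industrial",
    "e_tech_market_share", "Proportion of technology market turnover to GDP", "Economic structure: technical",
    "e_fai_growth", "Growth rate of fixed-asset investment", "Economic dynamics: investment",
    "e_budget_exp_growth", "Growth rate of general public budget expenditure", "Economic dynamics: investment",
    "e_pc_retail_sales", "Total retail sales of consumer goods per capita", "Economic dynamics: consumption",
    "e_trade_growth", "Growth rate of exports and imports", "Economic dynamics: trade",
    "e_patents_granted", "Number of patents granted", "Economic dynamics: innovation",
    "e_pc_disposable_income", "Per capita disposable income", "Economic benefits: income",
    "e_cpi", "CPI", "Economic benefits: price fluctuation",
    "e_unemployed", "Urban registered unemployed population", "Economic benefits: employment"
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(h, system = "health"),
    dplyr::mutate(e, system = "economy")
  )
  out$direction <- ifelse(out$id %in% c("e_cpi", "e_unemployed"), -1L, 1L)
  dplyr::select(out, "id", "name", "system", "layer", "direction")
}

#' Read an indicator schema from file
#'
#' Loads a schema from JSON, YAML or CSV. The file must describe a list of
#' indicators with fields `id`, `name`, `system`, `layer` and `direction`.
#' The bundled default schema is installed at
#' `system.file("extdata", "indicator_schema.json", package = "ccdm")`.
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` or `.csv` schema file.
#' @return A validated schema tibble (see [indicator_schema()]).
#' @export
read_indicator_schema <- function(path) {
  if (!file.exists(path)) {
    stop("schema file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml = {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML schemas requires the 'yaml' package", call. = FALSE)
      }
      do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
    },
    csv = readr::read_csv(path, show_col_types = FALSE),
    stop("unsupported schema format: .", ext, call. = FALSE)
  )
  schema <- tibble::as_tibble(raw)
  schema$direction <- as.integer(schema$direction)
  validate_schema(schema)
}

#' @keywords internal
validate_schema <- function(schema) {
  needed <- c("id", "name", "system", "layer", "direction")
  missing <- setdiff(needed, names(schema))
  if (length(missing) > 0) {
    stop("schema is missing fields: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(schema$id)) {
    stop("schema error: duplicated indicator ids: ",
      paste(unique(schema$id[duplicated(schema$id)]), collapse = ", "),
      call. = FALSE
    )
  }
  bad_sys <- setdiff(unique(schema$system), c("health", "economy"))
  if (length(bad_sys) > 0) {
    stop("schema error: unknown system(s): ", paste(bad_sys, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(schema$direction %in% c(-1L, 1L))) {
    stop("schema error: direction must be +1 or -1", call. = FALSE)
  }
  tibble::as_tibble(schema[needed])
}
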