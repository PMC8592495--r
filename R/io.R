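# CSV/JSON/YAML readers and writers. Every CSV is UTF-8, comma-separated,
# header required, empty string = missing; each writer emits a sidecar
# JSON declaring the column schema and coding conventions (sex as
# female/male strings; IMD quintile 1 = most deprived).

csv_sidecar <- function(path, df, notes = NULL) {
  side <- list(
    file = basename(path),
    columns = lapply(names(df), function(nm) {
      list(name = nm, type = class(df[[nm]])[1L])
    }),
    conventions = c(
      "sex coded as strings: female, male",
      "imd_quintile: integer 1-5, 1 = most deprived",
      "empty string = missing"
    )
  )
  if (!is.null(notes)) side$notes <- notes
  jsonlite::write_json(side, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Write a table as CSV with a sidecar schema
#'
#' @param df Data frame to write.
#' @param path Output CSV path.
#' @param notes Optional character notes stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, notes = NULL) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  csv_sidecar(path, df, notes)
  invisible(path)
}

#' Read and validate survey microdata
#'
#' Expects columns `id`, `age_band`, `sex`, `imd_quintile`, `weight` and
#' one column per deficit item (`deficit_*` by default). Age bands must be
#' one of the nine labels 50-54 ... 85-89, 90+; weights must be positive;
#' ids unique. Empty cells are parsed as missing.
#'
#' @param path CSV file path.
#' @return Validated survey data.frame.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                        check.names = FALSE)
  need <- c("id", "age_band", "sex", "imd_quintile", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("survey file lacks columns: %s", paste(miss, collapse = ", "))
  bad <- which(!df$age_band %in% age_bands())
  if (length(bad))
    stopf("row %d: unknown age band label '%s'", bad[1L], df$age_band[bad[1L]])
  bad <- which(!df$sex %in% sex_levels())
  if (length(bad))
    stopf("row %d: unknown sex label '%s'", bad[1L], df$sex[bad[1L]])
  bad <- which(!df$imd_quintile %in% 1:5)
  if (length(bad))
    stopf("row %d: imd_quintile must be 1..5", bad[1L])
  bad <- which(!is.finite(df$weight) | df$weight <= 0)
  if (length(bad))
    stopf("row %d: non-positive weight", bad[1L])
  dup <- which(duplicated(df$id))
  if (length(dup))
    stopf("row %d: duplicate respondent id '%s'", dup[1L], df$id[dup[1L]])
  df
}

#' Read and validate an area population table
#'
#' @param path CSV path with columns `area_id`, `name`, `imd_rank`,
#'   `imd_quintile`, `age_band`, `sex`, `population` (long format, one row
#'   per area x age band x sex).
#' @return Validated area data.frame.
#' @export
read_areas <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  validate_area_table(df)
  df
}

#' Read a vaccination (first-dose) table
#'
#' @param path CSV path with columns `area_id`, `doses`.
#' @return Validated data.frame.
#' @export
read_doses <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  miss <- setdiff(c("area_id", "doses"), names(df))
  if (length(miss))
    stopf("dose file lacks columns: %s", paste(miss, collapse = ", "))
  if (any(!is.finite(df$doses) | df$doses < 0))
    stopf("dose counts must be non-negative")
  df
}

#' Read a long-format risk-factor table
#'
#' @param path CSV path with columns `area_id`, `factor`, `count`.
#' @return Validated data.frame.
#' @export
read_risk_factors <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  miss <- setdiff(c("area_id", "factor", "count"), names(df))
  if (length(miss))
    stopf("risk-factor file lacks columns: %s", paste(miss, collapse = ", "))
  if (any(!is.finite(df$count) | df$count < 0))
    stopf("risk-factor counts must be non-negative")
  df
}

#' Read a deficit schema from YAML or JSON
#'
#' The file holds a list of items, each with `name`, `kind` and (for graded
#' items) a `mapping` of observed levels to values in [0, 1].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `deficit_schema`.
#' @export
read_deficit_schema <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  items <- lapply(raw$items, function(it) {
    if (!is.null(it$mapping)) it$mapping <- unlist(it$mapping)
    it
  })
  deficit_schema(items)
}

#' Write a deficit schema to YAML
#'
#' @param schema A `deficit_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deficit_schema <- function(schema, path) {
  items <- lapply(schema$items, function(it) {
    list(name = it$name, kind = it$kind, mapping = as.list(it$mapping))
  })
  yaml::write_yaml(list(items = items), path)
  invisible(path)
}

#' Write generated survey and area tables to a directory
#'
#' Emits `survey.csv`, `areas.csv`, `doses.csv`, `risk_factors.csv` (each
#' with a sidecar schema) and `truth.json` with the generator's analytic
#' stratum probabilities and configuration.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return The list from [generate_survey()] and [generate_areas()],
#'   invisibly.
#' @export
write_simulation <- function(config = generator_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sv <- generate_survey(config)
  ar <- generate_areas(config)
  write_table_csv(sv$survey, file.path(dir, "survey.csv"))
  write_table_csv(ar$areas, file.path(dir, "areas.csv"))
  write_table_csv(ar$doses, file.path(dir, "doses.csv"))
  write_table_csv(ar$risk_factors, file.path(dir, "risk_factors.csv"))
  truth <- list(config = unclass(sv$truth$config),
                nonresponse_realized = sv$truth$nonresponse_realized,
                stratum_probs = sv$truth$stratum_probs)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(survey = sv$survey, truth = sv$truth, areas = ar$areas,
                 doses = ar$doses, risk_factors = ar$risk_factors))
}
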