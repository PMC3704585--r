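#' Read a long-format case panel from CSV
#'
#' Expects columns `region,year,age_class,count` (header mandatory,
#' UTF-8). Validation failures name the file and offending line.
#'
#' @param path CSV file path.
#' @param scheme the [age_scheme] the panel must be keyed on.
#' @return Validated case panel data frame.
#' @export
read_case_panel <- function(path, scheme = fine_age_scheme()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("region", "year", "age_class", "count")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, ": missing columns: ", paste(miss, collapse = ", "))
  bad <- which(is.na(df$count) | df$count < 0)
  if (length(bad))
    stop(path, ": negative or missing count at line ", bad[1L] + 1L)
  unknown <- which(!df$age_class %in% scheme$label)
  if (length(unknown))
    stop(path, ": unknown age class '", df$age_class[unknown[1L]],
         "' at line ", unknown[1L] + 1L)
  dup <- which(duplicated(df[req[1:3]]))
  if (length(dup))
    stop(path, ": duplicate (region, year, age_class) key at line ", dup[1L] + 1L)
  df$region <- as.character(df$region)
  df$year <- as.integer(df$year)
  df
}

#' Read a population panel and optional standard structure from CSV
#'
#' The panel has columns `region,year,age_class,population`; the standard
#' structure file has `age_class,proportion`.
#'
#' @inheritParams read_case_panel
#' @param standard_path optional CSV of the standard structure.
#' @return List with `pop` and (if requested) `standard`.
#' @export
read_population_panel <- function(path, scheme = coarse_age_scheme(),
                                  standard_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("region", "year", "age_class", "population")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, ": missing columns: ", paste(miss, collapse = ", "))
  bad <- which(is.na(df$population) | df$population <= 0)
  if (length(bad))
    stop(path, ": non-positive population at line ", bad[1L] + 1L)
  df$region <- as.character(df$region)
  df$year <- as.integer(df$year)
  validate_population_panel(df, scheme)
  out <- list(pop = df)
  if (!is.null(standard_path)) {
    st <- utils::read.csv(standard_path, stringsAsFactors = FALSE)
    validate_standard(st, scheme)
    out$standard <- st
  }
  out
}

#' Read a long-format covariate panel from CSV
#'
#' Columns `region,year,variable,value`.
#'
#' @inheritParams read_case_panel
#' @return Data frame.
#' @export
read_covariate_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("region", "year", "variable", "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, ": missing columns: ", paste(miss, collapse = ", "))
  df$region <- as.character(df$region)
  df$year <- as.integer(df$year)
  df
}

#' Read an adjacency edge list from CSV
#'
#' Two columns of region ids, with an optional third column tagging
#' bridge edges by opening year; `exclude_bridges = TRUE` drops tagged
#' edges for sensitivity runs.
#'
#' @inheritParams read_case_panel
#' @param regions region id vector fixing matrix order.
#' @param exclude_bridges drop edges with a non-empty bridge tag.
#' @return Binary adjacency matrix.
#' @export
read_adjacency <- function(path, regions, exclude_bridges = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(df) < 2L) stop(path, ": need at least two columns")
  if (exclude_bridges && ncol(df) >= 3L)
    df <- df[is.na(df[[3L]]) | df[[3L]] == "", , drop = FALSE]
  build_adjacency(df[, 1:2], regions)
}

#' Read a national year/value series from CSV
#'
#' @inheritParams read_case_panel
#' @return Data frame `year`, `value`.
#' @export
read_national_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("year", "value") %in% names(df)))
    stop(path, ": need columns year,value")
  if (any(df$value <= 0, na.rm = TRUE))
    stop(path, ": national series values must be positive")
  df$year <- as.integer(df$year)
  df[order(df$year), c("year", "value")]
}

#' Write a metric series to CSV
#'
#' Columns `region,year,value`; missing values are written as empty
#' fields.
#'
#' @param series metric series data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a JSON run configuration
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [pipeline_config()].
#'
#' @param path JSON file path.
#' @return A `pipeline_config` list.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(path, ": unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}
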