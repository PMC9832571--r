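#' Convert calendar dates to the day-of-season coordinate
#'
#' Field dates are expressed as whole days elapsed since the most recent
#' season anchor (1 July by default, the austral mid-winter reference used
#' for a southern-hemisphere flowering season). The season year is the
#' calendar year in which that anchor falls, so a date in January belongs
#' to the season that started the previous July.
#'
#' @param dates `Date` vector or character coercible with [as.Date()]
#'   (ISO-8601).
#' @param anchor month-day string `"MM-DD"`; default `"07-01"`.
#' @return data.frame with columns `season_year` (integer) and `day`
#'   (integer days since the anchor, >= 0).
#' @examples
#' to_day_of_season(as.Date(c("2008-07-01", "2008-09-08", "2009-01-15")))
#' @export
to_day_of_season <- function(dates, anchor = "07-01") {
  if (!inherits(dates, "Date")) {
    parsed <- tryCatch(as.Date(dates), error = function(e) NA)
    if (all(is.na(parsed)) && length(dates) > 0 || anyNA(parsed))
      md_validation_error("malformed calendar date(s); expected ISO-8601")
    dates <- parsed
  }
  if (anyNA(dates)) md_validation_error("malformed calendar date(s)")
  if (!grepl("^[0-1][0-9]-[0-3][0-9]$", anchor))
    md_config_error(sprintf("invalid anchor '%s'; expected 'MM-DD'", anchor))
  yr <- as.integer(format(dates, "%Y"))
  anchor_this <- as.Date(paste0(yr, "-", anchor))
  season_year <- ifelse(dates >= anchor_this, yr, yr - 1L)
  day <- as.integer(dates - as.Date(paste0(season_year, "-", anchor)))
  data.frame(season_year = as.integer(season_year), day = day)
}

# Canonical column sets per table
.floral_cols <- c("season_year", "day", "site", "unit", "plant_taxon",
                  "flower_count")
.nest_cols   <- c("nest_id", "bee_taxon", "site", "season_year", "end_day",
                  "brood_cells", "cavity_length")
.pollen_cols <- c("nest_id", "plant_taxon", "grain_count")

# Resolve a file's columns to the canonical schema via a dialect mapping
# (named character vector: canonical -> file column name). A `date` column
# may stand in for (season_year, day) and is converted with `anchor`.
resolve_dialect <- function(df, canonical, dialect = NULL, anchor = "07-01",
                            optional = character()) {
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || any(names(dialect) == ""))
      md_config_error("dialect must be a named vector: canonical = file column")
    for (canon in names(dialect)) {
      file_col <- dialect[[canon]]
      if (!file_col %in% names(df))
        md_config_error(sprintf("dialect maps '%s' to missing column '%s'",
                                canon, file_col))
      names(df)[names(df) == file_col] <- canon
    }
  }
  needs_day <- all(c("season_year", "day") %in% canonical)
  if (needs_day && !all(c("season_year", "day") %in% names(df)) &&
      "date" %in% names(df)) {
    conv <- to_day_of_season(df$date, anchor = anchor)
    df$season_year <- conv$season_year
    df$day <- conv$day
    df$date <- NULL
  }
  required <- setdiff(canonical, optional)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    md_config_error(paste0("missing required column(s): ",
                           paste(missing, collapse = ", ")))
  for (opt in setdiff(canonical, names(df))) df[[opt]] <- NA
  df[, canonical, drop = FALSE]
}

fail_rows <- function(bad, what) {
  if (any(bad, na.rm = TRUE))
    md_validation_error(sprintf("%s in row(s): %s", what,
                                paste(which(bad), collapse = ", ")))
}

#' Validate a floral-survey table
#'
#' @param df data.frame with the canonical floral-survey columns.
#' @return the validated data.frame (invisibly identical to the input).
#' @export
validate_floral_surveys <- function(df) {
  fail_rows(is.na(df$flower_count) | df$flower_count < 0,
            "negative or missing flower_count")
  fail_rows(is.na(df$day) | df$day < 0 | df$day > 365,
            "day outside [0, 365]")
  fail_rows(is.na(df$season_year), "missing season_year")
  df$season_year <- as.integer(df$season_year)
  df$day <- as.integer(df$day)
  df
}

#' @rdname validate_floral_surveys
#' @export
validate_nest_records <- function(df) {
  fail_rows(is.na(df$season_year), "missing season_year")
  fail_rows(is.na(df$end_day) | df$end_day < 0, "negative or missing end_day")
  cells <- df$brood_cells
  fail_rows(!is.na(cells) & (cells < 1 | cells != round(cells)),
            "brood_cells not a positive integer")
  fail_rows(!is.na(df$cavity_length) & df$cavity_length < 0,
            "negative cavity_length")
  fail_rows(is.na(cells) & is.na(df$cavity_length),
            "neither brood_cells nor cavity_length present")
  fail_rows(is.na(df$nest_id) | duplicated(df$nest_id), "duplicate or missing nest_id")
  df$season_year <- as.integer(df$season_year)
  df
}

#' @rdname validate_floral_surveys
#' @export
validate_pollen_samples <- function(df) {
  fail_rows(is.na(df$grain_count) | df$grain_count < 0 |
              df$grain_count != round(df$grain_count),
            "grain_count not a non-negative integer")
  fail_rows(duplicated(df[, c("nest_id", "plant_taxon")]),
            "duplicated (nest_id, plant_taxon)")
  df
}

read_table_generic <- function(path, canonical, validator, dialect, anchor,
                               optional = character()) {
  if (!file.exists(path)) md_config_error(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- resolve_dialect(df, canonical, dialect, anchor, optional)
  if (nrow(df) == 0) {
    warning(sprintf("empty table read from %s", path), call. = FALSE)
    return(df)
  }
  validator(df)
}

#' Read the three field tables
#'
#' Comma-delimited UTF-8 text with a header row. A `dialect` (named
#' character vector, canonical name = file column name) absorbs naming
#' differences between field campaigns; a `date` column in ISO-8601 may
#' replace the (`season_year`, `day`) pair and is converted with
#' [to_day_of_season()]. Rows violating the table invariants abort with a
#' row-indexed validation error.
#'
#' @param path CSV file path.
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names.
#' @param anchor season anchor passed to [to_day_of_season()].
#' @return validated data.frame in the canonical schema.
#' @export
read_floral_surveys <- function(path, dialect = NULL, anchor = "07-01") {
  read_table_generic(path, .floral_cols, validate_floral_surveys, dialect,
                     anchor)
}

#' @rdname read_floral_surveys
#' @export
read_nest_records <- function(path, dialect = NULL, anchor = "07-01") {
  read_table_generic(path, .nest_cols, validate_nest_records, dialect, anchor,
                     optional = c("brood_cells", "cavity_length"))
}

#' @rdname read_floral_surveys
#' @export
read_pollen_samples <- function(path, dialect = NULL) {
  read_table_generic(path, .pollen_cols, validate_pollen_samples, dialect,
                     "07-01")
}

#' Write a table in the canonical schema
#'
#' The writer emits exactly the schema the readers accept, so a write/read
#' round trip is lossless.
#'
#' @param df validated table.
#' @param path output CSV path.
#' @export
write_canonical_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Pool per-plot flower counts
#'
#' Sums flower counts over plots (and, by default, over sites) per
#' (season_year, day, plant_taxon) before phenology estimation. Because
#' weighted mean dates depend only on relative abundances, any common
#' scaling of the pooled counts is immaterial.
#'
#' @param surveys validated floral-survey table.
#' @param stratify_sites if `TRUE`, keep sites separate (adds a `site`
#'   column to the grouping).
#' @return data.frame with `season_year`, `day`, `plant_taxon`,
#'   (optionally `site`) and pooled `flower_count`.
#' @export
pool_floral_surveys <- function(surveys, stratify_sites = FALSE) {
  keys <- c("season_year", "day", "plant_taxon",
            if (stratify_sites) "site")
  agg <- stats::aggregate(surveys["flower_count"], by = surveys[keys],
                          FUN = sum)
  agg[do.call(order, agg[keys]), c(keys, "flower_count"), drop = FALSE]
}
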