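# Reading, validating and writing the pipeline's tables.
#
# All tables are RFC-4180 CSV, UTF-8, header row, ISO-8601 dates and WGS84
# decimal-degree coordinates. Readers reject invalid rows with row-numbered
# diagnostics instead of aborting; the rejected rows travel on the result as
# an attribute so that accepted + rejected always partition the input.

#' Day of year
#'
#' Calendar day index with January 1 = 1. Leap years are kept as-is, so
#' 2008-02-27 is day 58 and dates after February in a leap year are shifted
#' by one relative to common years; no 365-day normalisation is applied.
#'
#' @param date a `Date` vector, or anything `as.Date()` accepts.
#' @return integer vector, 1-366.
#' @export
#' @examples
#' day_of_year(as.Date("2008-02-27")) # 58
day_of_year <- function(date) {
  date <- as.Date(date)
  as.integer(as.POSIXlt(date)$yday) + 1L
}

# Parse dates trying each format in turn; NA where none matches.
parse_dates <- function(x, formats = c("%Y-%m-%d", "%d.%m.%Y")) {
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  todo <- rep(TRUE, length(x))
  for (fmt in formats) {
    if (!any(todo)) break
    parsed <- as.Date(x[todo], format = fmt)
    out[todo][!is.na(parsed)] <- parsed[!is.na(parsed)]
    todo[todo] <- is.na(parsed)
  }
  out
}

read_table_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  df
}

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  names(col_map) <- tolower(names(col_map))
  col_map[] <- tolower(col_map)
  for (canonical in names(col_map)) {
    from <- col_map[[canonical]]
    if (from %in% names(df)) names(df)[names(df) == from] <- canonical
  }
  df
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

# Shared row-validation scaffold: `checks` is a named list of logical
# vectors, TRUE = bad row, name = reason. Returns accepted tibble with the
# rejected rows (and reasons) attached as attribute "rejected".
partition_rows <- function(df, checks, what, quiet = FALSE) {
  reason <- rep(NA_character_, nrow(df))
  for (nm in names(checks)) {
    bad <- checks[[nm]] & is.na(reason)
    reason[bad] <- nm
  }
  keep <- is.na(reason)
  rejected <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  accepted <- tibble::as_tibble(df[keep, , drop = FALSE])
  if (!quiet) {
    message(sprintf("%s: %d row(s) accepted, %d rejected", what,
                    nrow(accepted), nrow(rejected)))
    if (nrow(rejected) > 0) {
      for (i in seq_len(min(nrow(rejected), 10))) {
        message(sprintf("  row %d rejected: %s", rejected$row[i],
                        rejected$reason[i]))
      }
      if (nrow(rejected) > 10) message("  ...")
    }
  }
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Read amphibian sighting records
#'
#' Expected columns (case-insensitive, remappable through `col_map`):
#' `record_id` (optional), `species`, `date`, `lon`, `lat`, `individuals`,
#' `mat_degc`. Rows violating the record invariants (unknown species,
#' unparseable date, individuals < 1, coordinates off the globe, non-finite
#' MAT, date outside `study_years`) are rejected individually with
#' row-numbered diagnostics; a missing mandatory column is a schema error.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(individuals = "anzahl")`.
#' @param date_formats formats tried in order when parsing dates.
#' @param study_years optional integer vector; dates outside it are
#'   rejected.
#' @param quiet suppress the accept/reject log.
#' @return tibble of accepted records with a `rejected` attribute
#'   (tibble of row numbers and reasons).
#' @export
read_observations <- function(path, col_map = NULL,
                              date_formats = c("%Y-%m-%d", "%d.%m.%Y"),
                              study_years = NULL, quiet = FALSE) {
  df <- apply_col_map(read_table_csv(path), col_map)
  require_columns(df, c("species", "date", "lon", "lat", "individuals",
                        "mat_degc"), "observations")
  if (!"record_id" %in% names(df)) {
    df$record_id <- sprintf("obs-%06d", seq_len(nrow(df)))
  }
  df$date <- parse_dates(df$date, date_formats)
  df$individuals <- suppressWarnings(as.numeric(df$individuals))
  df$mat_degc <- suppressWarnings(as.numeric(df$mat_degc))
  checks <- list(
    "unknown species"      = !(df$species %in% AMPHIBIAN_SPECIES),
    "unparseable date"     = is.na(df$date),
    "individuals < 1"      = is.na(df$individuals) | df$individuals < 1,
    "latitude out of range"  = is.na(df$lat) | abs(df$lat) > 90,
    "longitude out of range" = is.na(df$lon) | abs(df$lon) > 180,
    "non-finite MAT"       = !is.finite(df$mat_degc)
  )
  if (!is.null(study_years)) {
    yr <- as.integer(format(df$date, "%Y"))
    checks[["date outside study window"]] <- !is.na(df$date) &
      !(yr %in% study_years)
  }
  out <- partition_rows(df, checks, "observations", quiet = quiet)
  out$individuals <- as.integer(out$individuals)
  out
}

#' Read plant phenophase reports
#'
#' Same conventions as [read_observations()]; additionally the
#' (species, phase) pair must be one the monitoring scheme defines:
#' flowering for snowdrop, common hazel, goat willow and apricot, leaf
#' unfolding for European larch, horse chestnut and silver birch.
#'
#' @inheritParams read_observations
#' @return tibble of accepted reports with a `rejected` attribute.
#' @export
read_phenology <- function(path, col_map = NULL,
                           date_formats = c("%Y-%m-%d", "%d.%m.%Y"),
                           study_years = NULL, quiet = FALSE) {
  df <- apply_col_map(read_table_csv(path), col_map)
  require_columns(df, c("species", "phase", "date", "lon", "lat",
                        "mat_degc"), "phenology")
  if (!"record_id" %in% names(df)) {
    df$record_id <- sprintf("phe-%06d", seq_len(nrow(df)))
  }
  df$date <- parse_dates(df$date, date_formats)
  df$mat_degc <- suppressWarnings(as.numeric(df$mat_degc))
  valid_pair <- !is.na(PLANT_PHASES[df$species]) &
    df$phase == unname(PLANT_PHASES[df$species])
  checks <- list(
    "unknown species"           = !(df$species %in% names(PLANT_PHASES)),
    "invalid species/phase pair" = !valid_pair,
    "unparseable date"          = is.na(df$date),
    "latitude out of range"     = is.na(df$lat) | abs(df$lat) > 90,
    "longitude out of range"    = is.na(df$lon) | abs(df$lon) > 180,
    "non-finite MAT"            = !is.finite(df$mat_degc)
  )
  if (!is.null(study_years)) {
    yr <- as.integer(format(df$date, "%Y"))
    checks[["date outside study window"]] <- !is.na(df$date) &
      !(yr %in% study_years)
  }
  partition_rows(df, checks, "phenology", quiet = quiet)
}

validate_start_dates <- function(rows, what = "start dates") {
  require_columns(rows, c("taxon", "region", "year", "onset_doy"), what)
  rows$year <- as.integer(rows$year)
  rows$onset_doy <- as.integer(rows$onset_doy)
  if (any(!rows$region %in% REGION_LEVELS)) {
    stop(what, ": unknown region value", call. = FALSE)
  }
  if (any(is.na(rows$onset_doy)) ||
      any(rows$onset_doy < 1 | rows$onset_doy > 366)) {
    stop(what, ": onset_doy must be in [1, 366]", call. = FALSE)
  }
  key <- paste(rows$taxon, rows$region, rows$year, sep = "/")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    stop(what, ": duplicate (taxon, region, year) key(s): ",
         paste(dup, collapse = "; "), call. = FALSE)
  }
  tibble::as_tibble(rows[order(rows$taxon, rows$region, rows$year),
                         c("taxon", "region", "year", "onset_doy")])
}

#' Write / read the onset (start-date) table
#'
#' The central table of the analysis: one row per (taxon, region, year)
#' giving the onset day of year. The round trip is lossless; rows are
#' sorted by (taxon, region, year); a duplicate key is an error naming the
#' key. `read_start_dates()` is also the entry point for an externally
#' derived onset table (e.g. a published regional onset dataset) when the
#' raw sighting records are not available.
#'
#' @param rows data frame with columns `taxon`, `region`, `year`,
#'   `onset_doy`.
#' @param path CSV file path.
#' @return `write_start_dates()` returns `path` invisibly;
#'   `read_start_dates()` returns the validated, sorted tibble.
#' @export
write_start_dates <- function(rows, path) {
  rows <- validate_start_dates(rows)
  readr::write_csv(rows, path)
  invisible(path)
}

#' @rdname write_start_dates
#' @export
read_start_dates <- function(path) {
  df <- read_table_csv(path)
  validate_start_dates(df)
}
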