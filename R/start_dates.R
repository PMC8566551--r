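# Onset (start-date) extraction: flagged sightings and phenophase reports
# reduced to one onset day-of-year per taxon, climatic region and year.

#' Regional onset of amphibian migration
#'
#' For each (species, region, year) with at least `min_events` flagged
#' migration observations, the onset is the day of year of the earliest
#' flagged record; region-years below the minimum yield no row (presence-
#' only data: too few migrations means the true start was likely missed).
#' Alpine records are excluded. Ties on the earliest day collapse to one
#' onset but each flagged observation counts separately toward the
#' minimum; set `count_unit = "events"` to count deduplicated migration
#' events instead.
#'
#' @param flagged_records record table from [classify_migrations()]
#'   (columns `species`, `date`, `region`, `migration`).
#' @param min_events minimum flagged observations (or events) required in
#'   a region-year.
#' @param count_unit what the minimum counts: `"records"` (flagged
#'   observations, default) or `"events"` (deduplicated member sets,
#'   requires `events`).
#' @param events event table from [classify_migrations()] when
#'   `count_unit = "events"`.
#' @param quiet suppress the suppressed-region-year log message.
#' @return tibble (`taxon`, `region`, `year`, `onset_doy`), one row per
#'   (taxon, region, year); the number of suppressed region-years is
#'   attached as attribute `suppressed`.
#' @export
amphibian_start_dates <- function(flagged_records, min_events = 4,
                                  count_unit = c("records", "events"),
                                  events = NULL, quiet = FALSE) {
  count_unit <- match.arg(count_unit)
  rec <- tibble::as_tibble(flagged_records)
  stopifnot(all(c("species", "date", "region", "migration") %in% names(rec)))
  rec <- rec[rec$migration & rec$region != "alpine", ]
  empty <- tibble::tibble(taxon = character(), region = character(),
                          year = integer(), onset_doy = integer())
  if (nrow(rec) == 0) {
    attr(empty, "suppressed") <- 0L
    return(empty)
  }
  rec$year <- as.integer(format(as.Date(rec$date), "%Y"))
  rec$doy <- day_of_year(rec$date)
  grp <- rec |>
    dplyr::group_by(taxon = .data$species, .data$region, .data$year) |>
    dplyr::summarise(onset_doy = min(.data$doy), n_flagged = dplyr::n(),
                     .groups = "drop")
  if (count_unit == "events") {
    if (is.null(events)) {
      stop("count_unit = \"events\" requires the events table", call. = FALSE)
    }
    ev <- tibble::as_tibble(events)
    ev$year <- as.integer(format(as.Date(ev$anchor_date), "%Y"))
    ev_n <- ev |>
      dplyr::group_by(taxon = .data$species, .data$region, .data$year) |>
      dplyr::summarise(n_events = dplyr::n(), .groups = "drop")
    grp <- dplyr::left_join(grp, ev_n, by = c("taxon", "region", "year"))
    grp$n_events[is.na(grp$n_events)] <- 0L
    keep <- grp$n_events >= min_events
  } else {
    keep <- grp$n_flagged >= min_events
  }
  suppressed <- sum(!keep)
  if (!quiet && suppressed > 0) {
    message(sprintf(
      "amphibian_start_dates: %d region-year(s) suppressed (< %d %s)",
      suppressed, min_events, count_unit))
  }
  out <- grp[keep, c("taxon", "region", "year", "onset_doy")]
  out <- out[order(out$taxon, out$region, out$year), ]
  attr(out, "suppressed") <- suppressed
  attr(out, "taxon_kind") <- "amphibian"
  out
}

#' Regional onset of plant phenophases
#'
#' One row per (plant species, region, year): the day of year of the
#' earliest report. No event-count minimum applies to plants. Records
#' without a `region` column are banded from their `mat_degc`; alpine
#' reports are excluded.
#'
#' @param phenology_records validated phenology records.
#' @return tibble (`taxon`, `region`, `year`, `onset_doy`).
#' @export
plant_start_dates <- function(phenology_records) {
  rec <- tibble::as_tibble(phenology_records)
  stopifnot(all(c("species", "date") %in% names(rec)))
  if (!"region" %in% names(rec)) rec$region <- assign_region(rec$mat_degc)
  rec <- rec[rec$region != "alpine", ]
  empty <- tibble::tibble(taxon = character(), region = character(),
                          year = integer(), onset_doy = integer())
  if (nrow(rec) == 0) return(empty)
  rec$year <- as.integer(format(as.Date(rec$date), "%Y"))
  rec$doy <- day_of_year(rec$date)
  out <- rec |>
    dplyr::group_by(taxon = .data$species, .data$region, .data$year) |>
    dplyr::summarise(onset_doy = min(.data$doy), .groups = "drop") |>
    dplyr::arrange(.data$taxon, .data$region, .data$year)
  attr(out, "taxon_kind") <- "plant"
  out
}

select_taxon <- function(series, taxon, what) {
  series <- tibble::as_tibble(series)
  present <- unique(series$taxon)
  if (is.null(taxon)) {
    if (length(present) > 1) {
      stop(what, " series holds several taxa (",
           paste(present, collapse = ", "),
           "); name one via the taxon argument", call. = FALSE)
    }
    return(series)
  }
  series[series$taxon == taxon, , drop = FALSE]
}

#' Pair amphibian and plant onset series
#'
#' Inner join on (region, year) of one amphibian and one plant onset
#' series, pooled across regions into a single table per species pair,
#' with a scalar temperature covariate attached: the region's MAT band
#' midpoint (cool 6, moderate 8, warm 10 degC) by default, or the region
#' name itself with `mat_encoding = "categorical"`.
#'
#' @param amphibian,plant onset tibbles (`taxon`, `region`, `year`,
#'   `onset_doy`).
#' @param amphibian_taxon,plant_taxon species to select when a series
#'   holds several taxa.
#' @param regions optional region filter applied before pairing.
#' @param mat_encoding "midpoint" (numeric `mat`) or "categorical"
#'   (factor `region` only).
#' @return tibble (`region`, `year`, `amphibian_doy`, `plant_doy`, `mat`);
#'   zero rows (never an error) when the join is empty.
#' @export
pair_series <- function(amphibian, plant, amphibian_taxon = NULL,
                        plant_taxon = NULL, regions = NULL,
                        mat_encoding = c("midpoint", "categorical")) {
  mat_encoding <- match.arg(mat_encoding)
  a <- select_taxon(amphibian, amphibian_taxon, "amphibian")
  p <- select_taxon(plant, plant_taxon, "plant")
  if (!is.null(regions)) {
    a <- a[a$region %in% regions, ]
    p <- p[p$region %in% regions, ]
  }
  paired <- dplyr::inner_join(
    a[, c("region", "year", "onset_doy")],
    p[, c("region", "year", "onset_doy")],
    by = c("region", "year"), suffix = c("_a", "_p"))
  out <- tibble::tibble(
    region = paired$region,
    year = paired$year,
    amphibian_doy = paired$onset_doy_a,
    plant_doy = paired$onset_doy_p
  )
  if (mat_encoding == "midpoint") {
    out$mat <- if (nrow(out) > 0) region_mat_midpoint(out$region) else numeric(0)
  } else {
    out$region <- factor(out$region, levels = REGION_LEVELS)
  }
  out[order(out$region, out$year), ]
}

#' Build a multi-predictor model table
#'
#' Wide table for regression: one response column named after the
#' amphibian and one column per plant predictor, inner-joined on
#' (region, year), with the MAT midpoint covariate.
#'
#' @param amphibian amphibian onset series.
#' @param plant plant onset series (may hold several taxa).
#' @param response amphibian species (response column).
#' @param predictors character vector of 1-2 plant species.
#' @return tibble (`region`, `year`, `<response>`, `<predictor...>`,
#'   `mat`).
#' @export
model_table <- function(amphibian, plant, response, predictors) {
  a <- select_taxon(amphibian, response, "amphibian")
  out <- tibble::tibble(region = a$region, year = a$year)
  out[[response]] <- a$onset_doy
  for (p in predictors) {
    ps <- select_taxon(plant, p, "plant")
    ps <- tibble::tibble(region = ps$region, year = ps$year, x = ps$onset_doy)
    names(ps)[3] <- p
    out <- dplyr::inner_join(out, ps, by = c("region", "year"))
  }
  out$mat <- if (nrow(out) > 0) region_mat_midpoint(out$region) else numeric(0)
  out[order(out$region, out$year), ]
}
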