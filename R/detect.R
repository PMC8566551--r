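# Migration-event classification.
#
# A sighting is part of a migration when the individuals summed over its
# spatiotemporal neighbourhood reach the quantitative threshold. The
# neighbourhood is a disc of area 1 km^2 centred on the examined record
# (radius sqrt(1e6/pi) ~ 564.19 m) crossed with a two-sided 7-day calendar
# window; a 1 km x 1 km grid-cell mode is available for sensitivity
# analysis. Distances are great-circle (haversine) on WGS84, or Euclidean
# for pre-projected metric coordinates.

#' Radius (m) of a disc with area 1 km^2
#' @export
DISC_RADIUS_1KM2 <- sqrt(1e6 / pi)

#' Assign a climatic region from site mean annual temperature
#'
#' Left-closed MAT bands partitioning the real line: alpine < 5 degC,
#' cool \[5, 7), moderate \[7, 9), warm >= 9. Alpine records are retained
#' here but excluded from onset extraction downstream.
#'
#' @param mat_degc numeric vector of site MAT values (1971-2000 normal).
#' @return character vector of region names.
#' @export
#' @examples
#' assign_region(c(4.9, 5, 6.2, 7, 9.5))
assign_region <- function(mat_degc) {
  if (any(!is.finite(mat_degc))) {
    stop("mat_degC must be finite", call. = FALSE)
  }
  as.character(cut(mat_degc, breaks = c(-Inf, 5, 7, 9, Inf),
                   labels = REGION_LEVELS, right = FALSE))
}

pairwise_distances <- function(lon, lat, distance = "haversine") {
  if (distance == "haversine") {
    geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine)
  } else {
    dx <- outer(lon, lon, "-")
    dy <- outer(lat, lat, "-")
    sqrt(dx^2 + dy^2)
  }
}

#' Spatiotemporal neighbourhood of a sighting record
#'
#' Records of the same species within `radius_m` great-circle metres and
#' `window_days` calendar days (two-sided, inclusive) of the examined
#' record, the record itself included. Membership is symmetric.
#'
#' @param record a one-row data frame (the examined record).
#' @param all_records data frame of candidate records, same species.
#' @param radius_m search radius in metres (> 0).
#' @param window_days two-sided day window.
#' @param distance "haversine" for lon/lat degrees, "euclidean" for metric
#'   x/y.
#' @return the subset of `all_records` in the neighbourhood.
#' @export
neighborhood <- function(record, all_records, radius_m = DISC_RADIUS_1KM2,
                         window_days = 7, distance = c("haversine",
                                                       "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(nrow(record) == 1, radius_m > 0)
  if (length(unique(c(record$species, all_records$species))) > 1) {
    stop("neighborhood is defined within one species", call. = FALSE)
  }
  if (distance == "haversine") {
    d <- geosphere::distHaversine(c(record$lon, record$lat),
                                  cbind(all_records$lon, all_records$lat))
  } else {
    d <- sqrt((all_records$lon - record$lon)^2 +
                (all_records$lat - record$lat)^2)
  }
  dt <- abs(as.numeric(as.Date(all_records$date) - as.Date(record$date)))
  all_records[d <= radius_m & dt <= window_days, , drop = FALSE]
}

#' Classify sightings as migration events
#'
#' Applies the spatial, temporal and quantitative criteria to every
#' record: a record is flagged as part of a migration iff the individuals
#' summed over its neighbourhood (itself included, so a single sighting of
#' >= `min_individuals` always qualifies) reach `min_individuals`.
#' Criteria are applied within species; records of one species never
#' contribute to another's neighbourhood. Each flagged record's
#' neighbourhood is reported as a migration event, deduplicated by member
#' set.
#'
#' @param records validated observation records (columns `record_id`,
#'   `species`, `date`, `lon`, `lat`, `individuals`, `mat_degc`).
#' @param radius_m neighbourhood radius in metres; the default disc has
#'   area 1 km^2.
#' @param window_days two-sided inclusive day window.
#' @param min_individuals quantitative threshold on summed individuals.
#' @param distance "haversine" (lon/lat degrees) or "euclidean" (metric
#'   x/y).
#' @param geometry "disc" (radius around the examined record) or "grid"
#'   (records share a fixed 1 km x 1 km cell; euclidean coordinates only).
#' @param cell_size_m grid-cell edge for `geometry = "grid"`.
#' @param collect_events also assemble the deduplicated event table
#'   (skipping it speeds up flag-only runs on large tables).
#' @return list with `records` (input plus `region` and logical
#'   `migration`) and `events` (tibble: `event_id`, `species`, `region`,
#'   `anchor_date`, `n_members`, `total_individuals`, `member_record_ids`
#'   as a ";"-joined string).
#' @export
classify_migrations <- function(records, radius_m = DISC_RADIUS_1KM2,
                                window_days = 7, min_individuals = 10,
                                distance = c("haversine", "euclidean"),
                                geometry = c("disc", "grid"),
                                cell_size_m = 1000, collect_events = TRUE) {
  distance <- match.arg(distance)
  geometry <- match.arg(geometry)
  if (geometry == "grid" && distance != "euclidean") {
    stop("grid geometry requires pre-projected euclidean coordinates",
         call. = FALSE)
  }
  empty_events <- tibble::tibble(
    event_id = character(), species = character(), region = character(),
    anchor_date = as.Date(character()), n_members = integer(),
    total_individuals = integer(), member_record_ids = character())
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    records$region <- character(0)
    records$migration <- logical(0)
    return(list(records = records, events = empty_events))
  }
  records$region <- assign_region(records$mat_degc)
  records$migration <- FALSE
  records$date <- as.Date(records$date)

  events <- list()
  for (sp in unique(records$species)) {
    idx <- which(records$species == sp)
    sub <- records[idx, ]
    n <- length(idx)
    daynum <- as.numeric(sub$date)
    near_time <- abs(outer(daynum, daynum, "-")) <= window_days
    if (geometry == "disc") {
      d <- pairwise_distances(sub$lon, sub$lat, distance)
      near_space <- d <= radius_m
    } else {
      cx <- floor(sub$lon / cell_size_m)
      cy <- floor(sub$lat / cell_size_m)
      near_space <- outer(cx, cx, "==") & outer(cy, cy, "==")
    }
    adj <- near_space & near_time
    nbr_sum <- as.vector(adj %*% sub$individuals)
    flagged <- nbr_sum >= min_individuals
    records$migration[idx] <- flagged

    if (collect_events && any(flagged)) {
      seen <- character(0)
      for (i in which(flagged)) {
        members <- which(adj[i, ])
        sig <- paste(sort(sub$record_id[members]), collapse = ";")
        if (sig %in% seen) next
        seen <- c(seen, sig)
        anchor <- members[which.min(daynum[members])]
        events[[length(events) + 1]] <- tibble::tibble(
          species = sp,
          region = sub$region[anchor],
          anchor_date = sub$date[anchor],
          n_members = length(members),
          total_individuals = as.integer(sum(sub$individuals[members])),
          member_record_ids = sig
        )
      }
    }
  }
  events <- if (length(events) > 0) dplyr::bind_rows(events) else empty_events
  if (nrow(events) > 0) {
    events <- events[order(events$species, events$anchor_date,
                           events$member_record_ids), ]
    events$event_id <- sprintf("evt-%05d", seq_len(nrow(events)))
    events <- events[, c("event_id", "species", "region", "anchor_date",
                         "n_members", "total_individuals",
                         "member_record_ids")]
  }
  list(records = records, events = events)
}
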