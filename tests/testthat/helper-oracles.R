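# Independent oracles and fixture builders. The brute-force detector is
# deliberately written from first principles (explicit haversine formula,
# per-pair loop) so it shares no code with the package implementation.

oracle_haversine_m <- function(lat1, lon1, lat2, lon2) {
  r <- 6378137 # WGS84 equatorial radius, matching geosphere's default
  p <- pi / 180
  a <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# O(n^2) per-record reimplementation of the migration criteria: for each
# examined record the distances/day gaps to every record are recomputed
# from the raw columns with the explicit formula above.
oracle_flags <- function(records, radius_m = sqrt(1e6 / pi),
                         window_days = 7, min_individuals = 10) {
  n <- nrow(records)
  flags <- logical(n)
  day <- as.numeric(as.Date(records$date))
  for (i in seq_len(n)) {
    same <- records$species == records$species[i]
    in_time <- abs(day - day[i]) <= window_days
    d <- oracle_haversine_m(records$lat[i], records$lon[i],
                            records$lat, records$lon)
    members <- same & in_time & d <= radius_m
    flags[i] <- sum(records$individuals[members]) >= min_individuals
  }
  flags
}

# Random sighting table over a small spatial box; distances span the
# 564 m radius so both flag outcomes occur.
random_record_table <- function(n, species = "common_frog") {
  tibble::tibble(
    record_id = sprintf("r%04d", seq_len(n)),
    species = species,
    date = as.Date("2010-03-01") + sample(0:25, n, replace = TRUE),
    lon = 15 + runif(n, 0, 0.04),
    lat = 48 + runif(n, 0, 0.03),
    individuals = sample(1:8, n, replace = TRUE),
    mat_degc = runif(n, 5.5, 8.5)
  )
}

# Minimal record builder for hand-laid-out detection cases.
make_records <- function(doy, lon, lat, individuals,
                         species = "common_frog", year = 2010,
                         mat = 7.5) {
  n <- length(doy)
  tibble::tibble(
    record_id = sprintf("m%03d", seq_len(n)),
    species = rep_len(species, n),
    date = as.Date(sprintf("%d-01-01", year)) + doy - 1,
    lon = lon, lat = lat,
    individuals = individuals,
    mat_degc = rep_len(mat, n)
  )
}

# Displace a lon/lat point by metres (small-offset approximation, exact
# enough at the <5 km scales used in tests).
offset_m <- function(lon, lat, dx_m = 0, dy_m = 0) {
  lon <- unname(lon); lat <- unname(lat)
  c(lon = lon + dx_m / (111320 * cos(lat * pi / 180)),
    lat = lat + dy_m / 111320)
}

# All permutations of a vector (used by exact-test oracles, n <= 7).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

kendall_s_of <- function(x) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) s <- s + sum(sign(x[(i + 1):n] - x[i]))
  s
}
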