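# Synthetic citizen-science data with known ground truth.
#
# The generator emulates the structure of the Austrian study system: years
# 2000-2018, climatic regions banded by site mean annual temperature (MAT,
# 1971-2000 normal), two explosive-breeding amphibian species whose spring
# migration trails the flowering of an early-spring reference plant by a
# fixed true lag, and seven plant phenophases. One temperature anomaly per
# region-year, shared by plants and amphibians, induces the plant-amphibian
# correlation the regression stage exploits. Observation artefacts are
# modelled explicitly: migration sightings arrive as clustered bursts at a
# site, scattered non-migration singletons (counts <= 3) form background,
# and plant first-report dates are delayed by an exponential observer
# delay, so "first report per region-year" is a biased-late onset
# estimator whose size the tests quantify rather than hide.

sim_region_geometry <- list(
  cool     = list(lon = 14.0, lat = 48.6, mat = c(5, 7)),
  moderate = list(lon = 15.5, lat = 48.1, mat = c(7, 9)),
  warm     = list(lon = 16.4, lat = 48.0, mat = c(9, 11))
)

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the study conditions: 19 years (2000-2018), cool and
#' moderate regions well observed with the warm region sparse (one site),
#' plant base onsets spanning snowdrop (day 35) to silver birch (day 95)
#' in the moderate region with the cool region 9 days later and the warm
#' region 2 days earlier, a shared region-year temperature anomaly
#' (sd 1.5 degC) acting at -4 days per degC on every taxon, and amphibian
#' onsets tied to goat willow flowering: common frog 21 days and common
#' toad 23 days after it, plus Gaussian year noise.
#'
#' @param years integer vector of study years.
#' @param sites_per_region named integer vector, observation sites per
#'   region; regions with 0 sites are absent. Ignored when `n_sites` is
#'   given.
#' @param n_sites optional total site count; regions then drawn from
#'   `region_mix`.
#' @param region_mix named proportions over cool/moderate/warm (must sum
#'   to 1); only used with `n_sites`.
#' @param base_onset_doy named vector of plant base onsets (day of year,
#'   moderate region, zero anomaly).
#' @param region_shift_days named vector: additive onset shift per region
#'   (staggered starts: cool later, warm slightly earlier).
#' @param temp_sensitivity_days_per_degC onset response to the shared
#'   anomaly; must be <= 0 (warmer year, earlier onset).
#' @param anomaly_sd_degC sd of the region-year temperature anomaly.
#' @param true_lag_days named vector per amphibian: days between its
#'   reference plant's true onset and the true migration onset.
#' @param reference_plant named vector per amphibian: the plant whose
#'   onset the migration follows.
#' @param onset_noise_sd_days sd (days) of the amphibian onset around
#'   plant onset + lag; must be >= 0.
#' @param observer_delay_mean_days mean of the exponential delay between a
#'   plant's true onset and its first report at a site; >= 0 (reports can
#'   be late, never early).
#' @param burst_records integer `c(min, max)` sighting records per
#'   migration burst (min >= 4 so the onset-extraction minimum can be met
#'   from one site).
#' @param burst_mean_extra mean of the Poisson part of per-record
#'   individual counts (count = 1 + Poisson); burst totals are topped up
#'   to >= 10 so every burst passes the quantitative criterion.
#' @param background_rate expected scattered non-migration singletons per
#'   region-year (counts 1-3, uniform Jan-May).
#' @param seed integer RNG seed; identical seed + config give identical
#'   tables.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(years = 2000:2018,
                       sites_per_region = c(cool = 4, moderate = 4, warm = 1),
                       n_sites = NULL,
                       region_mix = c(cool = 0.45, moderate = 0.45, warm = 0.10),
                       base_onset_doy = c(snowdrop = 35, common_hazel = 38,
                                          goat_willow = 58, apricot = 74,
                                          european_larch = 88,
                                          horse_chestnut = 92,
                                          silver_birch = 95),
                       region_shift_days = c(cool = 9, moderate = 0, warm = -2),
                       temp_sensitivity_days_per_degC = -4,
                       anomaly_sd_degC = 1.5,
                       true_lag_days = c(common_frog = 21, common_toad = 23),
                       reference_plant = c(common_frog = "goat_willow",
                                           common_toad = "goat_willow"),
                       onset_noise_sd_days = 1,
                       observer_delay_mean_days = 2,
                       burst_records = c(min = 4, max = 8),
                       burst_mean_extra = 3,
                       background_rate = 20,
                       seed = 1L) {
  cfg <- list(
    years = as.integer(years),
    sites_per_region = sites_per_region,
    n_sites = n_sites,
    region_mix = region_mix,
    base_onset_doy = base_onset_doy,
    region_shift_days = region_shift_days,
    temp_sensitivity_days_per_degC = temp_sensitivity_days_per_degC,
    anomaly_sd_degC = anomaly_sd_degC,
    true_lag_days = true_lag_days,
    reference_plant = reference_plant,
    onset_noise_sd_days = onset_noise_sd_days,
    observer_delay_mean_days = observer_delay_mean_days,
    burst_records = burst_records,
    burst_mean_extra = burst_mean_extra,
    background_rate = background_rate,
    seed = as.integer(seed)
  )
  fail <- function(field, why) {
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  if (length(cfg$years) < 1) fail("years", "empty")
  if (!is.null(n_sites)) {
    if (abs(sum(region_mix) - 1) > 1e-8) {
      fail("region_mix", "proportions must sum to 1")
    }
    if (any(region_mix < 0)) fail("region_mix", "negative proportion")
    if (n_sites < 0) fail("n_sites", "negative")
  } else {
    if (is.null(names(sites_per_region)) ||
        !all(names(sites_per_region) %in% c("cool", "moderate", "warm"))) {
      fail("sites_per_region", "must be named with cool/moderate/warm")
    }
    if (any(sites_per_region < 0)) fail("sites_per_region", "negative count")
  }
  missing_plants <- setdiff(names(PLANT_PHASES), names(base_onset_doy))
  if (length(missing_plants) > 0) {
    fail("base_onset_doy", paste("missing", paste(missing_plants,
                                                  collapse = ", ")))
  }
  if (temp_sensitivity_days_per_degC > 0) {
    fail("temp_sensitivity_days_per_degC",
         "must be <= 0 (warmer anomaly, earlier onset)")
  }
  if (anomaly_sd_degC < 0) fail("anomaly_sd_degC", "negative")
  if (onset_noise_sd_days < 0) fail("onset_noise_sd_days", "negative")
  if (observer_delay_mean_days < 0) fail("observer_delay_mean_days",
                                         "negative")
  if (background_rate < 0) fail("background_rate", "negative")
  if (burst_records[["min"]] < 1) fail("burst_records", "min must be >= 1")
  if (burst_records[["max"]] < burst_records[["min"]]) {
    fail("burst_records", "max < min")
  }
  if (burst_mean_extra < 0) fail("burst_mean_extra", "negative")
  if (!all(names(true_lag_days) %in% AMPHIBIAN_SPECIES)) {
    fail("true_lag_days", "names must be amphibian species")
  }
  if (!all(reference_plant %in% names(PLANT_PHASES))) {
    fail("reference_plant", "unknown plant species")
  }
  if (!setequal(names(true_lag_days), names(reference_plant))) {
    fail("reference_plant", "must name the same species as true_lag_days")
  }
  structure(cfg, class = "sim_config")
}

#' Read a generator configuration from a YAML file
#'
#' Scalar and named-vector fields in the YAML override the defaults of
#' [sim_config()].
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's value.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown sim_config field(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  if (!is.null(seed)) raw$seed <- seed
  do.call(sim_config, raw)
}

#' Generate observation sites
#'
#' Sites are placed in distinct spatial clusters at least 5 km apart (so
#' 1 km^2 neighbourhoods never bridge sites) on a longitude grid inside
#' each region's home area, and each site's MAT is drawn uniformly inside
#' its region's band (cool \[5, 7) degC, moderate \[7, 9), warm >= 9).
#'
#' @param config a [sim_config()].
#' @return tibble: `site_id`, `region`, `lon`, `lat`, `mat_degc`.
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (!is.null(config$n_sites)) {
    mix <- config$region_mix[c("cool", "moderate", "warm")]
    draw <- sample(names(mix), config$n_sites, replace = TRUE, prob = mix)
    counts <- c(cool = sum(draw == "cool"), moderate = sum(draw == "moderate"),
                warm = sum(draw == "warm"))
  } else {
    counts <- c(cool = 0, moderate = 0, warm = 0)
    counts[names(config$sites_per_region)] <- config$sites_per_region
  }
  if (sum(counts) == 0) {
    warning("zero sites requested; returning empty site table")
    return(tibble::tibble(site_id = character(), region = character(),
                          lon = numeric(), lat = numeric(),
                          mat_degc = numeric()))
  }
  out <- lapply(names(counts)[counts > 0], function(r) {
    k <- counts[[r]]
    g <- sim_region_geometry[[r]]
    # 0.12 deg lon at ~48 deg lat is ~8.9 km: clusters never bridge.
    tibble::tibble(
      site_id = sprintf("%s-%02d", r, seq_len(k)),
      region = r,
      lon = g$lon + 0.12 * (seq_len(k) - 1),
      lat = g$lat,
      mat_degc = runif(k, g$mat[1], g$mat[2])
    )
  })
  dplyr::bind_rows(out)
}

doy_to_date <- function(year, doy) {
  as.Date(sprintf("%d-01-01", year)) + (pmax(1, round(doy)) - 1)
}

#' Generate sighting and phenology records with ground truth
#'
#' For every site, year and amphibian species a migration burst of 4-8
#' sighting records is laid down starting on the true onset day (offsets
#' 0-6 days, summed individuals topped up to >= 10, so every burst passes
#' the migration criteria by construction). Scattered background
#' singletons with counts <= 3 are strewn uniformly over January-May.
#' Plant records are one first-event report per site-year-species, delayed
#' by an exponential observer delay after the true regional onset. All
#' dates are ISO-8601; the ground truth (true onsets, anomalies, lags) is
#' returned alongside.
#'
#' @param config a [sim_config()].
#' @param sites site table from [generate_sites()]; must be nonempty.
#' @return list of class `sim_data`: `observations`, `phenology`, `sites`,
#'   and `ground_truth` (list with `onsets`, `anomalies`, `lags`).
#' @export
generate_observations <- function(config, sites) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(sites) == 0) stop("sites table is empty", call. = FALSE)
  set.seed(config$seed + 1L)

  regions <- sort(unique(sites$region))
  years <- config$years
  beta <- config$temp_sensitivity_days_per_degC

  anomalies <- expand.grid(region = regions, year = years,
                           stringsAsFactors = FALSE)
  anomalies <- tibble::as_tibble(anomalies[order(anomalies$region,
                                                 anomalies$year), ])
  anomalies$anomaly_degC <- rnorm(nrow(anomalies), 0, config$anomaly_sd_degC)

  # True plant onsets per (plant, region, year).
  plants <- names(PLANT_PHASES)
  plant_truth <- do.call(rbind, lapply(plants, function(p) {
    d <- anomalies
    d$taxon <- p
    d$true_onset_doy <- config$base_onset_doy[[p]] +
      config$region_shift_days[d$region] + beta * d$anomaly_degC
    d
  }))

  # True amphibian onsets: reference plant onset + lag + year noise.
  amphs <- names(config$true_lag_days)
  amph_truth <- do.call(rbind, lapply(amphs, function(a) {
    ref <- config$reference_plant[[a]]
    d <- plant_truth[plant_truth$taxon == ref, ]
    d$taxon <- a
    d$true_onset_doy <- d$true_onset_doy + config$true_lag_days[[a]] +
      rnorm(nrow(d), 0, config$onset_noise_sd_days)
    d
  }))
  truth <- tibble::as_tibble(rbind(plant_truth, amph_truth))
  truth <- truth[, c("taxon", "region", "year", "true_onset_doy",
                     "anomaly_degC")]

  # Amphibian migration bursts: one per site-year-species, first record on
  # the true onset day.
  burst_rows <- list()
  for (si in seq_len(nrow(sites))) {
    s <- sites[si, ]
    for (a in amphs) {
      tr <- truth[truth$taxon == a & truth$region == s$region, ]
      for (yi in seq_len(nrow(tr))) {
        m <- sample(config$burst_records[["min"]]:config$burst_records[["max"]], 1)
        offsets <- c(0, sort(sample(0:6, m - 1, replace = TRUE)))
        counts <- 1 + rpois(m, config$burst_mean_extra)
        if (sum(counts) < 10) counts[1] <- counts[1] + 10 - sum(counts)
        burst_rows[[length(burst_rows) + 1]] <- tibble::tibble(
          species = a,
          date = doy_to_date(tr$year[yi], tr$true_onset_doy[yi]) + offsets,
          lon = s$lon + runif(m, -0.001, 0.001),
          lat = s$lat + runif(m, -0.0007, 0.0007),
          individuals = counts,
          mat_degc = s$mat_degc,
          site_id = s$site_id,
          kind = "burst"
        )
      }
    }
  }

  # Background: scattered non-migration singletons, counts <= 3.
  bg_rows <- list()
  for (r in regions) {
    g <- sim_region_geometry[[r]]
    for (y in years) {
      k <- rpois(1, config$background_rate)
      if (k == 0) next
      bg_rows[[length(bg_rows) + 1]] <- tibble::tibble(
        species = sample(amphs, k, replace = TRUE),
        date = doy_to_date(y, sample(1:151, k, replace = TRUE)),
        lon = g$lon + runif(k, -0.5, 0.5),
        lat = g$lat + runif(k, -0.25, 0.25),
        individuals = sample(1:3, k, replace = TRUE),
        mat_degc = runif(k, g$mat[1], g$mat[2]),
        site_id = NA_character_,
        kind = "background"
      )
    }
  }

  observations <- dplyr::bind_rows(c(burst_rows, bg_rows))
  observations <- observations[order(observations$species, observations$date,
                                     observations$lon), ]
  observations$record_id <- sprintf("obs-%06d", seq_len(nrow(observations)))
  observations <- observations[, c("record_id", "species", "date", "lon",
                                   "lat", "individuals", "mat_degc",
                                   "site_id", "kind")]

  # Plant first-event reports: one per site-year-plant, biased late by an
  # exponential observer delay.
  phe_rows <- list()
  for (si in seq_len(nrow(sites))) {
    s <- sites[si, ]
    for (p in plants) {
      tr <- truth[truth$taxon == p & truth$region == s$region, ]
      delay <- if (config$observer_delay_mean_days > 0) {
        rexp(nrow(tr), 1 / config$observer_delay_mean_days)
      } else {
        rep(0, nrow(tr))
      }
      phe_rows[[length(phe_rows) + 1]] <- tibble::tibble(
        species = p,
        phase = unname(PLANT_PHASES[p]),
        date = doy_to_date(tr$year, tr$true_onset_doy + delay),
        lon = s$lon + runif(nrow(tr), -0.001, 0.001),
        lat = s$lat + runif(nrow(tr), -0.0007, 0.0007),
        mat_degc = s$mat_degc,
        site_id = s$site_id
      )
    }
  }
  phenology <- dplyr::bind_rows(phe_rows)
  phenology <- phenology[order(phenology$species, phenology$date,
                               phenology$lon), ]
  phenology$record_id <- sprintf("phe-%06d", seq_len(nrow(phenology)))
  phenology <- phenology[, c("record_id", "species", "phase", "date", "lon",
                             "lat", "mat_degc", "site_id")]

  lags <- tibble::tibble(
    amphibian = amphs,
    plant = unname(config$reference_plant[amphs]),
    true_lag_days = unname(config$true_lag_days[amphs])
  )

  structure(list(observations = observations, phenology = phenology,
                 sites = sites,
                 ground_truth = list(onsets = truth, anomalies = anomalies,
                                     lags = lags),
                 config = config),
            class = "sim_data")
}

#' Simulate a full dataset in one call
#'
#' @param config a [sim_config()].
#' @return a `sim_data` list (see [generate_observations()]).
#' @export
simulate_dataset <- function(config = sim_config()) {
  generate_observations(config, generate_sites(config))
}

#' Write a simulated dataset to CSV files
#'
#' Writes `observations.csv`, `phenology.csv`, `sites.csv`,
#' `ground_truth.csv` (true onsets with anomalies) and
#' `ground_truth_lags.csv` into `dir`.
#'
#' @param sim a `sim_data` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_sim_data <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    observations = file.path(dir, "observations.csv"),
    phenology = file.path(dir, "phenology.csv"),
    sites = file.path(dir, "sites.csv"),
    ground_truth = file.path(dir, "ground_truth.csv"),
    ground_truth_lags = file.path(dir, "ground_truth_lags.csv")
  )
  readr::write_csv(sim$observations, paths[["observations"]])
  readr::write_csv(sim$phenology, paths[["phenology"]])
  readr::write_csv(sim$sites, paths[["sites"]])
  readr::write_csv(sim$ground_truth$onsets, paths[["ground_truth"]])
  readr::write_csv(sim$ground_truth$lags, paths[["ground_truth_lags"]])
  invisible(paths)
}
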