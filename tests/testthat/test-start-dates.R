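# Flagged records for one region-year, flags/regions attached by hand so
# the onset logic is exercised in isolation from the detector.
flagged_fixture <- function(doys, migration = TRUE, species = "common_frog",
                            region = "moderate", year = 2010) {
  n <- length(doys)
  tibble::tibble(
    record_id = sprintf("f%03d", seq_len(n)),
    species = rep_len(species, n),
    date = as.Date(sprintf("%d-01-01", year)) + doys - 1,
    region = rep_len(region, n),
    migration = rep_len(migration, n)
  )
}

test_that("onset is the earliest flagged day, suppressed below 4 events", {
  sd <- amphibian_start_dates(flagged_fixture(c(70, 72, 75, 80)),
                              quiet = TRUE)
  expect_equal(nrow(sd), 1)
  expect_equal(sd$onset_doy, 70L)
  expect_equal(sd$taxon, "common_frog")

  # only 3 flagged records: region-year suppressed
  sd3 <- amphibian_start_dates(flagged_fixture(c(70, 72, 75)), quiet = TRUE)
  expect_equal(nrow(sd3), 0)
  expect_equal(attr(sd3, "suppressed"), 1L)

  # unflagged records never count
  mix <- dplyr::bind_rows(flagged_fixture(c(70, 72, 75)),
                          flagged_fixture(65, migration = FALSE))
  expect_equal(nrow(amphibian_start_dates(mix, quiet = TRUE)), 0)

  # alpine region-years are excluded outright
  alp <- flagged_fixture(c(70, 72, 75, 80), region = "alpine")
  expect_equal(nrow(amphibian_start_dates(alp, quiet = TRUE)), 0)
})

test_that("ties on the earliest day are one onset but count separately", {
  sd <- amphibian_start_dates(flagged_fixture(c(70, 70, 70, 81)),
                              quiet = TRUE)
  expect_equal(nrow(sd), 1)
  expect_equal(sd$onset_doy, 70L)
})

test_that("the suppression rule is exact over all subsets of a fixture", {
  doys <- c(60L, 64L, 64L, 71L, 80L, 92L)
  for (mask in 0:(2^6 - 1)) {
    pick <- which(bitwAnd(mask, 2^(0:5)) > 0)
    rec <- flagged_fixture(doys[pick])
    got <- amphibian_start_dates(rec, quiet = TRUE)
    if (length(pick) >= 4) {
      expect_equal(got$onset_doy, min(doys[pick]))
    } else {
      expect_equal(nrow(got), 0)
    }
  }
})

test_that("inserting an earlier flagged record lowers or keeps the onset", {
  base <- flagged_fixture(c(70, 72, 75, 80))
  sd0 <- amphibian_start_dates(base, quiet = TRUE)$onset_doy
  earlier <- dplyr::bind_rows(base, flagged_fixture(66))
  sd1 <- amphibian_start_dates(earlier, quiet = TRUE)$onset_doy
  expect_lte(sd1, sd0)
  expect_equal(sd1, 66L)
})

test_that("event counting mode uses deduplicated events for the minimum", {
  rec <- flagged_fixture(c(70, 71, 72, 73))
  one_event <- tibble::tibble(
    event_id = "evt-00001", species = "common_frog", region = "moderate",
    anchor_date = as.Date("2010-03-11"), n_members = 4L,
    total_individuals = 20L, member_record_ids = "f001;f002;f003;f004")
  got <- amphibian_start_dates(rec, count_unit = "events",
                               events = one_event, quiet = TRUE)
  expect_equal(nrow(got), 0)   # 1 event < 4
  got2 <- amphibian_start_dates(rec, count_unit = "events",
                                events = one_event, min_events = 1,
                                quiet = TRUE)
  expect_equal(got2$onset_doy, 70L)
})

test_that("plant onsets take the first report, no minimum, absent years absent", {
  phe <- tibble::tibble(
    record_id = c("p1", "p2", "p3"),
    species = c("goat_willow", "goat_willow", "silver_birch"),
    phase = c("flowering", "flowering", "leaf_unfolding"),
    date = as.Date(c("2005-02-09", "2005-02-24", "2006-04-05")),
    mat_degc = c(7.5, 7.8, 7.5))
  sd <- plant_start_dates(phe)
  gw <- sd[sd$taxon == "goat_willow", ]
  expect_equal(gw$onset_doy, 40L)          # DOY of 2005-02-09
  expect_equal(gw$year, 2005L)
  sb <- sd[sd$taxon == "silver_birch", ]
  expect_equal(nrow(sb), 1)                 # a single report is the onset
  expect_equal(sb$year, 2006L)              # 2005 absent for silver birch
})

test_that("pairing joins on region-year and attaches the MAT midpoint", {
  amph <- tibble::tibble(taxon = "common_frog", region = "cool",
                         year = 2005L, onset_doy = 85L)
  plant <- tibble::tibble(taxon = "goat_willow", region = "cool",
                          year = 2005L, onset_doy = 60L)
  p <- pair_series(amph, plant)
  expect_equal(nrow(p), 1)
  expect_equal(p$amphibian_doy, 85L)
  expect_equal(p$plant_doy, 60L)
  expect_equal(p$mat, 6)

  # mismatched years: empty pairing, not an error
  plant2 <- plant; plant2$year <- 2006L
  expect_equal(nrow(pair_series(amph, plant2)), 0)

  # cardinality bound |pairs| <= min(|A|, |P|)
  set.seed(4)
  amph_many <- tibble::tibble(taxon = "common_frog",
                              region = sample(c("cool", "moderate"), 12,
                                              TRUE),
                              year = rep(2000:2005, 2), onset_doy = 80L)
  amph_many <- amph_many[!duplicated(amph_many[c("region", "year")]), ]
  plant_many <- tibble::tibble(taxon = "goat_willow",
                               region = "cool", year = 2000:2008,
                               onset_doy = 55L)
  p2 <- pair_series(amph_many, plant_many)
  expect_lte(nrow(p2), min(nrow(amph_many), nrow(plant_many)))

  # multi-taxon series require naming the taxon
  both <- dplyr::bind_rows(
    amph, tibble::tibble(taxon = "common_toad", region = "cool",
                         year = 2005L, onset_doy = 88L))
  expect_error(pair_series(both, plant), "several taxa")
  p3 <- pair_series(both, plant, amphibian_taxon = "common_toad")
  expect_equal(p3$amphibian_doy, 88L)
})

test_that("model_table builds wide two-predictor tables", {
  amph <- tibble::tibble(taxon = "common_frog",
                         region = rep(c("cool", "moderate"), each = 3),
                         year = rep(2001:2003, 2),
                         onset_doy = c(86L, 84L, 88L, 77L, 75L, 79L))
  plant <- dplyr::bind_rows(
    tibble::tibble(taxon = "goat_willow", region = rep(c("cool", "moderate"),
                                                       each = 3),
                   year = rep(2001:2003, 2),
                   onset_doy = c(64L, 62L, 66L, 55L, 53L, 57L)),
    tibble::tibble(taxon = "apricot", region = "cool", year = 2001:2003,
                   onset_doy = c(80L, 78L, 82L)))
  tab <- model_table(amph, plant, "common_frog",
                     c("goat_willow", "apricot"))
  expect_equal(nrow(tab), 3)  # apricot exists only in the cool region
  expect_named(tab, c("region", "year", "common_frog", "goat_willow",
                      "apricot", "mat"))
  expect_equal(tab$mat, rep(6, 3))
})
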