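# End-to-end orchestration: simulate (or load) -> detect -> extract ->
# analyze -> model -> predict, as one reproducible run with a manifest.

analyze_series <- function(amph_sd, plant_sd, alpha = 0.05) {
  all_sd <- dplyr::bind_rows(amph_sd, plant_sd)

  normality <- dplyr::bind_rows(lapply(unique(all_sd$taxon), function(tx) {
    v <- all_sd$onset_doy[all_sd$taxon == tx]
    res <- tryCatch(shapiro_wilk(v), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    tibble::tibble(taxon = tx, w = res$statistic, p_value = res$p_value,
                   n = res$n)
  }))

  grp <- unique(all_sd[, c("taxon", "region")])
  trends <- dplyr::bind_rows(lapply(seq_len(nrow(grp)), function(i) {
    s <- all_sd[all_sd$taxon == grp$taxon[i] & all_sd$region == grp$region[i], ]
    if (nrow(s) < 4) return(NULL)
    res <- mann_kendall(s$year, s$onset_doy)
    tibble::tibble(taxon = grp$taxon[i], region = grp$region[i],
                   tau = res$statistic, S = res$extras$S, z = res$extras$z,
                   p_value = res$p_value, p_exact = res$extras$p_exact,
                   n = res$n, trend = res$p_value < alpha)
  }))

  region_pairs <- dplyr::bind_rows(lapply(unique(amph_sd$taxon), function(tx) {
    a <- amph_sd[amph_sd$taxon == tx & amph_sd$region == "moderate", ]
    b <- amph_sd[amph_sd$taxon == tx & amph_sd$region == "cool", ]
    m <- dplyr::inner_join(a, b, by = c("taxon", "year"),
                           suffix = c("_mod", "_cool"))
    if (nrow(m) < 2) return(NULL)
    res <- paired_region_test(m$onset_doy_mod, m$onset_doy_cool)
    tibble::tibble(taxon = tx, comparison = "moderate - cool",
                   mean_difference = res$extras$mean_difference,
                   t = res$statistic, p_value = res$p_value, n = res$n)
  }))

  combos <- expand.grid(amphibian = unique(amph_sd$taxon),
                        plant = unique(plant_sd$taxon),
                        stringsAsFactors = FALSE)
  correlations <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    paired <- pair_series(amph_sd, plant_sd,
                          amphibian_taxon = combos$amphibian[i],
                          plant_taxon = combos$plant[i])
    if (nrow(paired) < 3) return(NULL)
    res <- tryCatch(pearson_correlation(paired$plant_doy,
                                        paired$amphibian_doy),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    tibble::tibble(amphibian = combos$amphibian[i], plant = combos$plant[i],
                   r = res$statistic, p_value = res$p_value, n = res$n,
                   significant = res$p_value < alpha)
  }))

  list(normality = normality, trends = trends,
       region_comparison = region_pairs, correlations = correlations)
}

fit_candidate_models <- function(amph_sd, plant_sd, correlations,
                                 alpha = 0.05, include_mat = TRUE,
                                 seed = MM_SEED_DEFAULT) {
  mean_onset <- dplyr::bind_rows(amph_sd, plant_sd) |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(mean_doy = mean(.data$onset_doy), .groups = "drop")
  mean_of <- function(tx) mean_onset$mean_doy[mean_onset$taxon == tx]

  rows <- list()
  fits <- list()
  for (a in unique(amph_sd$taxon)) {
    cors <- correlations[correlations$amphibian == a, ]
    # Suitable predictors: phase starts before the migration on average
    # and correlates significantly with it.
    suitable <- cors$plant[cors$significant &
                             vapply(cors$plant, mean_of, numeric(1)) <
                             mean_of(a)]
    for (p in suitable) {
      tab <- model_table(amph_sd, plant_sd, response = a, predictors = p)
      spec <- model_spec(a, p, include_mat = include_mat)
      cmp <- tryCatch(compare_to_null(spec, tab, seed = seed),
                      error = function(e) NULL)
      if (is.null(cmp)) next
      fit <- cmp$fit
      slope_row <- fit$coef_table[fit$coef_table$term == p |
                                    fit$coef_table$term == "plant_doy", ]
      key <- paste(a, p, sep = "~")
      fits[[key]] <- fit
      rows[[key]] <- tibble::tibble(
        response = a, predictor = p, n = fit$n,
        intercept = unname(fit$coefficients[1]),
        slope = slope_row$estimate, slope_p = slope_row$p_value,
        scale = fit$scale, adj_r2 = fit$adj_r2,
        rmse_loocv = fit$rmse_loocv,
        null_rmse_loocv = cmp$table$rmse_loocv[2],
        rmse_improvement = cmp$rmse_improvement)
    }
  }
  list(table = dplyr::bind_rows(rows), fits = fits)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> detect -> extract -> analyze -> model ->
#' predict under one config and seed. When `start_dates` (a table or CSV
#' path of onset rows, e.g. an externally published onset dataset) is
#' supplied, the simulation and detection stages are skipped and the
#' analysis enters mid-pipeline. The report ends with a lag lookup table
#' (plant day 50-90 in steps of 5) for each amphibian's best model by
#' LOOCV RMSE.
#'
#' @param config a [sim_config()] driving the synthetic stages.
#' @param start_dates optional onset table (or CSV path) with columns
#'   `taxon`, `region`, `year`, `onset_doy`; bypasses simulate/detect.
#' @param out_dir optional directory; when given, CSV tables and a JSON
#'   report are written and digested into the manifest.
#' @param radius_m,window_days,min_individuals detection criteria, see
#'   [classify_migrations()].
#' @param min_events onset suppression minimum, see
#'   [amphibian_start_dates()].
#' @param include_mat include the MAT covariate in models.
#' @param alpha significance level used throughout the report.
#' @return list of class `pipeline_report`: `start_dates`, `analysis`
#'   (normality/trends/region comparison/correlations), `models`,
#'   `fits`, `best_models`, `lag_tables`, and `manifest` (config, seed,
#'   stage row counts, versions, file digests when written).
#' @export
run_all <- function(config = sim_config(), start_dates = NULL,
                    out_dir = NULL, radius_m = DISC_RADIUS_1KM2,
                    window_days = 7, min_individuals = 10, min_events = 4,
                    include_mat = TRUE, alpha = 0.05) {
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    versions = list(r = R.version.string,
                    amphipheno = as.character(utils::packageVersion("amphipheno"))),
    stages = list()
  )
  ground_truth <- NULL
  detection <- NULL

  if (is.null(start_dates)) {
    sites <- generate_sites(config)
    sim <- generate_observations(config, sites)
    ground_truth <- sim$ground_truth
    if (nrow(sim$observations) == 0) {
      warning("no observations generated; returning empty report")
    }
    detection <- classify_migrations(sim$observations, radius_m = radius_m,
                                     window_days = window_days,
                                     min_individuals = min_individuals)
    amph_sd <- amphibian_start_dates(detection$records,
                                     min_events = min_events, quiet = TRUE)
    phe <- sim$phenology
    plant_sd <- plant_start_dates(phe)
    manifest$stages$simulate <- list(n_sites = nrow(sites),
                                     n_observations = nrow(sim$observations),
                                     n_phenology = nrow(phe))
    manifest$stages$detect <- list(
      n_flagged = sum(detection$records$migration),
      n_events = nrow(detection$events))
  } else {
    if (is.character(start_dates)) start_dates <- read_start_dates(start_dates)
    start_dates <- validate_start_dates(start_dates)
    amph_sd <- start_dates[start_dates$taxon %in% AMPHIBIAN_SPECIES, ]
    plant_sd <- start_dates[!start_dates$taxon %in% AMPHIBIAN_SPECIES, ]
    manifest$stages$input <- list(n_start_dates = nrow(start_dates),
                                  detection_skipped = TRUE)
  }
  manifest$stages$extract <- list(n_amphibian_rows = nrow(amph_sd),
                                  n_plant_rows = nrow(plant_sd),
                                  suppressed = attr(amph_sd, "suppressed") %||% NA)

  if (nrow(amph_sd) == 0 || nrow(plant_sd) == 0) {
    warning("empty onset series; analysis and modelling skipped")
    report <- structure(list(
      start_dates = dplyr::bind_rows(amph_sd, plant_sd),
      analysis = NULL, models = tibble::tibble(), fits = list(),
      best_models = tibble::tibble(), lag_tables = list(),
      detection = detection, ground_truth = ground_truth,
      manifest = manifest), class = "pipeline_report")
    return(report)
  }

  analysis <- analyze_series(amph_sd, plant_sd, alpha = alpha)
  mods <- fit_candidate_models(amph_sd, plant_sd, analysis$correlations,
                               alpha = alpha, include_mat = include_mat)

  best <- tibble::tibble()
  lag_tables <- list()
  if (nrow(mods$table) > 0) {
    best <- mods$table |>
      dplyr::group_by(.data$response) |>
      dplyr::filter(.data$rmse_loocv == min(.data$rmse_loocv)) |>
      dplyr::ungroup()
    for (i in seq_len(nrow(best))) {
      key <- paste(best$response[i], best$predictor[i], sep = "~")
      lag_tables[[key]] <- lag_table(mods$fits[[key]])
    }
  }

  report <- structure(list(
    start_dates = dplyr::bind_rows(amph_sd, plant_sd),
    analysis = analysis, models = mods$table, fits = mods$fits,
    best_models = best, lag_tables = lag_tables,
    detection = detection, ground_truth = ground_truth,
    manifest = manifest), class = "pipeline_report")

  if (!is.null(out_dir)) {
    report$manifest$files <- write_report(report, out_dir)
  }
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    paths[[name]] <<- p
  }
  wr(report$start_dates, "start_dates.csv")
  if (!is.null(report$detection)) {
    wr(report$detection$records, "flagged_observations.csv")
    wr(report$detection$events, "migration_events.csv")
  }
  if (!is.null(report$analysis)) {
    wr(report$analysis$correlations, "correlations.csv")
    if (nrow(report$analysis$trends) > 0) wr(report$analysis$trends,
                                             "trends.csv")
  }
  if (nrow(report$models) > 0) wr(report$models, "models.csv")
  if (length(report$lag_tables) > 0) {
    lt <- dplyr::bind_rows(report$lag_tables, .id = "model")
    wr(lt, "lag_tables.csv")
  }
  json_path <- file.path(out_dir, "report.json")
  json_body <- list(
    manifest = report$manifest[c("seed", "versions", "stages")],
    models = report$models,
    best_models = report$best_models,
    lag_tables = lapply(report$lag_tables, function(t) {
      t[, c("plant_doy", "lag_days", "ci95_low", "ci95_high")]
    })
  )
  jsonlite::write_json(json_body, json_path, auto_unbox = TRUE, digits = 8,
                       pretty = TRUE)
  paths[["report.json"]] <- json_path
  digests <- tools::md5sum(unlist(paths))
  names(digests) <- names(paths)
  as.list(digests)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("amphipheno pipeline report\n")
  st <- x$manifest$stages
  if (!is.null(st$simulate)) {
    cat(sprintf("  simulated: %d observation(s), %d phenology report(s)\n",
                st$simulate$n_observations, st$simulate$n_phenology))
  }
  if (!is.null(st$detect)) {
    cat(sprintf("  flagged as migration: %d record(s), %d event(s)\n",
                st$detect$n_flagged, st$detect$n_events))
  }
  cat(sprintf("  onset rows: %d amphibian, %d plant\n",
              st$extract$n_amphibian_rows, st$extract$n_plant_rows))
  if (nrow(x$models) > 0) {
    cat("  models (LOOCV RMSE, days):\n")
    print(as.data.frame(x$models[, c("response", "predictor", "slope",
                                     "rmse_loocv", "null_rmse_loocv",
                                     "adj_r2")]),
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
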