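# Internal helpers and domain constants.

#' Amphibian species handled by the pipeline
#' @export
AMPHIBIAN_SPECIES <- c("common_frog", "common_toad")

#' Plant species and their observable spring phenophase
#'
#' Flowering for the early species (snowdrop, common hazel, goat willow,
#' apricot), leaf unfolding for the trees leafing later (European larch,
#' horse chestnut, silver birch).
#' @export
PLANT_PHASES <- c(
  snowdrop       = "flowering",
  common_hazel   = "flowering",
  goat_willow    = "flowering",
  apricot        = "flowering",
  european_larch = "leaf_unfolding",
  horse_chestnut = "leaf_unfolding",
  silver_birch   = "leaf_unfolding"
)

#' Climatic region names, coldest first
#' @export
REGION_LEVELS <- c("alpine", "cool", "moderate", "warm")

# MAT band midpoints used as the scalar temperature covariate for
# region-level rows (the warm band is open above; 10 degC is the midpoint
# of the 9-11 degC span that holds nearly all non-urban warm-region sites).
REGION_MAT_MIDPOINT <- c(cool = 6, moderate = 8, warm = 10)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' MAT band midpoint for a climatic region
#'
#' @param region character vector of region names ("cool", "moderate",
#'   "warm").
#' @return numeric vector of band midpoints in degrees Celsius.
#' @export
region_mat_midpoint <- function(region) {
  bad <- setdiff(unique(region), names(REGION_MAT_MIDPOINT))
  if (length(bad) > 0) {
    stop("no MAT midpoint for region(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(REGION_MAT_MIDPOINT[region])
}
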