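#' Built-in taxon registry for coastwide YOY rockfish surveys
#'
#' Returns the registry of *Sebastes* taxa used throughout the package: the
#' 20 species-level taxa retained by the assemblage analysis plus the pooled
#' unidentified/mixed categories. Each species carries its fishery group
#' (`"target"` for commercially or recreationally important taxa, `"forage"`
#' for small-bodied food-web taxa) and an asymptotic length `linf_cm` from
#' the von Bertalanffy growth curve, used to weight catches by adult body
#' size. The values here are a synthetic stand-in registry assembled from
#' commonly cited growth parameters; they drive the simulator and the
#' group-aggregation operations, not any species-level stock advice.
#'
#' @return A `data.frame` with columns `taxon_code`, `common_name`,
#'   `scientific_name`, `group` (one of `"target"`, `"forage"`, `"other"`)
#'   and `linf_cm` (NA for non-species-level taxa).
#' @export
#' @examples
#' tx <- default_taxon_table()
#' table(tx$group)
default_taxon_table <- function() {
  df <- data.frame(
    taxon_code = c("SBY", "SQSP", "STRP", "HFBN", "PYGMY", "SPKL",
                   "BCAC", "CHIL", "WID", "CAN", "YLTL", "BLUE", "BRWN",
                   "BLCK", "COW", "DKBL", "SPLT", "BANK", "BLGL", "OLV",
                   "RFUNID", "RFMIX"),
    common_name = c("shortbelly", "squarespot", "stripetail", "halfbanded",
                    "pygmy", "speckled", "bocaccio", "chilipepper", "widow",
                    "canary", "yellowtail", "blue/deacon", "brown", "black",
                    "cowcod", "darkblotched", "splitnose", "bank",
                    "blackgill", "olive", "unidentified rockfish",
                    "mixed juvenile rockfish"),
    scientific_name = c("Sebastes jordani", "Sebastes hopkinsi",
                        "Sebastes saxicola", "Sebastes semicinctus",
                        "Sebastes wilsoni", "Sebastes ovalis",
                        "Sebastes paucispinis", "Sebastes goodei",
                        "Sebastes entomelas", "Sebastes pinniger",
                        "Sebastes flavidus", "Sebastes mystinus/diaconus",
                        "Sebastes auriculatus", "Sebastes melanops",
                        "Sebastes levis", "Sebastes crameri",
                        "Sebastes diploproa", "Sebastes rufus",
                        "Sebastes melanostomus", "Sebastes serranoides",
                        "Sebastes spp.", "Sebastes spp."),
    group = c("forage", "forage", "forage", "forage", "forage", "forage",
              "target", "target", "target", "target", "target", "target",
              "target", "target", "target", "target", "target", "target",
              "target", "target", "other", "other"),
    linf_cm = c(32, 29, 41, 25, 23, 37,
                91, 59, 54, 66, 66, 53, 56,
                60, 94, 58, 46, 55, 77, 61,
                NA, NA),
    stringsAsFactors = FALSE
  )
  df
}

#' Geographic region registry
#'
#' The twelve coastwide survey regions, ordered south to north, with their
#' approximate central latitudes and latitude bounds, plus the
#' `north_of_columbia` catch-all that is excluded from analysis. Bounds are
#' used to validate that haul latitude is consistent with the stated region.
#'
#' @return A `data.frame` with columns `region`, `lat_center`, `lat_min`,
#'   `lat_max` and `analysis` (FALSE for `north_of_columbia`).
#' @export
region_table <- function() {
  data.frame(
    region = c("SCI", "NCI", "Conception", "Monterey", "Farallones",
               "Reyes", "Navarro", "Mendocino", "Blanco", "Heceta",
               "Newport", "Columbia", "north_of_columbia"),
    lat_center = c(33.0, 34.0, 35.0, 36.7, 37.7, 38.2, 39.2, 40.3,
                   42.8, 44.0, 44.8, 46.2, 47.3),
    lat_min = c(32.0, 33.5, 34.3, 35.8, 37.2, 37.9, 38.6, 39.7, 41.8,
                43.4, 44.4, 45.4, 46.9),
    lat_max = c(33.5, 34.3, 35.8, 37.2, 37.9, 38.6, 39.7, 41.8, 43.4,
                44.4, 45.4, 46.9, 49.0),
    analysis = c(rep(TRUE, 12), FALSE),
    stringsAsFactors = FALSE
  )
}

#' Analysis region names, ordered south to north
#' @return Character vector of the 12 analysis regions.
#' @export
analysis_regions <- function() {
  rt <- region_table()
  rt$region[rt$analysis]
}
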