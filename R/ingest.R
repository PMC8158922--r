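#' QC configuration for haul ingestion and climatology selection
#'
#' @param climatology_years Years with (near) full coastwide coverage that
#'   define the spatial climatology; default 2004--2009 and 2013--2019.
#' @param min_station_years Minimum number of distinct climatology years a
#'   station must have been sampled to qualify for the climatology (default 3).
#' @param pseudo_station_radius_km Distance rule for attaching hauls to
#'   stations and for clustering orphan hauls into pseudo-stations
#'   (default 10 km).
#' @param min_cluster_hauls Minimum member hauls for a cluster of orphan
#'   hauls to become a pseudo-station (default 8).
#' @param exclude_regions Regions dropped from all analyses (default
#'   `"north_of_columbia"`).
#' @param blank_is_zero If TRUE, blank count cells in the CSV are read as
#'   zero; if FALSE a blank count is an error.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(climatology_years = c(2004:2009, 2013:2019),
                      min_station_years = 3,
                      pseudo_station_radius_km = 10,
                      min_cluster_hauls = 8,
                      exclude_regions = "north_of_columbia",
                      blank_is_zero = TRUE) {
  stopifnot(min_station_years >= 1, pseudo_station_radius_km > 0,
            length(climatology_years) > 0)
  structure(list(climatology_years = climatology_years,
                 min_station_years = min_station_years,
                 pseudo_station_radius_km = pseudo_station_radius_km,
                 min_cluster_hauls = min_cluster_hauls,
                 exclude_regions = exclude_regions,
                 blank_is_zero = blank_is_zero),
            class = "qc_config")
}

# columns of a haul table that hold per-taxon counts
#' Names of the per-taxon count columns of a haul table
#' @param hauls A haul table as returned by [read_haul_table()].
#' @return Character vector of taxon column names.
#' @export
taxon_columns <- function(hauls) {
  meta <- c("haul_id", "survey", "year", "date", "latitude", "longitude",
            "bottom_depth", "station", "region", "julian_day", "depth_bin",
            "period_bin")
  setdiff(names(hauls), meta)
}

#' Read a haul-level catch table
#'
#' Reads the wide-format haul CSV (one row per haul; metadata columns plus
#' one nonnegative integer count column per taxon, YOY >= 20 mm only) and
#' validates coordinates, years and region/latitude consistency. Taxon
#' columns not present in the registry are kept but flagged as
#' unidentified (`"other"` group) downstream.
#'
#' @param path Path to the CSV file.
#' @param taxa Taxon registry, see [default_taxon_table()].
#' @param cfg A [qc_config()].
#' @return A `data.frame` haul table; taxon columns are all columns not in
#'   the metadata set (see [taxon_columns()]).
#' @export
read_haul_table <- function(path, taxa = default_taxon_table(),
                            cfg = qc_config()) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("haul_id", "year", "date", "latitude", "longitude", "region")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("haul table is missing required columns: ",
         paste(miss, collapse = ", "))
  if (!"survey" %in% names(df)) df$survey <- "RREAS"
  if (!"station" %in% names(df)) df$station <- NA_character_
  if (!"bottom_depth" %in% names(df)) df$bottom_depth <- NA_real_
  if (anyDuplicated(df$haul_id))
    stop("duplicate haul_id values: ",
         paste(head(df$haul_id[duplicated(df$haul_id)]), collapse = ", "))
  bad_date <- which(is.na(as.Date(df$date, optional = TRUE)))
  if (length(bad_date))
    stop("malformed date in row(s): ", paste(head(bad_date), collapse = ", "))
  df$date <- as.Date(df$date)
  lat <- suppressWarnings(as.numeric(df$latitude))
  lon <- suppressWarnings(as.numeric(df$longitude))
  bad <- which(is.na(lat) | is.na(lon) | lat < 30 | lat > 49)
  if (length(bad))
    stop("latitude/longitude out of range [30, 49] in row(s): ",
         paste(head(bad), collapse = ", "))
  df$latitude <- lat
  df$longitude <- lon
  bad_yr <- which(df$year < 2001 | df$year > 2019 | is.na(df$year))
  if (length(bad_yr))
    stop("year outside 2001-2019 in row(s): ",
         paste(head(bad_yr), collapse = ", "))
  tc <- taxon_columns(df)
  if (!length(tc)) stop("no taxon count columns found")
  for (j in tc) {
    v <- df[[j]]
    if (is.character(v)) {
      v[!nzchar(trimws(v))] <- NA
      v <- suppressWarnings(as.numeric(v))
    }
    if (anyNA(v)) {
      if (!cfg$blank_is_zero)
        stop("blank count cells in column ", j,
             " and blank_is_zero = FALSE")
      v[is.na(v)] <- 0
    }
    if (any(v < 0)) stop("negative counts in column ", j)
    df[[j]] <- v
  }
  df
}

#' Apply haul-level exclusion rules
#'
#' Removes hauls in the excluded regions (by default the sparsely sampled
#' area north of the Columbia region) and returns an exclusion ledger so the
#' kept and excluded sets always partition the input.
#'
#' @param hauls A haul table.
#' @param cfg A [qc_config()].
#' @return A list with `kept` (haul table) and `ledger` (named integer
#'   vector of counts per exclusion reason, plus `kept`).
#' @export
filter_analysis_hauls <- function(hauls, cfg = qc_config()) {
  drop <- hauls$region %in% cfg$exclude_regions
  ledger <- c(north_of_columbia = sum(drop), kept = sum(!drop))
  kept <- hauls[!drop, , drop = FALSE]
  if (!nrow(kept)) warning("no hauls remain after exclusion")
  list(kept = kept, ledger = ledger)
}

#' Attach hauls to stations and create pseudo-stations
#'
#' Hauls lacking a station id are attached to the nearest existing station
#' if within the great-circle radius (default 10 km). Remaining orphan
#' hauls are clustered by single-linkage agglomeration cut at the radius;
#' clusters with at least `min_cluster_hauls` members become pseudo-stations
#' located at the spherical centroid of their member hauls, while smaller
#' clusters keep `station = NA` (excluded from station-based analyses).
#' The operation is idempotent: re-running it on its own output changes
#' nothing.
#'
#' @param hauls Haul table; rows with `station` NA must carry coordinates.
#' @param stations Optional `data.frame` with `station`, `latitude`,
#'   `longitude`; if NULL, station positions are taken as centroids of the
#'   hauls already carrying each station id.
#' @param cfg A [qc_config()].
#' @return List with `hauls` (station column filled where possible) and
#'   `stations` (registry including pseudo-stations, flagged `is_pseudo`).
#' @export
assign_pseudo_stations <- function(hauls, stations = NULL,
                                   cfg = qc_config()) {
  if (anyNA(hauls$latitude) || anyNA(hauls$longitude))
    stop("hauls without coordinates cannot be assigned to stations")
  if (is.null(stations)) {
    known <- hauls[!is.na(hauls$station), , drop = FALSE]
    if (nrow(known)) {
      sp <- lapply(split(known, known$station), function(g)
        spherical_centroid(g$latitude, g$longitude))
      stations <- data.frame(station = names(sp),
                             latitude = vapply(sp, `[[`, 0, "lat"),
                             longitude = vapply(sp, `[[`, 0, "lon"),
                             is_pseudo = FALSE, stringsAsFactors = FALSE)
    } else {
      stations <- data.frame(station = character(), latitude = numeric(),
                             longitude = numeric(), is_pseudo = logical())
    }
  } else if (is.null(stations$is_pseudo)) {
    stations$is_pseudo <- FALSE
  }
  rad <- cfg$pseudo_station_radius_km
  orphan <- which(is.na(hauls$station))
  # nearest-station attachment within the radius
  if (length(orphan) && nrow(stations)) {
    for (i in orphan) {
      d <- haversine_km(hauls$latitude[i], hauls$longitude[i],
                        stations$latitude, stations$longitude)
      j <- which.min(d)
      if (length(j) && d[j] <= rad) hauls$station[i] <- stations$station[j]
    }
    orphan <- which(is.na(hauls$station))
  }
  # single-linkage clustering of the remaining orphans
  if (length(orphan) > 0) {
    if (length(orphan) == 1) {
      cl <- 1L
    } else {
      dm <- haversine_matrix(hauls$latitude[orphan], hauls$longitude[orphan])
      cl <- cutree(hclust(as.dist(dm), method = "single"), h = rad)
    }
    k <- 0L
    for (g in unique(cl)) {
      idx <- orphan[cl == g]
      if (length(idx) >= cfg$min_cluster_hauls ||
          (cfg$min_cluster_hauls <= 1 && length(idx) >= 1)) {
        k <- k + 1L
        cen <- spherical_centroid(hauls$latitude[idx], hauls$longitude[idx])
        id <- sprintf("PSEUDO_%02d", sum(stations$is_pseudo) + 1L)
        stations <- rbind(stations,
                          data.frame(station = id, latitude = cen[["lat"]],
                                     longitude = cen[["lon"]],
                                     is_pseudo = TRUE,
                                     stringsAsFactors = FALSE))
        hauls$station[idx] <- id
      }
    }
  }
  list(hauls = hauls, stations = stations)
}

#' Select climatology-qualified stations
#'
#' A station qualifies for the spatial climatology when it was sampled in at
#' least `min_station_years` distinct climatology years.
#'
#' @param hauls Station-assigned haul table.
#' @param cfg A [qc_config()].
#' @return List with `stations` (character vector of qualifying station
#'   ids), `n_station_years` (count of distinct station-by-year pairs among
#'   them within the climatology years) and `years_per_station`.
#' @export
select_climatology_stations <- function(hauls, cfg = qc_config()) {
  h <- hauls[!is.na(hauls$station) &
               hauls$year %in% cfg$climatology_years, , drop = FALSE]
  if (!nrow(h))
    return(list(stations = character(), n_station_years = 0L,
                years_per_station = integer()))
  yrs <- tapply(h$year, h$station, function(y) length(unique(y)))
  keep <- names(yrs)[yrs >= cfg$min_station_years]
  sy <- unique(h[h$station %in% keep, c("station", "year")])
  list(stations = keep, n_station_years = nrow(sy),
       years_per_station = yrs)
}

#' Catch and effort summary
#'
#' Totals over the catch columns, per-taxon fractions (identified taxa
#' only), haul counts per survey, and the region-by-year haul count table.
#'
#' @param hauls QC-filtered haul table.
#' @param taxa Taxon registry.
#' @return List with `total_catch`, `fractions` (per-taxon fraction of the
#'   identified catch), `fractions_all` (of the full catch), `hauls_per_survey`,
#'   `hauls_per_year`, and `region_year_hauls` (matrix).
#' @export
catch_summary <- function(hauls, taxa = default_taxon_table()) {
  tc <- taxon_columns(hauls)
  totals <- vapply(hauls[tc], sum, 0)
  total_catch <- sum(totals)
  unident <- taxa$taxon_code[taxa$group == "other"]
  ident <- setdiff(tc, unident)
  frac <- totals[ident] / sum(totals[ident])
  regions <- intersect(region_table()$region, unique(hauls$region))
  ry <- table(factor(hauls$region, levels = regions), hauls$year)
  list(total_catch = total_catch,
       fractions = frac,
       fractions_all = totals / total_catch,
       hauls_per_survey = table(hauls$survey),
       hauls_per_year = table(hauls$year),
       region_year_hauls = unclass(ry))
}
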