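#' Log catch-per-unit-effort transform
#'
#' Catches span orders of magnitude, so all catch-rate analyses work on
#' `ln(catch + 1)`.
#'
#' @param count Nonnegative catch count(s).
#' @return `log(count + 1)`.
#' @export
#' @examples
#' log_cpue(0)    # 0
#' log_cpue(423)  # ~6.05
log_cpue <- function(count) {
  if (any(count < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  log(count + 1)
}

#' Per-haul total catch within a taxon scope
#' @param hauls Haul table.
#' @param taxon_scope Optional character vector of taxon codes; default all
#'   taxon columns.
#' @return Numeric vector of per-haul totals.
#' @export
scope_catch <- function(hauls, taxon_scope = NULL) {
  tc <- taxon_columns(hauls)
  if (!is.null(taxon_scope)) {
    missing_tax <- setdiff(taxon_scope, tc)
    if (length(missing_tax))
      stop("taxa not present in haul table: ",
           paste(missing_tax, collapse = ", "))
    tc <- taxon_scope
  }
  if (length(tc) == 1) hauls[[tc]] else rowSums(hauls[tc])
}

#' Station-by-year mean log-CPUE
#'
#' Transform first, then average: the per-haul `ln(catch + 1)` values are
#' averaged within each station-year combination.
#'
#' @param hauls Station-assigned haul table.
#' @param taxon_scope Optional character vector of taxon codes; default all.
#' @return A `data.frame` with `station`, `year`, `mean_log_cpue`, `n_hauls`.
#' @export
station_year_mean <- function(hauls, taxon_scope = NULL) {
  h <- hauls[!is.na(hauls$station), , drop = FALSE]
  v <- log_cpue(scope_catch(h, taxon_scope))
  key <- interaction(h$station, h$year, drop = TRUE)
  agg <- aggregate(list(mean_log_cpue = v),
                   by = list(station = h$station, year = h$year), FUN = mean)
  agg$n_hauls <- as.integer(table(key)[paste(agg$station, agg$year,
                                             sep = ".")])
  agg[order(agg$station, agg$year), , drop = FALSE]
}

#' Station climatology and per-year z-score anomalies
#'
#' The climatology is the mean of the station-year mean log-CPUE over the
#' sampled climatology years; the anomaly for a station-year is its z-score
#' against that station's own mean and standard deviation (denominator
#' n - 1). Stations sampled in a single year get `NA` anomalies; stations
#' with zero SD get anomaly 0 and are flagged.
#'
#' @param station_year Output of [station_year_mean()], restricted (or
#'   restrictable via `cfg`) to climatology-qualified stations.
#' @param cfg A [qc_config()]; rows outside `cfg$climatology_years` are
#'   dropped.
#' @return A list of class `climatology_field`: `stations` (data.frame with
#'   `station`, `climatology`, `sd`, `n_years`, `zero_sd` flag) and
#'   `anomalies` (data.frame with `station`, `year`, `value`, `z`).
#' @export
climatology_and_anomalies <- function(station_year, cfg = qc_config()) {
  sy <- station_year[station_year$year %in% cfg$climatology_years, ,
                     drop = FALSE]
  sp <- split(sy, sy$station)
  st <- data.frame(
    station = names(sp),
    climatology = vapply(sp, function(g) mean(g$mean_log_cpue), 0),
    sd = vapply(sp, function(g)
      if (nrow(g) >= 2) sd(g$mean_log_cpue) else NA_real_, 0),
    n_years = vapply(sp, nrow, 0L),
    stringsAsFactors = FALSE
  )
  st$zero_sd <- !is.na(st$sd) & st$sd == 0
  z <- mapply(function(g, m, s, zs) {
    if (is.na(s)) rep(NA_real_, nrow(g))
    else if (zs) rep(0, nrow(g))
    else (g$mean_log_cpue - m) / s
  }, sp, st$climatology, st$sd, st$zero_sd, SIMPLIFY = FALSE)
  anom <- do.call(rbind, mapply(function(g, zz) {
    data.frame(station = g$station, year = g$year,
               value = g$mean_log_cpue, z = zz,
               stringsAsFactors = FALSE)
  }, sp, z, SIMPLIFY = FALSE))
  rownames(anom) <- NULL
  structure(list(stations = st, anomalies = anom),
            class = "climatology_field")
}

#' Frequency of occurrence of positive tows by region
#'
#' @param hauls Haul table (restrict to climatology years upstream for the
#'   tabled frequencies).
#' @param taxon_scope Optional taxon codes; default all rockfish.
#' @param regions Region ordering for the output (default the 12 analysis
#'   regions present in the data).
#' @return Named numeric vector: fraction of hauls with positive catch in
#'   scope, per region; `NA` for regions with no hauls.
#' @export
occurrence_frequency <- function(hauls, taxon_scope = NULL,
                                 regions = NULL) {
  pos <- scope_catch(hauls, taxon_scope) > 0
  if (is.null(regions))
    regions <- intersect(region_table()$region, unique(hauls$region))
  out <- vapply(regions, function(r) {
    idx <- hauls$region == r
    if (!any(idx)) NA_real_ else mean(pos[idx])
  }, 0)
  names(out) <- regions
  out
}

#' Group-aggregated per-haul CPUE
#'
#' Pools species-level catches into fishery groups. Modes:
#' `"target"`/`"forage"` sum counts over the group then log-transform;
#' `"ratio"` is target/(target+forage) on raw counts (NA when both are 0);
#' `"linf"` weights each species count by its asymptotic length relative to
#' the mean L-infinity of the included species,
#' `ln(1 + sum(count_s * Linf_s) / mean(Linf))`, so large-bodied taxa count
#' for more. Mixed/unidentified taxa are always excluded.
#'
#' @param hauls Haul table.
#' @param taxa Taxon registry with `group` and `linf_cm`.
#' @param mode One of `"target"`, `"forage"`, `"ratio"`, `"linf"`.
#' @return Numeric vector, one value per haul.
#' @export
group_aggregate <- function(hauls, taxa = default_taxon_table(),
                            mode = c("target", "forage", "ratio", "linf")) {
  mode <- match.arg(mode)
  tc <- taxon_columns(hauls)
  reg <- taxa[match(tc, taxa$taxon_code), ]
  if (anyNA(reg$group))
    stop("taxa missing from the registry: ",
         paste(tc[is.na(reg$group)], collapse = ", "))
  tgt <- tc[reg$group == "target"]
  for_ <- tc[reg$group == "forage"]
  sum_cols <- function(cols)
    if (!length(cols)) rep(0, nrow(hauls)) else
      if (length(cols) == 1) hauls[[cols]] else rowSums(hauls[cols])
  switch(mode,
    target = log_cpue(sum_cols(tgt)),
    forage = log_cpue(sum_cols(for_)),
    ratio = {
      t <- sum_cols(tgt); f <- sum_cols(for_)
      out <- t / (t + f)
      out[t + f == 0] <- NA_real_
      out
    },
    linf = {
      sp <- c(tgt, for_)
      linf <- reg$linf_cm[match(sp, tc)]
      if (anyNA(linf)) stop("L-infinity missing for: ",
                            paste(sp[is.na(linf)], collapse = ", "))
      w <- as.matrix(hauls[sp]) %*% linf / mean(linf)
      log_cpue(as.numeric(w))
    })
}

#' Inverse-distance-weighted interpolation surface
#'
#' Interpolates station values onto a regular latitude/longitude lattice
#' using the k nearest stations (great-circle distance) with weights
#' `d^-power`. A node coinciding with a station returns the station value;
#' nodes farther than `mask_km` from every station are masked `NA`.
#'
#' @param points `data.frame` with `latitude`, `longitude`, `value`.
#' @param grid Optional `data.frame` of nodes (`latitude`, `longitude`); if
#'   NULL a lattice at `resolution` degrees spanning the points is built.
#' @param k Neighborhood size (default 5, the typical stations-per-transect).
#' @param power IDW power (default 2).
#' @param resolution Lattice spacing in degrees (default 0.05).
#' @param mask_km Mask distance (default 75 km); `Inf` disables masking.
#' @return `data.frame` with `latitude`, `longitude`, `value`.
#' @export
idw_surface <- function(points, grid = NULL, k = 5, power = 2,
                        resolution = 0.05, mask_km = 75) {
  stopifnot(k >= 1)
  if (nrow(points) < k)
    stop("need at least k = ", k, " points, got ", nrow(points))
  if (is.null(grid)) {
    grid <- expand.grid(
      latitude = seq(min(points$latitude), max(points$latitude),
                     by = resolution),
      longitude = seq(min(points$longitude), max(points$longitude),
                      by = resolution))
  }
  eps <- 1e-6
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    d <- haversine_km(grid$latitude[i], grid$longitude[i],
                      points$latitude, points$longitude)
    if (min(d) > mask_km) return(NA_real_)
    ord <- order(d)[seq_len(k)]
    dk <- d[ord]
    vk <- points$value[ord]
    if (dk[1] < eps) return(vk[1])
    w <- dk^(-power)
    sum(w * vk) / sum(w)
  }, 0)
  data.frame(latitude = grid$latitude, longitude = grid$longitude,
             value = vals)
}
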