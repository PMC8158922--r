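#' Standardize every region and assemble the index matrix
#'
#' Runs the delta-GLM standardization region by region (AIC factor
#' selection per component) and z-scores the resulting series into the
#' regions-by-years matrix that feeds the trend analysis.
#'
#' @param hauls QC-filtered haul table covering all regions.
#' @param regions Regions to standardize (default all present, in
#'   south-to-north registry order).
#' @param years Matrix year range (default 2001:2019).
#' @param ... Passed to [standardize_region()].
#' @return List with `series` (per-region `regional_index` data frames)
#'   and `matrix` (`index_matrix`).
#' @export
regional_index_pipeline <- function(hauls, regions = NULL,
                                    years = 2001:2019, ...) {
  if (is.null(regions))
    regions <- intersect(region_table()$region, unique(hauls$region))
  series <- lapply(regions, function(r) {
    standardize_region(hauls[hauls$region == r, , drop = FALSE],
                       region = r, ...)
  })
  names(series) <- regions
  list(series = series,
       matrix = zscore_index_matrix(series, years = years))
}
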