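#' Build the haul-by-species matrix for ordination
#'
#' Applies the assemblage filters in a fixed, ledgered order: restrict to
#' the full-coverage climatology years; keep species-level taxa only; drop
#' species occurring in fewer than `min_occurrence` of the candidate hauls
#' (candidates = year-restricted hauls with at least one species-level
#' fish); drop hauls with fewer than `min_species` species present.
#'
#' @param hauls QC-filtered haul table.
#' @param taxa Taxon registry.
#' @param years Years retained (default the climatology years).
#' @param min_occurrence Species occurrence threshold as a fraction of
#'   candidate hauls (default 0.01).
#' @param min_species Minimum species per haul (default 3).
#' @return List of class `species_matrix`: `counts` (haul x species
#'   matrix), `meta` (haul metadata: latitude, year, region), `ledger`
#'   (named counts at each filter step).
#' @export
build_species_matrix <- function(hauls, taxa = default_taxon_table(),
                                 years = c(2004:2009, 2013:2019),
                                 min_occurrence = 0.01, min_species = 3) {
  ledger <- c(input_hauls = nrow(hauls))
  h <- hauls[hauls$year %in% years, , drop = FALSE]
  ledger["after_year_filter"] <- nrow(h)
  tc <- taxon_columns(h)
  species <- tc[tc %in% taxa$taxon_code[taxa$group != "other"]]
  if (!length(species)) stop("no species-level taxa in the haul table")
  ledger["species_level_taxa"] <- length(species)
  cnt <- as.matrix(h[species])
  rownames(cnt) <- h$haul_id
  candidate <- rowSums(cnt) > 0
  occ <- colMeans(cnt[candidate, , drop = FALSE] > 0)
  keep_sp <- occ >= min_occurrence
  ledger["species_after_occurrence"] <- sum(keep_sp)
  cnt <- cnt[, keep_sp, drop = FALSE]
  keep_haul <- rowSums(cnt > 0) >= min_species
  ledger["hauls_after_min_species"] <- sum(keep_haul)
  cnt <- cnt[keep_haul, , drop = FALSE]
  if (!nrow(cnt)) stop("no hauls left after assemblage filters")
  meta <- h[keep_haul, c("haul_id", "latitude", "longitude", "year",
                         "region"), drop = FALSE]
  structure(list(counts = cnt, meta = meta, ledger = ledger),
            class = "species_matrix")
}

#' Fourth-root transform
#'
#' Compresses the several orders of magnitude separating dominant from rare
#' species before computing compositional dissimilarities.
#'
#' @param x Nonnegative matrix or vector.
#' @return `x^0.25`.
#' @export
fourth_root <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("negative abundances")
  x^0.25
}

#' Bray-Curtis dissimilarity between hauls
#'
#' `d(a, b) = sum|a_s - b_s| / sum(a_s + b_s)` on the (transformed)
#' abundance rows; symmetric with zero diagonal, values in [0, 1].
#' Bray-Curtis is a semi-metric (the triangle inequality may fail), which
#' is acceptable for rank-based ordination. Delegates to
#' [vegan::vegdist()].
#'
#' @param mat Haul x species abundance matrix (already transformed).
#' @return A `dist` object.
#' @export
dissimilarity <- function(mat) {
  if (any(rowSums(mat) == 0))
    stop("haul(s) with all-zero rows: dissimilarity undefined")
  vegan::vegdist(mat, method = "bray")
}

#' Remove outlier hauls by mean dissimilarity
#'
#' Each haul is scored by its mean dissimilarity to all other hauls; hauls
#' whose score exceeds the overall mean by more than `threshold_sd`
#' standard deviations (of the scores) are removed in a single pass.
#'
#' @param diss A `dist` object or square dissimilarity matrix.
#' @param threshold_sd Threshold in SD units (default 2).
#' @return List with `retained` and `removed` (integer indices) and
#'   `scores`.
#' @export
remove_outlier_hauls <- function(diss, threshold_sd = 2) {
  d <- as.matrix(diss)
  n <- nrow(d)
  scores <- rowSums(d) / (n - 1)
  cut <- mean(scores) + threshold_sd * sd(scores)
  removed <- which(scores > cut)
  list(retained = setdiff(seq_len(n), removed), removed = removed,
       scores = scores)
}

#' Non-metric multidimensional scaling of the assemblage
#'
#' Kruskal NMDS (stress-1) via [vegan::metaMDS()] on a precomputed
#' dissimilarity, with multiple random starts; the best solution is
#' centred and principal-axis rotated, and stress is reported on the 0-100
#' scale. Species centroids are abundance-weighted averages of haul
#' coordinates.
#'
#' @param diss `dist` object.
#' @param comm Optional transformed community matrix (for species
#'   centroids).
#' @param k Dimensions (default 3).
#' @param n_starts Random starts (default 50).
#' @param seed RNG seed.
#' @return List of class `ordination_result`: `points` (haul x k),
#'   `stress` (percent), `species` (centroids or NULL), `converged`,
#'   `engine` (the `metaMDS` object).
#' @export
nmds <- function(diss, comm = NULL, k = 3, n_starts = 50, seed = 1) {
  stopifnot(k >= 1)
  set.seed(seed)
  ord <- vegan::metaMDS(diss, k = k, try = n_starts, trymax = n_starts,
                        autotransform = FALSE, trace = 0, maxit = 200)
  pts <- vegan::scores(ord, display = "sites")
  sp <- if (!is.null(comm)) vegan::wascores(pts, comm) else NULL
  structure(list(points = pts, stress = 100 * ord$stress, species = sp,
                 converged = isTRUE(ord$converged) || ord$converged > 0,
                 engine = ord),
            class = "ordination_result")
}

#' Latitude surface over the ordination plane
#'
#' Penalized thin-plate spline regression of haul latitude on ordination
#' axes 1-2 (REML smoothness selection), the same construction as
#' `vegan::ordisurf`. Returns the fitted GAM, its effective degrees of
#' freedom and a prediction grid.
#'
#' @param ordination An `ordination_result` (or matrix of coordinates).
#' @param latitude Haul latitudes aligned with the ordination rows.
#' @param k_basis Basis dimension (default 30; reduced with a warning when
#'   rank-deficient).
#' @param grid_n Prediction lattice size per axis (default 31).
#' @return List with `gam`, `edf`, `p_value`, `r_sq`, `grid`
#'   (axis1/axis2/fitted latitude).
#' @export
latitude_surface <- function(ordination, latitude, k_basis = 30,
                             grid_n = 31) {
  pts <- if (inherits(ordination, "ordination_result"))
    ordination$points else as.matrix(ordination)
  if (nrow(pts) < 30) stop("need at least 30 hauls")
  df <- data.frame(lat = latitude, a1 = pts[, 1], a2 = pts[, 2])
  if (sd(df$lat) < 1e-12) {
    # degenerate constant response: the null smooth
    grid <- expand.grid(a1 = seq(min(df$a1), max(df$a1),
                                 length.out = grid_n),
                        a2 = seq(min(df$a2), max(df$a2),
                                 length.out = grid_n))
    grid$fit <- mean(df$lat)
    g <- mgcv::gam(lat ~ 1, data = df)
    return(list(gam = g, edf = 1, p_value = NA_real_, r_sq = 0,
                grid = grid))
  }
  kb <- min(k_basis, nrow(df) - 2)
  g <- tryCatch(
    mgcv::gam(lat ~ s(a1, a2, bs = "tp", k = kb), data = df,
              method = "REML"),
    error = function(e) {
      warning("reducing spline basis: ", conditionMessage(e))
      mgcv::gam(lat ~ s(a1, a2, bs = "tp", k = max(5, kb %/% 2)),
                data = df, method = "REML")
    })
  sm <- summary(g)
  grid <- expand.grid(a1 = seq(min(df$a1), max(df$a1), length.out = grid_n),
                      a2 = seq(min(df$a2), max(df$a2), length.out = grid_n))
  grid$fit <- as.numeric(predict(g, newdata = grid))
  list(gam = g, edf = unname(sm$s.table[1, "edf"]),
       p_value = sm$s.table[1, "p-value"],
       r_sq = sm$r.sq, grid = grid)
}

#' Run the assemblage ordination end to end
#'
#' Species matrix, fourth-root transform, Bray-Curtis dissimilarity,
#' one-pass outlier removal, 3-D NMDS and the latitude surface.
#'
#' @param hauls QC-filtered haul table.
#' @param taxa Taxon registry.
#' @param k,n_starts,seed Passed to [nmds()].
#' @param ... Passed to [build_species_matrix()].
#' @return List with `matrix` (`species_matrix`), `outliers`, `ordination`,
#'   `surface`, and an updated `ledger`.
#' @export
assemblage_pipeline <- function(hauls, taxa = default_taxon_table(),
                                k = 3, n_starts = 50, seed = 1, ...) {
  sm <- build_species_matrix(hauls, taxa, ...)
  tr <- fourth_root(sm$counts)
  d <- dissimilarity(tr)
  out <- remove_outlier_hauls(d)
  ledger <- c(sm$ledger, outliers_removed = length(out$removed),
              hauls_final = length(out$retained))
  tr2 <- tr[out$retained, , drop = FALSE]
  meta2 <- sm$meta[out$retained, , drop = FALSE]
  d2 <- dissimilarity(tr2)
  ord <- nmds(d2, comm = tr2, k = k, n_starts = n_starts, seed = seed)
  surf <- latitude_surface(ord, meta2$latitude)
  list(matrix = sm, transformed = tr2, meta = meta2, outliers = out,
       ordination = ord, surface = surf, ledger = ledger)
}
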