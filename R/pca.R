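#' PCA of the regional index matrix over complete-coverage years
#'
#' Principal components of the region-by-year index matrix with years as
#' observations and regions as variables, restricted to years in which
#' every region has a value (after the zeros-to-missing rule). Computed on
#' the correlation scale; eigenvalues are reported as variance fractions.
#' Sign convention: each component is oriented so its largest-|loading|
#' region loads positively.
#'
#' @param mat An `index_matrix` (regions x years, NA = missing).
#' @param years Candidate years (default the climatology years); years with
#'   any missing region are dropped with a message.
#' @return A list of class `pca_result`: `fractions` (variance fractions),
#'   `scores` (years x components), `loadings` (regions x components),
#'   `years_used`.
#' @export
pca_indices <- function(mat, years = c(2004:2009, 2013:2019)) {
  cols <- intersect(as.character(years), colnames(mat))
  if (!length(cols)) stop("none of the requested years are in the matrix")
  sub <- mat[, cols, drop = FALSE]
  complete <- colSums(is.na(sub)) == 0
  if (!any(complete)) {
    bad <- apply(sub, 2, function(v) paste(rownames(sub)[is.na(v)],
                                           collapse = ","))
    stop("no complete years; missing region-years: ",
         paste(sprintf("%s[%s]", colnames(sub), bad), collapse = "; "))
  }
  if (any(!complete))
    message("dropping incomplete year(s): ",
            paste(colnames(sub)[!complete], collapse = ", "))
  X <- t(sub[, complete, drop = FALSE])   # years x regions
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  fractions <- pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation
  scores <- pc$x
  for (k in seq_len(ncol(load))) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(fractions = fractions, scores = scores,
                 loadings = load, years_used = rownames(X)),
            class = "pca_result")
}

#' Correlate principal components with DFA trends
#'
#' Pearson correlations between each PC score series and each smoothed DFA
#' trend over the years shared by both.
#'
#' @param pca A `pca_result`.
#' @param fit A `dfa_fit` with `years` set.
#' @param n_components Number of PCs to correlate (default 2).
#' @return `data.frame` with `pc`, `trend`, `r`, `abs_r`.
#' @export
correlate_components <- function(pca, fit, n_components = 2) {
  if (is.null(fit$years)) stop("fit carries no year labels")
  shared <- intersect(pca$years_used, fit$years)
  if (length(shared) < 3) stop("fewer than 3 overlapping years")
  m <- fit$spec$m
  n_components <- min(n_components, ncol(pca$scores))
  out <- expand.grid(pc = seq_len(n_components), trend = seq_len(m))
  out$r <- NA_real_
  for (i in seq_len(nrow(out))) {
    s <- pca$scores[match(shared, pca$years_used), out$pc[i]]
    x <- fit$xs[out$trend[i], match(shared, fit$years)]
    out$r[i] <- cor(s, x)
  }
  out$abs_r <- abs(out$r)
  out
}
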