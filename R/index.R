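#' Prepare haul covariates for index standardization
#'
#' Adds the factors used by the delta-GLM: `depth_bin` (inshore/offshore at
#' a 90 m bottom-depth split), `period_bin` (Julian day in 10-day bins) and
#' coerces `year` and `station` to factors. Hauls without a station keep a
#' `"none"` level so they still inform year effects.
#'
#' @param hauls Haul table.
#' @param depth_split Bottom-depth split in metres (default 90).
#' @return The haul table with `catch` (total rockfish per haul), `year_f`,
#'   `depth_bin`, `station_f`, `period_bin` columns appended.
#' @export
prepare_index_data <- function(hauls, depth_split = 90) {
  hauls$catch <- scope_catch(hauls)
  hauls$year_f <- factor(hauls$year)
  bd <- hauls$bottom_depth
  bd[is.na(bd)] <- depth_split + 1
  hauls$depth_bin <- factor(ifelse(bd < depth_split, "inshore", "offshore"))
  jd <- if (!is.null(hauls$julian_day)) hauls$julian_day else
    as.integer(format(hauls$date, "%j"))
  hauls$period_bin <- factor(jd %/% 10L)
  st <- as.character(hauls$station)
  st[is.na(st)] <- "none"
  hauls$station_f <- factor(st)
  hauls
}

# build a formula from the factor short codes Y/D/S/P
index_formula <- function(response, factors) {
  map <- c(Y = "year_f", D = "depth_bin", S = "station_f", P = "period_bin")
  rhs <- paste(map[factors], collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

# drop factors that have fewer than 2 observed levels in this subset
viable_factors <- function(data, factors) {
  map <- c(Y = "year_f", D = "depth_bin", S = "station_f", P = "period_bin")
  keep <- vapply(factors, function(f)
    nlevels(droplevels(data[[map[f]]])) >= 2, TRUE)
  factors[keep]
}

#' Fit the positive-catch component of the delta-GLM
#'
#' Ordinary least squares on `ln(catch)` for positive hauls with additive
#' year / depth-bin / station / period factors under sum-to-zero contrasts,
#' so year effects are interpretable without a baseline year.
#'
#' @param data Output of [prepare_index_data()] for one region.
#' @param factors Character subset of `c("Y","D","S","P")`; `"Y"` is always
#'   retained.
#' @return List with the `lm` fit, `sigma2` (ML residual variance),
#'   `loglik`, `aic`, `factors`, and `year_levels` with positive data.
#' @export
fit_positive_component <- function(data, factors = c("Y", "D", "S", "P")) {
  factors <- union("Y", factors)
  pos <- droplevels(data[data$catch > 0, , drop = FALSE])
  if (!nrow(pos)) stop("no positive hauls")
  factors <- viable_factors(pos, factors)
  if (!length(factors)) factors <- "Y"
  if (!"Y" %in% factors || nlevels(pos$year_f) < 2)
    fml <- stats::as.formula("log(catch) ~ 1")
  else fml <- index_formula("log(catch)", factors)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(fml, data = pos)
  n <- nrow(pos)
  sigma2 <- sum(stats::residuals(fit)^2) / n
  list(fit = fit, sigma2 = sigma2, loglik = as.numeric(logLik(fit)),
       aic = AIC(fit), factors = factors,
       year_levels = levels(pos$year_f), data = pos)
}

#' Fit the presence/absence component of the delta-GLM
#'
#' Bernoulli GLM with logit link on the same candidate factors. If the fit
#' separates (a factor level with all-positive or all-zero hauls), the
#' returned prediction fit is refit on weakly augmented data: every row is
#' duplicated with flipped response at a small prior weight, shrinking
#' fitted probabilities away from 0/1 (a light-touch stand-in for Firth
#' penalization). The unpenalized AIC is kept for factor selection.
#'
#' @inheritParams fit_positive_component
#' @param prior_weight Total augmentation weight per observation
#'   (default 0.02).
#' @return List with `fit` (for prediction), `aic`, `loglik`, `factors`,
#'   `separated` flag, and `p_fixed` (0/1 when the region is degenerate).
#' @export
fit_binomial_component <- function(data, factors = c("Y", "D", "S", "P"),
                                   prior_weight = 0.02) {
  factors <- union("Y", factors)
  data <- droplevels(data)
  data$pos <- as.integer(data$catch > 0)
  if (all(data$pos == 1) || all(data$pos == 0)) {
    warning("region is all-positive or all-zero; fixed p used")
    return(list(fit = NULL, aic = NA_real_, loglik = NA_real_,
                factors = "Y", separated = FALSE,
                p_fixed = mean(data$pos), data = data))
  }
  factors <- viable_factors(data, factors)
  if (!length(factors)) factors <- "Y"
  fml <- if ("Y" %in% factors && nlevels(data$year_f) >= 2)
    index_formula("pos", factors) else stats::as.formula("pos ~ 1")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = data))
  separated <- !fit$converged || any(abs(coef(fit)) > 10, na.rm = TRUE)
  pred_fit <- fit
  if (separated) {
    aug <- rbind(data, data)
    aug$pos <- c(data$pos, 1L - data$pos)
    aug$.w <- c(rep(1, nrow(data)), rep(prior_weight, nrow(data)))
    pred_fit <- suppressWarnings(
      glm(fml, family = binomial(), data = aug, weights = .w))
  }
  list(fit = pred_fit, aic = AIC(fit),
       loglik = as.numeric(logLik(fit)), factors = factors,
       separated = separated, p_fixed = NULL, data = data)
}

#' AIC factor selection for both delta-GLM components
#'
#' Exhaustive search over the 8 subsets of `{Y, D, S, P}` containing the
#' year effect, independently for the positive and binomial components;
#' minimum AIC wins, ties break toward fewer parameters.
#'
#' @param data Output of [prepare_index_data()] for one region.
#' @param candidates Candidate factor codes (default Y, D, S, P).
#' @return List with `positive` and `binomial` selected factor subsets and
#'   the AIC tables.
#' @export
select_factors_aic <- function(data, candidates = c("Y", "D", "S", "P")) {
  others <- setdiff(candidates, "Y")
  subsets <- lapply(0:length(others), function(sz)
    if (sz == 0) list(character()) else
      utils::combn(others, sz, simplify = FALSE))
  subsets <- lapply(unlist(subsets, recursive = FALSE),
                    function(s) c("Y", s))
  score <- function(fun) {
    aic <- vapply(subsets, function(s) {
      out <- tryCatch(fun(data, s)$aic, error = function(e) NA_real_)
      if (is.null(out) || is.na(out)) Inf else out
    }, 0)
    npar <- lengths(subsets)
    ord <- order(aic, npar)
    list(best = subsets[[ord[1]]],
         table = data.frame(
           subset = vapply(subsets, paste, "", collapse = "+"),
           k = npar, aic = aic))
  }
  pos <- score(fit_positive_component)
  bin <- score(fit_binomial_component)
  list(positive = pos$best, binomial = bin$best,
       positive_table = pos$table, binomial_table = bin$table)
}

#' Combine delta-GLM components into an annual index
#'
#' For each year the positive-catch mean and the probability of a positive
#' tow are predicted marginally: covariates other than year are held at
#' their observed distribution (every haul is re-predicted with its year
#' replaced, then averaged on the linear-predictor scale for the lognormal
#' mean and on the probability scale for presence). The index is
#' `p(y) * exp(mu_pos(y) + sigma2/2)` (lognormal bias correction,
#' switchable).
#'
#' @param pos_fit Output of [fit_positive_component()].
#' @param bin_fit Output of [fit_binomial_component()].
#' @param data The region's prepared haul table (defines years and the
#'   covariate distribution).
#' @param region Region label carried through.
#' @param bias_correct Apply `exp(sigma2/2)` (default TRUE).
#' @return `data.frame` of class `regional_index`: `region`, `year`, `p`,
#'   `mu_pos`, `index` (NA where the year has no hauls or no positive
#'   hauls).
#' @export
combine_index <- function(pos_fit, bin_fit, data, region = "region",
                          bias_correct = TRUE) {
  years <- sort(unique(data$year))
  bc <- if (bias_correct) exp(pos_fit$sigma2 / 2) else 1
  out <- data.frame(region = region, year = years, p = NA_real_,
                    mu_pos = NA_real_, index = NA_real_)
  for (i in seq_along(years)) {
    y <- as.character(years[i])
    # presence probability
    p <- if (!is.null(bin_fit$p_fixed)) bin_fit$p_fixed else {
      nd <- bin_fit$data
      if (!y %in% levels(nd$year_f)) NA_real_ else {
        nd$year_f <- factor(y, levels = levels(nd$year_f))
        mean(predict(bin_fit$fit, newdata = nd, type = "response"))
      }
    }
    # positive-catch mean on the log scale
    mu <- {
      nd <- pos_fit$data
      if (!y %in% levels(nd$year_f)) NA_real_ else {
        nd$year_f <- factor(y, levels = levels(nd$year_f))
        mean(predict(pos_fit$fit, newdata = nd))
      }
    }
    out$p[i] <- p
    out$mu_pos[i] <- mu
    out$index[i] <- p * exp(mu) * bc
  }
  class(out) <- c("regional_index", class(out))
  out
}

#' Standardized index series for one region
#'
#' Convenience wrapper: AIC factor selection, both component fits, and the
#' combined annual index for a single region's hauls.
#'
#' @param hauls Haul table for one region.
#' @param region Region label.
#' @param candidates Candidate factors (default Y, D, S, P).
#' @param select Run AIC selection (default TRUE); if FALSE all candidates
#'   are used.
#' @param ... Passed to [combine_index()].
#' @return A `regional_index` data.frame.
#' @export
standardize_region <- function(hauls, region = hauls$region[1],
                               candidates = c("Y", "D", "S", "P"),
                               select = TRUE, ...) {
  data <- prepare_index_data(hauls)
  fac <- if (select) select_factors_aic(data, candidates) else
    list(positive = candidates, binomial = candidates)
  pos <- fit_positive_component(data, fac$positive)
  bin <- fit_binomial_component(data, fac$binomial)
  combine_index(pos, bin, data, region = region, ...)
}

#' Region-by-year z-scored index matrix
#'
#' Zeros are converted to missing first (a zero index carries no usable
#' catch-rate information), the surviving indices are log-transformed by
#' default (the combined delta-GLM index is lognormal-scale and spans
#' orders of magnitude; z-scoring the raw index would let single spike
#' years dominate a series), then each region's series is z-scored over
#' its non-missing entries (denominator n - 1). Regions with fewer than 2
#' usable values or zero variance are dropped with a warning.
#'
#' @param series List of `regional_index` data.frames (or a single one).
#' @param years Year range of the matrix columns (default 2001:2019).
#' @param log Log-transform the index before z-scoring (default TRUE).
#' @return A numeric matrix (regions x years, NA for missing) of class
#'   `index_matrix`.
#' @export
zscore_index_matrix <- function(series, years = 2001:2019, log = TRUE) {
  if (is.data.frame(series)) series <- list(series)
  regions <- vapply(series, function(s) as.character(s$region[1]), "")
  m <- matrix(NA_real_, length(series), length(years),
              dimnames = list(regions, years))
  for (i in seq_along(series)) {
    s <- series[[i]]
    m[i, as.character(s$year)] <- s$index
  }
  m[!is.na(m) & m == 0] <- NA_real_
  if (log) m <- base::log(m)
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    ok <- !is.na(v)
    if (sum(ok) < 2 || sd(v[ok]) == 0) {
      keep[i] <- FALSE
      next
    }
    m[i, ok] <- (v[ok] - mean(v[ok])) / sd(v[ok])
  }
  if (any(!keep)) {
    warning("dropping region(s) with <2 usable values or zero variance: ",
            paste(rownames(m)[!keep], collapse = ", "))
    m <- m[keep, , drop = FALSE]
  }
  structure(m, class = c("index_matrix", "matrix"))
}
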