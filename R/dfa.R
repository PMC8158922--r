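#' Dynamic factor analysis model specification
#'
#' A DFA spec is the triple (number of latent trends, observation-variance
#' structure, AR-coefficient structure). The observation model is
#' `y_t = Z x_t + v_t` with diagonal R; the trends follow
#' `x_t = phi x_{t-1} + w_t` with process noise fixed at variance 1, so the
#' trend scale is carried by the loadings Z. `phi` near 1 gives random-walk
#' trends, near 0 white noise.
#'
#' @param m Number of latent trends (1--3 in the standard grid).
#' @param R_structure `"diagonal-unequal"` (one observation variance per
#'   series) or `"diagonal-equal"` (shared).
#' @param phi_structure `"shared"` (one AR coefficient), `"per-trend"`
#'   (one per trend, diagonal state transition) or `"fixed-one"`
#'   (random-walk trends, phi = 1).
#' @return A list of class `dfa_spec`.
#' @export
dfa_spec <- function(m,
                     R_structure = c("diagonal-unequal", "diagonal-equal"),
                     phi_structure = c("shared", "per-trend", "fixed-one")) {
  stopifnot(m >= 1)
  structure(list(m = as.integer(m),
                 R_structure = match.arg(R_structure),
                 phi_structure = match.arg(phi_structure)),
            class = "dfa_spec")
}

#' The standard 18-model DFA grid
#'
#' All combinations of 1--3 trends, equal/unequal diagonal R, and
#' shared / per-trend / fixed-at-one AR structure.
#'
#' @return List of 18 [dfa_spec()] objects.
#' @export
dfa_grid_specs <- function() {
  out <- list()
  for (m in 1:3)
    for (R in c("diagonal-equal", "diagonal-unequal"))
      for (p in c("shared", "per-trend", "fixed-one"))
        out[[length(out) + 1]] <- dfa_spec(m, R, p)
  out
}

# label for tables
spec_label <- function(spec)
  sprintf("m=%d, R=%s, phi=%s", spec$m, spec$R_structure, spec$phi_structure)

# initial state variance: stationary when |phi|<1, MARSS-style diffuse
# (variance 5) for random-walk trends
initial_state_var <- function(phi) {
  v <- ifelse(abs(phi) < 1, 1 / (1 - phi^2), 5)
  diag(v, length(phi))
}

# mask of free Z entries under the upper-triangle identifiability constraint
z_free_mask <- function(n, m) {
  mask <- matrix(TRUE, n, m)
  for (i in seq_len(min(n, m)))
    if (i < m) mask[i, (i + 1):m] <- FALSE
  mask
}

#' Exact Gaussian log-likelihood of a DFA parameterisation
#'
#' Kalman-filter evaluation of the log-density of the observed (non-missing)
#' cells; missing entries are skipped in the update step, never imputed.
#'
#' @param data Numeric matrix, series x time, NA = missing.
#' @param Z Loadings matrix (series x m).
#' @param rdiag Observation variances, length 1 (recycled) or nrow(data).
#' @param phi AR coefficient(s), length 1 (recycled) or m.
#' @return Scalar log-likelihood.
#' @export
kalman_loglik <- function(data, Z, rdiag, phi) {
  Z <- as.matrix(Z)
  n <- nrow(Z); m <- ncol(Z)
  if (m > n) stop("number of trends must not exceed the number of series")
  if (!all(is.finite(Z)) || !all(is.finite(rdiag)) || !all(is.finite(phi)))
    stop("non-finite parameters")
  rdiag <- rep_len(rdiag, n)
  phi <- rep_len(phi, m)
  if (any(abs(phi) > 1)) stop("|phi| must be <= 1")
  y <- as.matrix(data)
  storage.mode(y) <- "double"
  kalman_loglik_cpp(y, Z, rdiag, phi, initial_state_var(phi))
}

# pack/unpack the working parameter vector (used by the Hessian)
pack_params <- function(Z, rdiag, phi, spec, mask) {
  r <- if (spec$R_structure == "diagonal-equal") log(rdiag[1]) else log(rdiag)
  p <- switch(spec$phi_structure,
              "shared" = atanh(min(max(phi[1], -0.9999), 0.9999)),
              "per-trend" = atanh(pmin(pmax(phi, -0.9999), 0.9999)),
              "fixed-one" = numeric())
  c(Z[mask], r, p)
}

unpack_params <- function(theta, spec, n, mask) {
  m <- spec$m
  nz <- sum(mask)
  Z <- matrix(0, n, m)
  Z[mask] <- theta[seq_len(nz)]
  i <- nz
  if (spec$R_structure == "diagonal-equal") {
    rdiag <- rep(exp(theta[i + 1]), n); i <- i + 1
  } else {
    rdiag <- exp(theta[i + seq_len(n)]); i <- i + n
  }
  phi <- switch(spec$phi_structure,
                "shared" = rep(tanh(theta[i + 1]), m),
                "per-trend" = tanh(theta[i + seq_len(m)]),
                "fixed-one" = rep(1, m))
  list(Z = Z, rdiag = rdiag, phi = phi)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; `NA` when `n <= k + 1`.
#'
#' @param loglik Log-likelihood at the MLE.
#' @param k Number of free parameters.
#' @param n Number of observations (non-missing cells for a DFA fit).
#' @return Scalar AICc.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# number of free parameters for AICc
dfa_n_params <- function(spec, n) {
  m <- spec$m
  nz <- n * m - m * (m - 1) / 2
  nr <- if (spec$R_structure == "diagonal-equal") 1 else n
  np <- switch(spec$phi_structure, "shared" = 1, "per-trend" = m,
               "fixed-one" = 0)
  nz + nr + np
}

# one ECME pass: E-step, exact M-steps for Z and R, then a conditional
# maximisation of the *marginal* likelihood over phi (so every step is
# guaranteed non-decreasing in the reported log-likelihood)
ecme_iterate <- function(y, Z, rdiag, phi, spec, phi_window = 0.4) {
  n <- nrow(y); Tn <- ncol(y); m <- spec$m
  ks <- kalman_smooth_cpp(y, Z, rdiag, phi, initial_state_var(phi))
  xs <- ks$xs; Ps <- ks$Ps
  # E[x_t x_t'] per time step
  Exx <- Ps
  for (t in seq_len(Tn))
    Exx[, , t] <- Exx[, , t] + tcrossprod(xs[, t, drop = FALSE])
  mask <- z_free_mask(n, m)
  # Z rows decouple because R is diagonal
  for (i in seq_len(n)) {
    obs <- which(!is.na(y[i, ]))
    J <- which(mask[i, ])
    if (!length(obs) || !length(J)) next
    A <- matrix(0, length(J), length(J))
    b <- numeric(length(J))
    for (t in obs) {
      A <- A + Exx[J, J, t, drop = FALSE][, , 1]
      b <- b + y[i, t] * xs[J, t]
    }
    zi <- tryCatch(solve(A, b), error = function(e) Z[i, J])
    Z[i, J] <- zi
  }
  # R update (expected squared residuals)
  ss <- numeric(n); cnt <- integer(n)
  for (i in seq_len(n)) {
    obs <- which(!is.na(y[i, ]))
    cnt[i] <- length(obs)
    zi <- Z[i, , drop = FALSE]
    for (t in obs) {
      e <- y[i, t] - sum(zi * xs[, t])
      ss[i] <- ss[i] + e^2 + zi %*% Ps[, , t] %*% t(zi)
    }
  }
  if (spec$R_structure == "diagonal-equal") {
    rdiag <- rep(max(sum(ss) / sum(cnt), 1e-6), n)
  } else {
    rdiag <- ifelse(cnt > 0, pmax(ss / pmax(cnt, 1), 1e-6), rdiag)
  }
  # conditional ML step for phi against the true marginal likelihood
  f <- function(p) kalman_loglik_cpp(y, Z, rdiag, p, initial_state_var(p))
  if (spec$phi_structure == "shared") {
    cur <- f(phi)
    opt <- optimize(function(p) f(rep(p, m)),
                    lower = max(-0.99, phi[1] - phi_window),
                    upper = min(0.99, phi[1] + phi_window),
                    maximum = TRUE, tol = 1e-4)
    if (opt$objective > cur) phi <- rep(opt$maximum, m)
  } else if (spec$phi_structure == "per-trend") {
    for (j in seq_len(m)) {
      cur <- f(phi)
      g <- function(p) { ph <- phi; ph[j] <- p; f(ph) }
      opt <- optimize(g, lower = max(-0.99, phi[j] - phi_window),
                      upper = min(0.99, phi[j] + phi_window),
                      maximum = TRUE, tol = 1e-4)
      if (opt$objective > cur) phi[j] <- opt$maximum
    }
  }
  list(Z = Z, rdiag = rdiag, phi = phi, loglik = f(phi))
}

# starting values: deterministic PCA-based start or seeded random draws
dfa_start <- function(y, spec, random = FALSE) {
  n <- nrow(y); m <- spec$m
  mask <- z_free_mask(n, m)
  if (random) {
    Z <- matrix(rnorm(n * m, sd = 0.5), n, m)
    phi0 <- runif(1, -0.3, 0.9)
  } else {
    y0 <- y
    y0[is.na(y0)] <- 0
    S <- tcrossprod(y0) / ncol(y0)
    eg <- eigen(S, symmetric = TRUE)
    Z <- eg$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(eg$values[seq_len(m)], 1e-3)), m)
    phi0 <- 0.5
  }
  Z[!mask] <- 0
  phi <- switch(spec$phi_structure,
                "fixed-one" = rep(1, m),
                rep(phi0, m))
  if (spec$phi_structure == "per-trend" && random)
    phi <- runif(m, -0.3, 0.9)
  list(Z = Z, rdiag = rep(0.5, n), phi = phi)
}

#' Fit a DFA model by maximum likelihood
#'
#' ECME estimation: exact EM conditional-maximisation steps for the
#' loadings and observation variances, plus a direct conditional
#' maximisation of the marginal likelihood over the AR coefficient(s), so
#' the log-likelihood trace is non-decreasing by construction. Multiple
#' seeded random restarts (short runs) precede a full run from the best
#' start; the deterministic PCA start is always included.
#'
#' @param spec A [dfa_spec()].
#' @param data Series x time matrix (z-scored rows), NA = missing.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum ECME iterations (default 2000).
#' @param n_starts Number of random restarts besides the deterministic
#'   start (default 10).
#' @param start_iter Iterations used to triage the starts (default 30).
#' @param seed Seed for the random restarts (default 1).
#' @return A list of class `dfa_fit`: `Z`, `rdiag`, `phi` (length m),
#'   `xs` (smoothed trends, m x T), `xs_se`, `Ps` (state covariance cube),
#'   `loglik`, `loglik_trace`, `n_params`, `n_obs`, `aicc`, `converged`,
#'   `spec`, `rotation` (NULL until [rotate_loadings()]).
#' @export
em_fit <- function(spec, data, tol = 1e-6, max_iter = 2000,
                   n_starts = 10, start_iter = 30, seed = 1) {
  y <- as.matrix(data)
  storage.mode(y) <- "double"
  n <- nrow(y)
  if (spec$m >= n) stop("need more series than trends")
  usable <- rowSums(!is.na(y)) > 0
  if (sum(usable) < spec$m) stop("too few usable series")
  run <- function(par, iters) {
    trace <- numeric(0)
    for (it in seq_len(iters)) {
      par2 <- ecme_iterate(y, par$Z, par$rdiag, par$phi, spec)
      trace <- c(trace, par2$loglik)
      done <- it > 1 &&
        abs(trace[it] - trace[it - 1]) <
          tol * (abs(trace[it - 1]) + 1e-8)
      par <- par2
      if (done) break
    }
    par$trace <- trace
    par$converged <- length(par$trace) < iters ||
      (length(trace) > 1 &&
         abs(diff(utils::tail(trace, 2))) <
           tol * (abs(trace[length(trace) - 1]) + 1e-8))
    par
  }
  starts <- list(dfa_start(y, spec, random = FALSE))
  if (n_starts > 0) {
    set.seed(seed)
    for (s in seq_len(n_starts))
      starts[[length(starts) + 1]] <- dfa_start(y, spec, random = TRUE)
  }
  short <- lapply(starts, run, iters = start_iter)
  best <- short[[which.max(vapply(short, `[[`, 0, "loglik"))]]
  fit <- run(best, iters = max_iter)
  if (!fit$converged)
    warning("EM did not converge in ", max_iter, " iterations for ",
            spec_label(spec))
  ks <- kalman_smooth_cpp(y, fit$Z, fit$rdiag, fit$phi,
                          initial_state_var(fit$phi))
  xs_se <- sqrt(t(apply(ks$Ps, 3, diag)))
  if (spec$m == 1) xs_se <- matrix(xs_se, nrow = 1)
  k <- dfa_n_params(spec, n)
  n_obs <- sum(!is.na(y))
  aicc_val <- aicc(ks$loglik, k, n_obs)
  structure(list(Z = fit$Z, rdiag = fit$rdiag, phi = fit$phi,
                 xs = ks$xs, xs_se = xs_se, Ps = ks$Ps,
                 loglik = ks$loglik, loglik_trace = c(best$trace, fit$trace),
                 n_params = k, n_obs = n_obs, aicc = aicc_val,
                 converged = isTRUE(fit$converged), spec = spec,
                 series = rownames(y), years = colnames(y),
                 rotation = NULL),
            class = "dfa_fit")
}

#' Fitted values of a DFA model
#' @param fit A `dfa_fit`.
#' @return Series x time matrix `Z %*% x`.
#' @export
fitted_dfa <- function(fit) {
  out <- fit$Z %*% fit$xs
  dimnames(out) <- list(fit$series, fit$years)
  out
}

#' AICc comparison table with Akaike weights
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with n the number of
#' non-missing observation cells. Specs with `n <= k + 1` are excluded with
#' a warning. Weights are normalised relative likelihoods
#' `exp(-delta/2) / sum(exp(-delta/2))`.
#'
#' @param fits List of `dfa_fit` objects on the same data.
#' @return `data.frame` sorted by AICc: `model`, `m`, `R`, `phi_structure`,
#'   `phi`, `k`, `loglik`, `AICc`, `delta_AICc`, `weight`.
#' @export
aicc_and_weights <- function(fits) {
  n_obs <- unique(vapply(fits, function(f) as.numeric(f$n_obs), 0))
  if (length(n_obs) != 1)
    stop("fits were not computed on identical data")
  tab <- data.frame(
    model = vapply(fits, function(f) spec_label(f$spec), ""),
    m = vapply(fits, function(f) f$spec$m, 0L),
    R = vapply(fits, function(f) f$spec$R_structure, ""),
    phi_structure = vapply(fits, function(f) f$spec$phi_structure, ""),
    phi = vapply(fits, function(f) round(f$phi[1], 3), 0),
    k = vapply(fits, `[[`, 0, "n_params"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    AICc = vapply(fits, `[[`, 0, "aicc"),
    stringsAsFactors = FALSE
  )
  if (anyNA(tab$AICc)) {
    warning("excluding spec(s) with undefined AICc (n <= k + 1)")
    tab <- tab[!is.na(tab$AICc), , drop = FALSE]
  }
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  rel <- exp(-tab$delta_AICc / 2)
  tab$weight <- rel / sum(rel)
  tab[order(tab$AICc), , drop = FALSE]
}

#' Varimax-rotate loadings and trends
#'
#' For m >= 2, applies the varimax rotation to Z and the inverse rotation
#' to the trends, leaving fitted values unchanged; each rotated trend is
#' oriented so that its largest-|loading| series loads positively. Identity
#' for m = 1.
#'
#' @param fit A `dfa_fit`.
#' @return The fit with rotated `Z`, `xs`, `xs_se`, and the orthogonal
#'   `rotation` matrix recorded.
#' @export
rotate_loadings <- function(fit) {
  m <- fit$spec$m
  if (m < 2) {
    fit$rotation <- diag(1, m)
    return(fit)
  }
  H <- varimax(fit$Z, normalize = FALSE)$rotmat
  Zr <- fit$Z %*% H
  signs <- vapply(seq_len(m), function(k) {
    i <- which.max(abs(Zr[, k]))
    if (Zr[i, k] < 0) -1 else 1
  }, 0)
  H <- H %*% diag(signs, m)
  fit$rotation <- H
  fit$Z <- fit$Z %*% H
  fit$xs <- t(H) %*% fit$xs
  Tn <- dim(fit$Ps)[3]
  se <- matrix(0, m, Tn)
  for (t in seq_len(Tn))
    se[, t] <- sqrt(pmax(diag(t(H) %*% fit$Ps[, , t] %*% H), 0))
  fit$xs_se <- se
  fit
}

# numerical Hessian of the negative log-likelihood (central differences)
dfa_hessian <- function(fit, data, step = 1e-4) {
  y <- as.matrix(data)
  storage.mode(y) <- "double"
  n <- nrow(y)
  spec <- fit$spec
  mask <- z_free_mask(n, spec$m)
  Z0 <- if (is.null(fit$rotation)) fit$Z else
    fit$Z %*% t(fit$rotation)  # back to the unrotated parameterisation
  th0 <- pack_params(Z0, fit$rdiag, fit$phi, spec, mask)
  f <- function(th) {
    p <- unpack_params(th, spec, n, mask)
    -kalman_loglik_cpp(y, p$Z, p$rdiag, p$phi, initial_state_var(p$phi))
  }
  k <- length(th0)
  H <- matrix(0, k, k)
  f0 <- f(th0)
  for (i in seq_len(k)) {
    ei <- rep(0, k); ei[i] <- step
    H[i, i] <- (f(th0 + ei) - 2 * f0 + f(th0 - ei)) / step^2
    if (i < k) for (j in (i + 1):k) {
      ej <- rep(0, k); ej[j] <- step
      H[i, j] <- H[j, i] <-
        (f(th0 + ei + ej) - f(th0 + ei - ej) -
           f(th0 - ei + ej) + f(th0 - ei - ej)) / (4 * step^2)
    }
  }
  list(H = H, theta = th0, mask = mask)
}

#' 95% confidence intervals for the factor loadings
#'
#' Intervals come from the observed information (numerical Hessian of the
#' likelihood at the MLE, central differences on the working scale) on the
#' unrotated loadings, propagated through the varimax rotation when the fit
#' has been rotated. Entries fixed to zero by the identifiability
#' constraint carry no interval.
#'
#' @param fit A `dfa_fit` (rotated or not).
#' @param data The matrix the fit was estimated on.
#' @return `data.frame` with `series`, `trend`, `loading`, `se`, `lwr`,
#'   `upr` (NA for constrained entries).
#' @export
loading_cis <- function(fit, data) {
  n <- nrow(fit$Z); m <- fit$spec$m
  hz <- dfa_hessian(fit, data)
  nz <- sum(hz$mask)
  cov <- tryCatch(solve(hz$H), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) ||
      any(diag(cov)[seq_len(nz)] < 0)) {
    warning("singular or indefinite Hessian; loading intervals set NA ",
            "(consider a parametric bootstrap)")
    cov <- matrix(NA_real_, length(hz$theta), length(hz$theta))
  }
  # covariance of the free entries of each row of (unrotated) Z
  idx <- matrix(NA_integer_, n, m)
  idx[hz$mask] <- seq_len(nz)
  H <- if (is.null(fit$rotation)) diag(1, m) else fit$rotation
  out <- expand.grid(series = seq_len(n), trend = seq_len(m))
  out$loading <- fit$Z[cbind(out$series, out$trend)]
  out$se <- NA_real_
  for (i in seq_len(n)) {
    free <- which(hz$mask[i, ])
    if (!length(free)) next
    Sig <- matrix(0, m, m)
    Sig[free, free] <- cov[idx[i, free], idx[i, free]]
    for (k in seq_len(m)) {
      # cells fixed to zero pre-rotation carry no interval, matching the
      # reporting convention for the constrained loading
      if (!hz$mask[i, k]) next
      h <- H[, k]
      out$se[out$series == i & out$trend == k] <-
        sqrt(max(t(h) %*% Sig %*% h, 0))
    }
  }
  out$lwr <- out$loading - 1.96 * out$se
  out$upr <- out$loading + 1.96 * out$se
  if (!is.null(fit$series)) out$series <- fit$series[out$series]
  out
}

#' Fit the full DFA model grid
#'
#' Runs [em_fit()] for every spec in the grid and tabulates AICc and
#' weights. The best model (and optionally all) is varimax-rotated.
#'
#' @param data Series x time matrix, NA = missing.
#' @param specs List of specs (default the 18-model grid).
#' @param ... Passed to [em_fit()].
#' @return List with `fits` (named by spec label), `comparison`
#'   (AICc table) and `best` (rotated best fit).
#' @export
dfa_grid <- function(data, specs = dfa_grid_specs(), ...) {
  fits <- lapply(specs, em_fit, data = data, ...)
  names(fits) <- vapply(fits, function(f) spec_label(f$spec), "")
  comparison <- aicc_and_weights(fits)
  best <- rotate_loadings(fits[[comparison$model[1]]])
  list(fits = fits, comparison = comparison, best = best)
}
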