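test_that("kalman_loglik equals the dense joint-Gaussian oracle for every
          spec structure", {
  set.seed(21)
  for (spec in dfa_grid_specs()) {
    n <- sample_one(max(spec$m + 1, 2):4)
    Tn <- sample_one(3:6)
    par <- random_dfa_params(spec, n)
    y <- matrix(rnorm(n * Tn), n, Tn)
    y[sample(n * Tn, 2)] <- NA
    ll <- kalman_loglik(y, par$Z, par$rdiag, par$phi)
    oracle <- dense_dfa_loglik(y, par$Z, par$rdiag, par$phi,
                               oracle_P1(par$phi))
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("white-noise limit and missing-data marginalization", {
  # m=1, phi=0, Z=1, R=r single series: iid N(0, 1+r)
  set.seed(2)
  y <- matrix(rnorm(30), 1, 30)
  r <- 0.4
  ll <- kalman_loglik(y, matrix(1, 1, 1), r, 0)
  expect_equal(ll, sum(dnorm(y, 0, sqrt(1 + r), log = TRUE)),
               tolerance = 1e-10)
  # a fully-missing final year marginalises away exactly (an interior gap
  # changes the implied state covariance and is checked against the dense
  # oracle instead)
  y2 <- matrix(rnorm(3 * 6), 3, 6)
  Z <- matrix(c(1, .5, .2), 3, 1)
  expect_equal(kalman_loglik(cbind(y2, NA), Z, rep(.3, 3), .6),
               kalman_loglik(y2, Z, rep(.3, 3), .6), tolerance = 1e-10)
  ygap <- cbind(y2[, 1:3], NA, y2[, 4:6])
  expect_equal(kalman_loglik(ygap, Z, rep(.3, 3), .6),
               dense_dfa_loglik(ygap, Z, rep(.3, 3), .6, oracle_P1(.6)),
               tolerance = 1e-8)
  # validation
  expect_error(kalman_loglik(y2, matrix(1, 3, 4), rep(.3, 3),
                             rep(.5, 4)), "trends")
  expect_error(kalman_loglik(y2, Z, rep(.3, 3), 1.2), "phi")
})

test_that("EM is monotone and recovers phi and R structure", {
  set.seed(31)
  x <- simulate_latent_trends(1, 200, 0.5, seed = 31)
  Z <- matrix(runif(12, .4, 1), 12, 1)
  Rtruth <- seq(0.15, 0.8, length.out = 12)
  y <- simulate_regional_indices(x, Z, Rtruth, seed = 32)
  fit <- em_fit(dfa_spec(1, "diagonal-unequal", "shared"), y,
                n_starts = 3, max_iter = 400)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_lt(abs(fit$phi[1] - 0.5), 0.1)
  expect_gt(cor(fit$rdiag, Rtruth, method = "spearman"), 0.8)
  # monotonicity holds on a second structure with missing data
  y2 <- y[1:6, 1:60]
  y2[sample(length(y2), 40)] <- NA
  fit2 <- suppressWarnings(
    em_fit(dfa_spec(2, "diagonal-equal", "per-trend"), y2,
           n_starts = 2, max_iter = 150))
  expect_true(all(diff(fit2$loglik_trace) > -1e-8))
})

test_that("missing-data consistency: a fully-missing column leaves
          estimates unchanged", {
  set.seed(41)
  x <- simulate_latent_trends(1, 120, 0.6, seed = 41)
  Z <- matrix(runif(8, .4, 1), 8, 1)
  y <- simulate_regional_indices(x, Z, rep(0.3, 8), seed = 42)
  spec <- dfa_spec(1, "diagonal-equal", "shared")
  f1 <- em_fit(spec, y, n_starts = 2, max_iter = 300)
  yma <- cbind(y[, 1:60], NA, y[, 61:120])
  f2 <- em_fit(spec, yma, n_starts = 2, max_iter = 300)
  expect_equal(f1$phi, f2$phi, tolerance = 1e-2)
  expect_equal(f1$Z, f2$Z, tolerance = 1e-2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-3)
})

test_that("AICc formula, exclusion rule and Akaike weights", {
  expect_equal(aicc(-5, 2, 10), 10 + 4 + 12 / 7)
  expect_equal(aicc(-5, 2, 10), 15.714, tolerance = 1e-3)
  mkfit <- function(ll, k, n) structure(
    list(loglik = ll, n_params = k, n_obs = n, aicc = aicc(ll, k, n),
         phi = 0.5, spec = dfa_spec(1)), class = "dfa_fit")
  cmp <- aicc_and_weights(list(mkfit(-5, 2, 10), mkfit(-5, 2, 10)))
  expect_equal(cmp$weight, c(0.5, 0.5))
  expect_equal(cmp$delta_AICc[1], 0)
  expect_true(all(cmp$weight >= 0 & cmp$weight <= 1))
  expect_equal(sum(cmp$weight), 1)
  # n <= k + 1 is excluded with a warning
  expect_warning(
    cmp2 <- aicc_and_weights(list(mkfit(-5, 2, 10), mkfit(-2, 9, 10))),
    "undefined")
  expect_equal(nrow(cmp2), 1)
  # fits on different data refuse to compare
  expect_error(aicc_and_weights(list(mkfit(-5, 2, 10), mkfit(-5, 2, 12))),
               "identical data")
})

test_that("varimax rotation preserves fits and recovers sparse structure", {
  set.seed(51)
  # m = 1 is the identity
  y <- simulate_regional_indices(simulate_latent_trends(1, 40, .5, seed = 5),
                                 matrix(runif(5, .4, 1), 5, 1), rep(.3, 5),
                                 seed = 6)
  f1 <- em_fit(dfa_spec(1), y, n_starts = 2, max_iter = 200)
  r1 <- rotate_loadings(f1)
  expect_equal(r1$Z, f1$Z)
  expect_equal(r1$xs, f1$xs)
  # m = 2: fitted values invariant to machine precision
  x2 <- simulate_latent_trends(2, 60, c(.4, .7), seed = 7)
  Z2 <- cbind(c(1, 1, 1, 0, 0, 0, .2, .1), c(0, .1, 0, 1, 1, 1, .1, 0))
  y2 <- simulate_regional_indices(x2, Z2, rep(.1, 8), seed = 8)
  f2 <- suppressWarnings(em_fit(dfa_spec(2), y2, n_starts = 3,
                                max_iter = 500))
  r2 <- rotate_loadings(f2)
  expect_lt(max(abs(fitted_dfa(r2) - fitted_dfa(f2))), 1e-10)
  expect_equal(crossprod(r2$rotation), diag(2), tolerance = 1e-12)
  # sign convention: largest-|loading| series of each trend positive
  for (k in 1:2) expect_gt(r2$Z[which.max(abs(r2$Z[, k])), k], 0)
  # varimax recovers an orthogonally mixed sparse pattern up to
  # sign/permutation: compare against the known block structure
  blocks <- apply(abs(r2$Z[1:6, ]), 1, which.max)
  expect_equal(length(unique(blocks[1:3])), 1)
  expect_equal(length(unique(blocks[4:6])), 1)
  expect_true(blocks[1] != blocks[4])
})

test_that("loading intervals: constrained cells NA, widths shrink with T", {
  set.seed(61)
  x <- simulate_latent_trends(2, 150, c(.5, .5), seed = 61)
  Z <- cbind(c(.9, .2, .6, .5, .4, .7), c(0, .8, -.4, .6, -.5, .3))
  y <- simulate_regional_indices(x, Z, rep(.2, 6), seed = 62)
  spec <- dfa_spec(2, "diagonal-equal", "shared")
  fit_long <- suppressWarnings(em_fit(spec, y, n_starts = 2, max_iter = 400))
  ci_long <- loading_cis(fit_long, y)
  # the identifiability-constrained cell (series 1, trend 2) has no interval
  expect_true(is.na(ci_long$se[ci_long$series == 1 & ci_long$trend == 2]))
  expect_true(all(is.finite(
    ci_long$se[!(ci_long$series == 1 & ci_long$trend == 2)])))
  fit_short <- suppressWarnings(
    em_fit(spec, y[, 1:25], n_starts = 2, max_iter = 400))
  ci_short <- loading_cis(fit_short, y[, 1:25])
  expect_lt(median(ci_long$se, na.rm = TRUE),
            median(ci_short$se, na.rm = TRUE))
  # rotation keeps the constrained-cell convention
  ci_rot <- loading_cis(rotate_loadings(fit_long), y)
  expect_true(is.na(ci_rot$se[ci_rot$series == 1 & ci_rot$trend == 2]))
})

test_that("trend CIs: smoothed-state envelopes behave sanely", {
  set.seed(71)
  x <- simulate_latent_trends(1, 50, .6, seed = 71)
  y <- simulate_regional_indices(x, matrix(runif(8, .5, 1), 8, 1),
                                 rep(.25, 8), seed = 72)
  fit <- em_fit(dfa_spec(1), y, n_starts = 2, max_iter = 300)
  expect_true(all(fit$xs_se > 0))
  # ~95% of true states inside the 95% envelope (up to trend sign/scale:
  # regress truth on the estimate first)
  sc <- lm(as.numeric(x) ~ as.numeric(fit$xs))$coefficients
  resid_z <- (as.numeric(x) - sc[1] - sc[2] * as.numeric(fit$xs))
  cover <- mean(abs(resid_z) <= 1.96 * abs(sc[2]) * fit$xs_se)
  expect_gt(cover, 0.8)
})
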