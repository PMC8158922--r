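# two tiny balanced fixtures used across the delta-GLM tests
two_year_fixture <- function(catches_by_year) {
  rows <- lapply(names(catches_by_year), function(y)
    make_hauls(length(catches_by_year[[y]]), year = as.integer(y),
               catch_sby = catches_by_year[[y]]))
  prepare_index_data(do.call(rbind, rows))
}

test_that("positive component recovers saturated year means", {
  d <- two_year_fixture(list(`2004` = c(exp(1), exp(1)),
                             `2005` = c(exp(2), exp(2))))
  fit <- fit_positive_component(d, "Y")
  cf <- coef(fit$fit)
  # sum-to-zero contrasts: year effects are -0.5 / +0.5, difference 1
  expect_equal(unname(cf["year_f1"] - (-cf["year_f1"])), -1, tolerance = 1e-8)
  expect_equal(unname(cf["(Intercept)"]), 1.5, tolerance = 1e-8)
  # intercept-only model equals the grand mean of log positives
  d1 <- droplevels(d[d$year == 2004, ])
  f1 <- fit_positive_component(d1, "Y")   # single year -> intercept only
  expect_equal(unname(coef(f1$fit)["(Intercept)"]), 1, tolerance = 1e-8)
})

test_that("binomial component: saturated p and separation handling", {
  d <- two_year_fixture(list(`2004` = c(1, 1, 1, 0)))
  fit <- fit_binomial_component(d, "Y")
  expect_equal(unname(plogis(coef(fit$fit)["(Intercept)"])), 0.75,
               tolerance = 1e-6)
  # a year with 0/20 positives separates; the penalized refit keeps p
  # finite and small without divergence
  d2 <- two_year_fixture(list(`2004` = rep(1, 20), `2005` = rep(0, 20)))
  fit2 <- suppressWarnings(fit_binomial_component(d2, "Y"))
  expect_true(fit2$separated)
  p <- predict(fit2$fit, newdata = transform(fit2$data,
    year_f = factor("2005", levels = levels(fit2$data$year_f))),
    type = "response")
  expect_true(all(is.finite(p)))
  expect_lt(mean(p), 0.1)
  # degenerate all-positive region: fixed p with warning, no GLM
  d3 <- two_year_fixture(list(`2004` = c(2, 3), `2005` = c(4, 1)))
  expect_warning(f3 <- fit_binomial_component(d3, "Y"), "all-positive")
  expect_equal(f3$p_fixed, 1)
})

test_that("AIC factor selection includes real effects, excludes null ones", {
  # strong period effect, no depth effect; selection rates are checked
  # against the chi-square false-inclusion oracle (a null 1-df factor is
  # spuriously included with prob ~P(chisq_1 > 2) ~= 0.157), using 20
  # scaled-down replicates
  n_rep <- 20
  incl_D <- incl_P <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    n <- 300
    h <- make_hauls(n, year = 2004)
    h$year <- sample(2004:2006, n, replace = TRUE)
    jd <- sample(130:180, n, replace = TRUE)
    h$date <- as.Date(sprintf("2004-01-01")) + jd
    eta <- 1 + 0.4 * (h$year - 2005) + 1.5 * sin(jd / 8)
    h$SBY <- rpois(n, exp(eta))
    h$SBY[h$SBY == 0] <- 1   # keep the positive model saturated
    d <- prepare_index_data(h)
    sel <- suppressWarnings(select_factors_aic(d, c("Y", "D", "P")))
    incl_D[r] <- "D" %in% sel$positive
    incl_P[r] <- "P" %in% sel$positive
  }
  expect_gte(sum(incl_P), 18)          # real effect almost always kept
  expect_gte(sum(!incl_D), 12)         # null effect mostly excluded
  # single candidate subset is returned unchanged
  d <- two_year_fixture(list(`2004` = c(1, 2), `2005` = c(3, 0)))
  expect_equal(select_factors_aic(d, "Y")$positive, "Y")
})

test_that("combine_index composes the hurdle components", {
  # p = 1 everywhere, intercept-only positives: constant exp(mu + s2/2)
  d <- two_year_fixture(list(`2004` = c(2, 8), `2005` = c(2, 8)))
  pos <- fit_positive_component(d, "Y")
  bin <- suppressWarnings(fit_binomial_component(d, "Y"))
  idx <- combine_index(pos, bin, d)
  expect_equal(idx$index[1], idx$index[2])
  expect_equal(idx$index[1], exp(mean(log(c(2, 8))) + pos$sigma2 / 2))
  # halving p halves the index, positive mean unchanged
  d2 <- two_year_fixture(list(`2004` = c(3, 3, 3, 3), `2005` = c(3, 3, 0, 0)))
  pos2 <- fit_positive_component(d2, "Y")
  bin2 <- suppressWarnings(fit_binomial_component(d2, "Y"))
  idx2 <- combine_index(pos2, bin2, d2)
  expect_equal(idx2$p, c(1, 0.5), tolerance = 0.02)
  expect_equal(idx2$index[2] / idx2$index[1], 0.5, tolerance = 0.03)
})

test_that("delta-GLM index equals the per-year brute-force oracle on
          balanced year-only data", {
  set.seed(42)
  catches <- lapply(setNames(nm = 2004:2009), function(y)
    rpois(30, exp(runif(1, 0.5, 3))))
  d <- two_year_fixture(catches)
  pos <- fit_positive_component(d, "Y")
  bin <- suppressWarnings(fit_binomial_component(d, "Y"))
  idx <- combine_index(pos, bin, d)
  for (i in seq_along(catches)) {
    cy <- catches[[i]]
    p_hat <- mean(cy > 0)
    gm <- exp(mean(log(cy[cy > 0])))
    oracle <- p_hat * gm * exp(pos$sigma2 / 2)
    expect_equal(idx$index[i], oracle, tolerance = 0.02)
  }
})

test_that("index is equivariant under catch rescaling", {
  set.seed(5)
  catches <- lapply(setNames(nm = 2004:2007), function(y) rpois(25, 8))
  d <- two_year_fixture(catches)
  d10 <- d
  d10$catch <- d$catch * 10
  i1 <- combine_index(fit_positive_component(d, "Y"),
                      suppressWarnings(fit_binomial_component(d, "Y")), d)
  i10 <- combine_index(fit_positive_component(d10, "Y"),
                       suppressWarnings(fit_binomial_component(d10, "Y")),
                       d10)
  expect_equal(i10$index, 10 * i1$index, tolerance = 1e-8)
})

test_that("year-effect recovery on synthetic hurdle data (2 SE check)", {
  # high baseline keeps integer rounding of the lognormal catches from
  # attenuating the slope (the estimator property, not the stated world)
  sim <- simulate_one_region(hauls_per_year = 200, seed = 11, mu_log = 5)
  res <- suppressWarnings(standardize_region(sim$hauls, select = FALSE))
  ok <- !is.na(res$index)
  # the positive component is linear in the true log abundance: the
  # regression of its marginal year means on the truth recovers the
  # generating log-scale gain within Monte-Carlo error
  s <- summary(lm(res$mu_pos[ok] ~ sim$truth_year[ok]))
  slope <- s$coefficients[2, 1]
  se <- s$coefficients[2, 2]
  expect_lt(abs(slope - sim$cfg$index_log_scale) / se, 3)
  expect_gte(cor(log(res$index[ok]), sim$truth_year[ok],
                 method = "spearman"), 0.9)
})

test_that("zscore_index_matrix applies zeros-to-null then z-scores rows", {
  mk <- function(region, years, index)
    structure(data.frame(region = region, year = years, p = NA, mu_pos = NA,
                         index = index),
              class = c("regional_index", "data.frame"))
  s1 <- mk("A", 2001:2003, c(2, 4, 6))
  m <- zscore_index_matrix(list(s1), years = 2001:2003, log = FALSE)
  expect_equal(unname(m["A", ]), c(-1, 0, 1))
  s2 <- mk("B", 2001:2003, c(0, 4, 6))
  m2 <- zscore_index_matrix(list(s2), years = 2001:2003, log = FALSE)
  expect_equal(unname(m2["B", ]), c(NA, -0.7071, 0.7071), tolerance = 1e-4)
  # log scale by default; any two distinct survivors z to +-0.7071
  m2l <- zscore_index_matrix(list(s2), years = 2001:2003)
  expect_equal(unname(m2l["B", ]), c(NA, -0.7071, 0.7071), tolerance = 1e-4)
  # all-equal rows are dropped with a warning
  s3 <- mk("C", 2001:2003, c(5, 5, 5))
  expect_warning(m3 <- zscore_index_matrix(list(s1, s3), years = 2001:2003),
                 "dropping")
  expect_equal(rownames(m3), "A")
  # row means 0, SD 1 over non-missing entries
  expect_equal(mean(m2l["B", ], na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(m2l["B", ], na.rm = TRUE), 1, tolerance = 1e-12)
})
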