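test_that("log_cpue transform", {
  expect_equal(log_cpue(0), 0)
  expect_equal(log_cpue(exp(1) - 1), 1)
  expect_equal(log_cpue(423), log(424))
  expect_equal(log_cpue(423), 6.0497, tolerance = 1e-4)
  expect_error(log_cpue(-1), "nonnegative")
  # strictly increasing
  expect_true(all(diff(log_cpue(0:100)) > 0))
})

test_that("station_year_mean transforms first then averages", {
  h <- make_hauls(2, catch_sby = c(3, 0))
  sym <- station_year_mean(h)
  expect_equal(sym$mean_log_cpue, (log(4) + log(1)) / 2)
  expect_equal(sym$mean_log_cpue, 0.6931, tolerance = 1e-3)
  # single haul is its own value; permutation invariance
  h2 <- rbind(make_hauls(1, catch_sby = 7),
              make_hauls(3, year = 2005, catch_sby = c(1, 2, 3)))
  a <- station_year_mean(h2)
  b <- station_year_mean(h2[sample(nrow(h2)), ])
  expect_equal(a, b)
  expect_equal(a$mean_log_cpue[a$year == 2004], log(8))
  # Jensen gap: transform-then-average < average-then-transform on
  # dispersed counts
  hd <- make_hauls(2, catch_sby = c(0, 100))
  expect_lt(station_year_mean(hd)$mean_log_cpue, log(mean(c(0, 100)) + 1))
})

test_that("climatology z-score anomalies", {
  sy <- data.frame(station = "S", year = c(2004, 2005, 2006),
                   mean_log_cpue = c(1, 2, 3))
  cf <- climatology_and_anomalies(sy)
  expect_equal(cf$anomalies$z, c(-1, 0, 1))
  expect_equal(cf$stations$climatology, 2)
  # hand-computed two-year case with n-1 denominator
  sy2 <- data.frame(station = "S", year = c(2004, 2005),
                    mean_log_cpue = c(0, 4))
  z2 <- climatology_and_anomalies(sy2)$anomalies$z
  expect_equal(z2, c(-0.7071, 0.7071), tolerance = 1e-4)
  # constant values flagged, anomalies zero
  syc <- data.frame(station = "S", year = 2004:2007, mean_log_cpue = 2)
  cfc <- climatology_and_anomalies(syc)
  expect_true(cfc$stations$zero_sd)
  expect_equal(cfc$anomalies$z, rep(0, 4))
  # single year: anomaly undefined
  sy1 <- data.frame(station = "S", year = 2004, mean_log_cpue = 1)
  expect_true(is.na(climatology_and_anomalies(sy1)$anomalies$z))
  # property: per-station mean 0 / SD 1 over sampled years whenever SD > 0
  set.seed(3)
  syr <- expand.grid(station = paste0("S", 1:6), year = c(2004:2009))
  syr$mean_log_cpue <- rexp(nrow(syr))
  an <- climatology_and_anomalies(syr)$anomalies
  for (s in unique(an$station)) {
    z <- an$z[an$station == s]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
  }
})

test_that("occurrence_frequency counts positive tows per region", {
  h <- make_hauls(4, catch_sby = c(1, 2, 0, 5))
  expect_equal(unname(occurrence_frequency(h)["Monterey"]), 0.75)
  hz <- make_hauls(3, region = "Heceta", lat = 44.0, catch_sby = 0)
  both <- rbind(h, hz)
  f <- occurrence_frequency(both)
  expect_equal(unname(f["Heceta"]), 0)
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
  # monotone under taxon-scope union
  both$WID <- c(0, 0, 1, 0, 1, 0, 0)
  f1 <- occurrence_frequency(both, "SBY")
  f2 <- occurrence_frequency(both, c("SBY", "WID"))
  expect_true(all(f2 >= f1))
})

test_that("group aggregation modes", {
  taxa <- data.frame(taxon_code = c("SBY", "WID"),
                     common_name = c("a", "b"), scientific_name = c("a", "b"),
                     group = c("forage", "target"), linf_cm = c(20, 40))
  h <- make_hauls(3, catch_sby = c(2, 0, 0))
  h$WID <- c(2, 0, 3)
  expect_equal(group_aggregate(h, taxa, "ratio"), c(0.5, NA, 1))
  expect_equal(group_aggregate(h, taxa, "target"), log(c(3, 1, 4)))
  expect_equal(group_aggregate(h, taxa, "forage"), log(c(3, 1, 1)))
  # L-infinity weighting: counts 1 and 1, Linf 40/20, mean 30 -> ln 3
  h1 <- make_hauls(1, catch_sby = 1)
  h1$WID <- 1
  expect_equal(group_aggregate(h1, taxa, "linf"), log(3))
  # unknown taxon in scope errors
  h$XXX <- 1
  expect_error(group_aggregate(h, taxa, "target"), "registry")
})

test_that("IDW interpolation", {
  # hand example: two points valued 0 and 1, the node twice as far from
  # the second, power 2 -> weights 4:1 -> 0.2
  pts <- data.frame(latitude = c(36.1, 36.4), longitude = -122,
                    value = c(0, 1))
  node <- data.frame(latitude = 36.2, longitude = -122)
  s <- idw_surface(pts, grid = node, k = 2, power = 2)
  expect_equal(s$value, 0.2, tolerance = 1e-6)
  # node at a station returns the station value
  s2 <- idw_surface(pts, grid = pts[2, 1:2], k = 2)
  expect_equal(s2$value, 1)
  # constant field stays constant; bounded by the local range; order
  # invariant
  set.seed(1)
  pts3 <- data.frame(latitude = runif(12, 36, 37),
                     longitude = runif(12, -123, -122),
                     value = rnorm(12))
  grid <- expand.grid(latitude = seq(36, 37, 0.2),
                      longitude = seq(-123, -122, 0.2))
  sa <- idw_surface(pts3, grid, k = 5)
  sb <- idw_surface(pts3[sample(12), ], grid, k = 5)
  expect_equal(sa$value, sb$value)
  expect_true(all(sa$value >= min(pts3$value) &
                    sa$value <= max(pts3$value), na.rm = TRUE))
  pts3$value <- 2.5
  expect_true(all(abs(idw_surface(pts3, grid, k = 5)$value - 2.5) < 1e-12,
                  na.rm = TRUE))
  # masking and argument validation
  far <- data.frame(latitude = 40, longitude = -122)
  expect_true(is.na(idw_surface(pts3, far, k = 5)$value))
  expect_error(idw_surface(pts3[1:3, ], grid, k = 5), "at least")
})
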