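# shared fixtures and the independent dense-Gaussian likelihood oracle

# independent oracle for the DFA log-likelihood: build the joint covariance
# of the stacked observation vector directly from the state recursion and
# evaluate the multivariate normal log-density of the observed cells
dense_dfa_loglik <- function(y, Z, rdiag, phi, P1) {
  n <- nrow(y); Tn <- ncol(y); m <- ncol(Z)
  Phi <- diag(phi, m)
  Vs <- vector("list", Tn)
  Vs[[1]] <- P1
  if (Tn > 1)
    for (t in 2:Tn) Vs[[t]] <- Phi %*% Vs[[t - 1]] %*% t(Phi) + diag(1, m)
  powPhi <- function(k) {
    P <- diag(1, m)
    if (k > 0) for (i in seq_len(k)) P <- Phi %*% P
    P
  }
  C <- matrix(0, n * Tn, n * Tn)
  for (t in 1:Tn) for (s in 1:Tn) {
    Cxx <- if (t >= s) powPhi(t - s) %*% Vs[[s]]
           else Vs[[t]] %*% t(powPhi(s - t))
    C[(t - 1) * n + 1:n, (s - 1) * n + 1:n] <- Z %*% Cxx %*% t(Z)
  }
  C <- C + diag(rep(rdiag, Tn))
  yv <- as.vector(y)
  obs <- !is.na(yv)
  Co <- C[obs, obs]
  yo <- yv[obs]
  as.numeric(-0.5 * (length(yo) * log(2 * pi) +
                       determinant(Co)$modulus + t(yo) %*% solve(Co, yo)))
}

# stationary / diffuse initial state variance matching the package rule
oracle_P1 <- function(phi) diag(ifelse(abs(phi) < 1, 1 / (1 - phi^2), 5),
                                length(phi))

# sample() that never unpacks a scalar into 1:x
sample_one <- function(x) if (length(x) == 1) x else sample(x, 1)

# random constrained parameters for a given spec / dimension
random_dfa_params <- function(spec, n) {
  m <- spec$m
  Z <- matrix(rnorm(n * m, sd = 0.7), n, m)
  for (i in seq_len(min(n, m))) if (i < m) Z[i, (i + 1):m] <- 0
  rdiag <- if (spec$R_structure == "diagonal-equal")
    rep(runif(1, 0.2, 0.8), n) else runif(n, 0.2, 0.8)
  phi <- switch(spec$phi_structure,
                "shared" = rep(runif(1, -0.8, 0.9), m),
                "per-trend" = runif(m, -0.8, 0.9),
                "fixed-one" = rep(1, m))
  list(Z = Z, rdiag = rdiag, phi = phi)
}

# a small wide-format haul CSV on disk; returns the path
write_toy_haul_csv <- function(rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      haul_id = c("H1", "H2", "H3"), survey = "RREAS",
      year = c(2004, 2004, 2005), date = c("2004-05-20", "2004-05-21",
                                           "2005-06-01"),
      latitude = c(36.7, 36.8, 36.75), longitude = c(-122.0, -122.1, -122.05),
      bottom_depth = c(80, 120, 100), station = c("M_1", "M_2", "M_1"),
      region = "Monterey", SBY = c(3, 0, 10), WID = c(1, 4, 0),
      stringsAsFactors = FALSE)
  }
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  f
}

# small in-memory haul table without touching disk
make_hauls <- function(n = 20, region = "Monterey", year = 2004,
                       station = "M_1", catch_sby = NULL, lat = 36.7) {
  if (is.null(catch_sby)) catch_sby <- rep(1, n)
  data.frame(
    haul_id = sprintf("%s_%d_%03d", region, year, seq_len(n)),
    survey = "RREAS", year = year,
    date = as.Date(sprintf("%d-05-20", year)) + seq_len(n) %% 20,
    latitude = lat + runif(n, -0.1, 0.1),
    longitude = -122 + runif(n, -0.1, 0.1),
    bottom_depth = sample(c(60, 150), n, replace = TRUE),
    station = station, region = region, SBY = catch_sby,
    stringsAsFactors = FALSE)
}

# single-region hurdle simulation with known year effects, used by the
# delta-GLM recovery tests (the index-module stated design: n hauls/year,
# 19 years, default noise levels)
simulate_one_region <- function(hauls_per_year = 200, years = 2001:2019,
                                seed = 1, mu_log = NULL) {
  cfg <- scenario_default()
  cfg$regions <- "Monterey"
  cfg$hauls_mean <- c(Monterey = hauls_per_year)
  cfg$missing_years <- list(Monterey = integer())
  cfg$years <- years
  if (!is.null(mu_log)) cfg$mu_log <- c(Monterey = mu_log)
  x <- simulate_latent_trends(1, length(years), cfg$phi_true, seed = seed)
  y <- matrix(x, 1, length(years),
              dimnames = list("Monterey", years))
  hauls <- simulate_hauls(y, cfg, seed = seed + 1)
  list(hauls = hauls, truth_year = y[1, ], cfg = cfg)
}
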