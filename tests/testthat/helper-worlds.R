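# shared simulated worlds, built once per test run and memoised

.world_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- force(expr)
  .world_cache[[key]]
}

# tiny fast world: one short season, coarse rasters
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_seasons = 1L,
             extent_north = c(0, 60), zone_split_north = 30,
             images_per_semimonth = 4L,
             flights_south = 4L, flights_north = 2L, ...)
}

# the standard two-season test world: cold vs warm anomaly contrast
# (a cold 2009/10-like vs a warm 2011/12-like winter), ~5000 units
std_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_seasons = 2L,
             sst_anomaly_per_season = c(-1.5, 1.5), ...)
}

std_world <- function() {
  memo("std_world", {
    cfg <- std_config()
    env <- generate_environment(cfg)
    truth <- generate_whales(env, cfg)
    surveys <- generate_surveys(truth, env, cfg)
    grid <- attr(truth, "grid")
    filtered <- filter_on_effort(surveys$segments, surveys$sightings)
    detections <- fit_detection_by_platform(filtered$sightings,
                                            truncation = 3)
    units <- aggregate_units(filtered$segments, filtered$sightings,
                             detections, grid)
    units <- add_unit_covariates(units, env, grid)
    list(cfg = cfg, env = env, truth = truth, surveys = surveys,
         grid = grid, filtered = filtered, detections = detections,
         units = units)
  })
}

std_hurdle <- function() {
  memo("std_hurdle", fit_hurdle(std_world()$units))
}

# truth row lookup aligned to a units/prediction table
truth_match <- function(truth, tab) {
  match(paste(tab$cell_id, tab$season_start_year, tab$semimonth),
        paste(truth$cell_id, truth$season_start_year, truth$semimonth))
}

# independent textbook IRLS (Fisher scoring) for unpenalized GLMs
irls_glm <- function(X, y, fam, tol = 1e-13, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    w <- as.vector(fam$mu.eta(eta)^2 / fam$variance(mu))
    z <- eta + (y - mu) / fam$mu.eta(eta)
    beta_new <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
    done <- max(abs(beta_new - beta)) < tol
    beta <- beta_new
    if (done) break
  }
  beta
}

# half-normal detection distances on [0, W]: rejection sampling
rhalfnorm_trunc <- function(n, sigma, W) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- abs(stats::rnorm(2 * n, 0, sigma))
    out <- c(out, x[x <= W])
  }
  out[seq_len(n)]
}

# simulate detected perpendicular distances under the conditional
# line-transect likelihood (uniform exposure, half-normal detection)
sim_detections <- function(n, b0, b1, W, seastates = 0:3) {
  z <- sample(seastates, n, replace = TRUE)
  sigma <- exp(b0 + b1 * z)
  x <- vapply(sigma, function(s) rhalfnorm_trunc(1, s, W), numeric(1))
  data.frame(perp_distance_km = x, seastate = z)
}
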