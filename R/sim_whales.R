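#' Generate the latent whale distribution (ground truth)
#'
#' Computes, for every sampling-grid cell and semimonthly period, the
#' latent occurrence probability and expected group size, then realises
#' whale groups. The occurrence logit is a sum of the configured smooth
#' responses:
#' \itemize{
#'   \item SST: unimodal Gaussian bump peaking at `sst_peak` (whales
#'     favour intermediate winter temperatures);
#'   \item distance to shore: exponential decay (whales concentrate
#'     nearshore);
#'   \item depth: unimodal around `depth_peak` m;
#'   \item signed distance to the 22 C isotherm: increases to a plateau
#'     (avoidance of Gulf Stream water);
#'   \item a semimonth-by-northing migration term placing whales
#'     farther north at the start and end of the season and farther
#'     south at mid-season;
#'   \item a per-season intercept (interannual variation in the number
#'     of migrants).
#' }
#' Positive group sizes are drawn as `1 + Poisson(m - 1)` where the mean
#' `m` is coupled to the same summed habitat response (better habitat
#' holds slightly larger groups, so the abundance component of the
#' hurdle sees the same covariate shapes as occurrence); each occupied
#' cell-period holds one
#' group placed uniformly inside the cell, flagged as a cow-calf pair
#' with probability `calf_fraction`.
#'
#' @param env an [generate_environment()] result.
#' @param config the matching [sim_config()].
#' @return Data frame of class `rw_truth`, one row per cell x season x
#'   semimonth, with latent (`p_occ`, `mu_pos`, `expected_whales`) and
#'   realised (`n_whales`, group position/size/calf) fields plus the
#'   true cell covariates. Attributes: `grid` (the sampling grid) and
#'   `curves` (the true response curves on dense covariate grids).
#' @export
generate_whales <- function(env, config = env$config) {
  set.seed(config$seed + 1L)
  grid <- build_grid(config$extent_east, config$extent_north,
                     config$zone_split_north, config$cell_size_south,
                     config$cell_size_north, config$north_azimuth)
  ef <- config$true_effects
  map <- pixel_cell_map(env$bathy, grid)
  dep <- cell_raster_mean(env$bathy, grid, grid$cell_id, map)
  dsh <- distance_to_shore(grid$cx, grid$cy, env$shoreline)
  y_mid <- mean(config$extent_north)
  n_half <- diff(config$extent_north) / 2
  season_int <- rep_len(ef$season_intercepts, config$n_seasons)

  rows <- list()
  for (s in seq_len(config$n_seasons)) {
    year <- config$first_season_year + s - 1L
    for (sm in 1:8) {
      sst_r <- true_semimonth_sst(env, year, sm)
      sstc <- cell_raster_mean(sst_r, grid, grid$cell_id, map)
      iso <- extract_isotherm(sst_r, 22)
      diso <- if (nrow(iso)) {
        isotherm_distance(grid$cx, grid$cy, sstc, iso, 22)
      } else rep(150, nrow(grid))   # no isotherm: plateau distance
      f_resp <- ef$sst_amp * exp(-(sstc - ef$sst_peak)^2 /
                                   (2 * ef$sst_sd^2)) +
        ef$shore_amp * exp(-dsh / ef$shore_scale) +
        ef$depth_amp * exp(-(dep - ef$depth_peak)^2 / (2 * ef$depth_sd^2)) +
        ef$iso_amp * tanh(diso / ef$iso_scale) +
        ef$mig_amp * ((grid$cy - y_mid) / n_half) * cos(2 * pi * (sm - 1) / 7)
      eta <- ef$intercept + season_int[s] + f_resp
      # cells without covariate coverage (edge cells outside the raster)
      # hold no whales
      p <- stats::plogis(eta)
      p[is.na(p)] <- 0
      # better habitat holds slightly larger groups: the abundance
      # component shares the occurrence component's covariate shapes;
      # 5 is the typical response level of occupied cells, so the
      # occupied-cell mean group size matches group_size_mean
      m_pos <- 1 + (config$group_size_mean - 1) *
        exp(config$abundance_gain * (f_resp - 5))
      m_pos[is.na(m_pos)] <- 1.01
      present <- stats::rbinom(nrow(grid), 1L, p)
      size <- ifelse(present == 1L,
                     1L + stats::rpois(nrow(grid), m_pos - 1), 0L)
      uoff <- stats::runif(nrow(grid)); voff <- stats::runif(nrow(grid))
      calf <- stats::rbinom(nrow(grid), 1L, config$calf_fraction) == 1L
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = grid$cell_id, season_start_year = year,
        season = paste0(year, "/", year + 1L), semimonth = sm,
        sst_true = sstc, depth_m = dep, dist_shore_km = dsh,
        dist_iso_km = diso, northing_km = grid$cy, easting_km = grid$cx,
        p_occ = p, mu_pos = m_pos, expected_whales = p * m_pos,
        n_whales = size,
        group_u = uoff, group_v = voff,
        group_size = size, calf_present = present == 1L & calf,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  # group positions: uniform within the cell polygon
  gi <- match(truth$cell_id, grid$cell_id)
  geom <- grid_geometry(grid)
  u <- (grid$col[gi] - 1 + truth$group_u) * grid$size[gi]
  v <- (grid$row[gi] - 1 + truth$group_v) * grid$size[gi]
  south <- grid$zone[gi] == "S"
  truth$group_x <- ifelse(south, geom$extent_east[1] + u,
                          geom$origin[1] + u * geom$along[1] +
                            v * geom$perp[1])
  truth$group_y <- ifelse(south, geom$extent_north[1] + v,
                          geom$origin[2] + u * geom$along[2] +
                            v * geom$perp[2])
  # edge cells extend slightly past the study area: keep groups inside
  truth$group_x <- pmin(pmax(truth$group_x, config$extent_east[1] + 1e-6),
                        config$extent_east[2] - 1e-6)
  truth$group_y <- pmin(pmax(truth$group_y, config$extent_north[1] + 1e-6),
                        config$extent_north[2] - 1e-6)
  truth$group_x[truth$n_whales == 0L] <- NA_real_
  truth$group_y[truth$n_whales == 0L] <- NA_real_
  truth$group_u <- truth$group_v <- NULL

  sst_grid <- seq(6, 26, length.out = 201)
  dsh_grid <- seq(0, diff(config$extent_east), length.out = 201)
  dep_grid <- seq(0, config$shelf_max_depth_m, length.out = 201)
  iso_grid <- seq(-50, 150, length.out = 201)
  attr(truth, "curves") <- list(
    sst = data.frame(x = sst_grid,
                     f = ef$sst_amp * exp(-(sst_grid - ef$sst_peak)^2 /
                                            (2 * ef$sst_sd^2))),
    dist_shore = data.frame(x = dsh_grid,
                            f = ef$shore_amp * exp(-dsh_grid / ef$shore_scale)),
    depth = data.frame(x = dep_grid,
                       f = ef$depth_amp *
                         exp(-(dep_grid - ef$depth_peak)^2 /
                               (2 * ef$depth_sd^2))),
    dist_iso = data.frame(x = iso_grid,
                          f = ef$iso_amp * tanh(iso_grid / ef$iso_scale))
  )
  attr(truth, "grid") <- grid
  class(truth) <- c("rw_truth", "data.frame")
  truth
}
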