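#' Generate the synthetic coastal environment
#'
#' Builds the environmental fields the survey pipeline consumes: a
#' bathymetry raster whose depth increases monotonically offshore up to
#' the shelf maximum, a shoreline polyline along the western edge, and a
#' stack of daily SST images with spatially coherent cloud masks. The
#' SST field is the sum of a seasonal base curve (coldest at
#' mid-season), a per-season anomaly, a north-south cooling gradient, a
#' warm offshore band standing in for the Gulf Stream (exceeding 22 C
#' inside the band), and smooth random noise.
#'
#' @param config an [sim_config()] object.
#' @return A list of class `rw_environment`: `x`, `y` pixel centres,
#'   `bathy` ([raster_grid()]), `shoreline` (vertex matrix), `images`
#'   (list of daily SST images with `season_start_year`, `semimonth`,
#'   `date`, `values`, `cloud`), and the `config`.
#' @export
generate_environment <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  px <- config$pixel_km
  x <- seq(config$extent_east[1] + px / 2,
           config$extent_east[2] + config$raster_margin_east_km, by = px)
  y <- seq(config$extent_north[1] + px / 2, config$extent_north[2], by = px)

  # shelf bathymetry: offshore deepening (monotone in x at every
  # northing), slightly above sea level at the coast so the
  # above-sea-level exclusion rule has work, with along-shore ripple so
  # depth is not an exact function of distance to shore (real shelves
  # are not; perfectly collinear covariates would make the habitat
  # model unidentifiable)
  ramp <- (x - config$extent_east[1]) / diff(config$extent_east)
  ripple <- 1 + 0.35 * sin(2 * pi * y / 80 + 1)
  depth_m <- -2 + (config$shelf_max_depth_m + 2) * outer(ramp, ripple)
  bathy <- raster_grid(x, y, depth_m)

  # gently sinuous coast (capes and bights) so distance to shore is not
  # an exact linear function of easting
  sy <- seq(config$extent_north[1], config$extent_north[2],
            length.out = 49)
  shoreline <- cbind(
    x = config$extent_east[1] + 2.5 * (1 + sin(2 * pi * sy / 120)),
    y = sy)

  band <- config$gulf_stream_amp *
    exp(-(x - config$gulf_stream_offset_km)^2 /
          (2 * max(config$gulf_stream_width_km, 1e-6)^2))
  if (config$gulf_stream_width_km == 0) band <- rep(0, length(x))
  lat_term <- -config$lat_gradient * (y - config$extent_north[1])
  spatial <- outer(band, rep(1, length(y))) +
    outer(rep(1, length(x)), lat_term)

  images <- list()
  for (s in seq_len(config$n_seasons)) {
    year <- config$first_season_year + s - 1L
    periods <- semimonth_periods(year)
    anom <- config$sst_anomaly_per_season[s]
    for (p in seq_len(nrow(periods))) {
      days <- seq(periods$start[p], periods$end[p], by = "day")
      n_img <- min(config$images_per_semimonth, length(days))
      pick <- sort(sample(seq_along(days), n_img))
      for (d in pick) {
        t <- day_of_season(days[d], year)
        base <- config$sst_base_start -
          config$sst_mid_drop * sin(pi * (t - 1) / 120)
        noise <- config$sst_noise_sd *
          smooth_field(x, y, config$sst_noise_scale_km)
        values <- base + anom + spatial + noise
        cloud <- if (config$cloud_fraction <= 0) {
          matrix(FALSE, length(x), length(y))
        } else {
          f <- smooth_field(x, y, config$sst_noise_scale_km)
          f < stats::quantile(f, config$cloud_fraction)
        }
        images[[length(images) + 1L]] <- list(
          season_start_year = year, semimonth = periods$semimonth[p],
          date = days[d], x = x, y = y, values = values, cloud = cloud)
      }
    }
  }
  structure(list(x = x, y = y, bathy = bathy, shoreline = shoreline,
                 images = images, config = config),
            class = "rw_environment")
}

# smooth unit-variance random field: iid gaussian on a coarse lattice,
# bilinearly interpolated to the pixel grid
smooth_field <- function(x, y, scale_km) {
  cx <- seq(min(x) - scale_km, max(x) + scale_km, by = scale_km)
  cy <- seq(min(y) - scale_km, max(y) + scale_km, by = scale_km)
  w <- matrix(stats::rnorm(length(cx) * length(cy)),
              length(cx), length(cy))
  ix <- findInterval(x, cx, rightmost.closed = TRUE)
  iy <- findInterval(y, cy, rightmost.closed = TRUE)
  tx <- (x - cx[ix]) / scale_km
  ty <- (y - cy[iy]) / scale_km
  f <- matrix(0, length(x), length(y))
  for (j in seq_along(y)) {
    j0 <- iy[j]; t2 <- ty[j]
    f[, j] <- (1 - tx) * (1 - t2) * w[cbind(ix, j0)] +
      tx * (1 - t2) * w[cbind(ix + 1L, j0)] +
      (1 - tx) * t2 * w[cbind(ix, j0 + 1L)] +
      tx * t2 * w[cbind(ix + 1L, j0 + 1L)]
  }
  sf <- stats::sd(f)
  if (sf > 0) f / sf else f
}

# true (cloud-free) semimonthly mean SST raster for one season x period
true_semimonth_sst <- function(env, season_start_year, semimonth) {
  sel <- vapply(env$images, function(im) {
    im$season_start_year == season_start_year && im$semimonth == semimonth
  }, logical(1))
  if (!any(sel)) stop("no daily images for the requested period")
  vals <- lapply(env$images[sel], `[[`, "values")
  raster_grid(env$x, env$y, Reduce(`+`, vals) / length(vals))
}
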