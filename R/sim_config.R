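#' Configuration for the synthetic wintering-ground survey generator
#'
#' Builds the complete parameter set that defines the simulated world:
#' study-area geometry, seasonal sea-surface-temperature dynamics with a
#' warm offshore band standing in for the Gulf Stream, the latent whale
#' response to environment and migration timing, and the aerial-survey
#' observation process (platforms, sea state, half-normal detection).
#'
#' Defaults emulate the conditions of the southeastern US calving ground
#' surveys: east-west transects spaced 5.56 km in the southern zone,
#' northwest-southeast transects spaced 7.52 km in the north, winter
#' (December--March) SST between roughly 10 and 18 C inshore with a
#' band exceeding 22 C offshore, ten survey seasons, and per-platform
#' detection scales yielding effective search widths of about
#' 1.3--2.2 km across Beaufort sea states 0--3.
#'
#' @param seed integer seed; a fixed config (including seed) reproduces
#'   byte-identical simulator output.
#' @param n_seasons number of survey seasons (December--March periods).
#' @param first_season_year calendar year of the first season's December.
#' @param extent_east,extent_north study-area extent, projected km.
#' @param zone_split_north northing (km) separating the southern
#'   east-west zone from the northern rotated zone.
#' @param cell_size_south,cell_size_north grid cell sizes (km).
#' @param north_azimuth azimuth (degrees clockwise from north) of the
#'   northern-zone transects (135 = northwest-southeast).
#' @param pixel_km environmental raster resolution (km).
#' @param raster_margin_east_km how far the environmental rasters extend
#'   east (offshore) of the surveyed study area; satellite imagery
#'   covers more ocean than the transects, and the warm band sits out
#'   there.
#' @param sst_base_start,sst_mid_drop seasonal SST curve: inshore
#'   southern SST starts at `sst_base_start` C and dips by
#'   `sst_mid_drop` C at mid-season.
#' @param sst_anomaly_per_season per-season SST offsets (C), recycled or
#'   truncated to `n_seasons`.
#' @param lat_gradient cooling rate with northing (C per km).
#' @param gulf_stream_offset_km,gulf_stream_width_km,gulf_stream_amp
#'   centre (km offshore), Gaussian width (km) and amplitude (C) of the
#'   warm offshore band.
#' @param sst_noise_sd,sst_noise_scale_km standard deviation (C) and
#'   correlation scale (km) of the smooth SST noise field.
#' @param cloud_fraction expected fraction of pixels cloud-masked per
#'   daily image, in \[0, 1\].
#' @param images_per_semimonth daily SST images generated per semimonth.
#' @param shelf_max_depth_m maximum shelf depth at the offshore edge (m).
#' @param true_effects named list of latent-response parameters; see
#'   [generate_whales()] for the meaning of each element.
#' @param detection named list with per-platform coefficients
#'   `c(b0, b1)` of the log detection scale
#'   `sigma = exp(b0 + b1 * seastate)`, and `truncation_km`.
#' @param group_size_mean mean whale-group size (groups are drawn as
#'   `1 + Poisson(mean - 1)`).
#' @param abundance_gain coupling of the mean positive group size to
#'   the latent habitat response: `m = 1 + (group_size_mean - 1) *
#'   exp(gain * (f - f_ref))` with `f` the summed covariate responses,
#'   so better habitat holds slightly larger groups (the abundance
#'   component sees the same habitat shapes as occurrence).
#' @param calf_fraction probability that a group is a cow-calf pair.
#' @param flights_south,flights_north surveys flown per semimonth in
#'   each zone.
#' @param bad_flight_rate fraction of flights flown in conditions that
#'   violate an on-effort rule (exercises the filters).
#' @param duplicate_rate,verification_rate,offeffort_sighting_rate
#'   injection rates for flagged duplicate records, verification
#'   surveys, and sightings whose initial status was off-effort.
#'
#' @return An object of class `rw_sim_config` (a named list).
#' @export
sim_config <- function(seed = 1L,
                       n_seasons = 10L,
                       first_season_year = 2003L,
                       extent_east = c(0, 55.6),
                       extent_north = c(0, 240),
                       zone_split_north = 120,
                       cell_size_south = 5.56,
                       cell_size_north = 7.52,
                       north_azimuth = 135,
                       pixel_km = 2.78,
                       raster_margin_east_km = 30,
                       sst_base_start = 17,
                       sst_mid_drop = 3,
                       sst_anomaly_per_season = c(0.6, 0.2, -0.3, 0.4,
                                                  -0.6, 0.3, -1.5, 0.1,
                                                  1.5, -0.4),
                       lat_gradient = 0.0125,
                       gulf_stream_offset_km = 70,
                       gulf_stream_width_km = 12,
                       gulf_stream_amp = 12,
                       sst_noise_sd = 1.0,
                       sst_noise_scale_km = 20,
                       cloud_fraction = 0.3,
                       images_per_semimonth = 8L,
                       shelf_max_depth_m = 45,
                       true_effects = list(),
                       detection = list(),
                       group_size_mean = 2.24,
                       abundance_gain = 0.35,
                       calf_fraction = 0.41,
                       flights_south = 18L,
                       flights_north = 5L,
                       bad_flight_rate = 0.08,
                       duplicate_rate = 0.04,
                       verification_rate = 0.03,
                       offeffort_sighting_rate = 0.03) {
  eff_default <- list(
    intercept = -7.6,
    season_intercepts = c(0.3, 0, -0.2, 0.1, 0.6, 0.5, 0.4, -0.1, -0.9, 0),
    sst_peak = 14, sst_sd = 2.5, sst_amp = 2.5,
    shore_scale = 25, shore_amp = 2,
    depth_peak = 18, depth_sd = 12, depth_amp = 1,
    iso_scale = 40, iso_amp = 1.5,
    mig_amp = 1
  )
  det_default <- list(
    Skymaster = c(b0 = 0.35, b1 = -0.10),
    TwinOtter = c(b0 = 0.45, b1 = -0.10),
    truncation_km = 3
  )
  true_effects <- utils::modifyList(eff_default, true_effects)
  detection <- utils::modifyList(det_default, detection)

  cfg <- list(
    seed = as.integer(seed), n_seasons = as.integer(n_seasons),
    first_season_year = as.integer(first_season_year),
    extent_east = extent_east, extent_north = extent_north,
    zone_split_north = zone_split_north,
    cell_size_south = cell_size_south, cell_size_north = cell_size_north,
    north_azimuth = north_azimuth, pixel_km = pixel_km,
    raster_margin_east_km = raster_margin_east_km,
    sst_base_start = sst_base_start, sst_mid_drop = sst_mid_drop,
    sst_anomaly_per_season = rep_len(sst_anomaly_per_season, n_seasons),
    lat_gradient = lat_gradient,
    gulf_stream_offset_km = gulf_stream_offset_km,
    gulf_stream_width_km = gulf_stream_width_km,
    gulf_stream_amp = gulf_stream_amp,
    sst_noise_sd = sst_noise_sd, sst_noise_scale_km = sst_noise_scale_km,
    cloud_fraction = cloud_fraction,
    images_per_semimonth = as.integer(images_per_semimonth),
    shelf_max_depth_m = shelf_max_depth_m,
    true_effects = true_effects, detection = detection,
    group_size_mean = group_size_mean,
    abundance_gain = abundance_gain,
    calf_fraction = calf_fraction,
    flights_south = as.integer(flights_south),
    flights_north = as.integer(flights_north),
    bad_flight_rate = bad_flight_rate,
    duplicate_rate = duplicate_rate,
    verification_rate = verification_rate,
    offeffort_sighting_rate = offeffort_sighting_rate
  )
  validate_sim_config(cfg)
  class(cfg) <- "rw_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num <- unlist(cfg[c("extent_east", "extent_north", "zone_split_north",
                      "cell_size_south", "cell_size_north", "pixel_km",
                      "sst_base_start", "sst_mid_drop",
                      "sst_anomaly_per_season", "lat_gradient",
                      "gulf_stream_offset_km", "gulf_stream_width_km",
                      "gulf_stream_amp", "cloud_fraction",
                      "shelf_max_depth_m", "group_size_mean",
                      "calf_fraction")])
  if (any(!is.finite(num)))
    stop("non-finite value in simulator configuration")
  if (cfg$cloud_fraction < 0 || cfg$cloud_fraction > 1)
    stop("cloud_fraction must lie in [0, 1]")
  if (cfg$gulf_stream_width_km < 0)
    stop("gulf_stream_width_km must be >= 0")
  if (cfg$cell_size_south <= 0 || cfg$cell_size_north <= 0 ||
      cfg$pixel_km <= 0)
    stop("grid and pixel sizes must be positive")
  if (cfg$detection$truncation_km <= 0)
    stop("detection truncation distance must be positive")
  if (cfg$n_seasons < 1) stop("need at least one season")
  invisible(cfg)
}

#' @export
print.rw_sim_config <- function(x, ...) {
  cat("Synthetic wintering-ground survey configuration\n")
  cat(sprintf("  seasons: %d (starting %d/%d), seed %d\n", x$n_seasons,
              x$first_season_year, x$first_season_year + 1L, x$seed))
  cat(sprintf("  area: %.1f x %.1f km, zone split at %.1f km north\n",
              diff(x$extent_east), diff(x$extent_north),
              x$zone_split_north))
  cat(sprintf("  SST: base %.1f C (mid-season dip %.1f), warm band +%.1f C at %.0f km offshore\n",
              x$sst_base_start, x$sst_mid_drop, x$gulf_stream_amp,
              x$gulf_stream_offset_km))
  cat(sprintf("  cloud fraction %.2f, %d images per semimonth\n",
              x$cloud_fraction, x$images_per_semimonth))
  invisible(x)
}
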