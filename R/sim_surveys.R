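#' Generate detection-thinned aerial surveys
#'
#' Simulates the observation process over the latent truth: per
#' semimonth, a configured number of flights covers each zone's fixed
#' track lines (east-west in the south, northwest-southeast in the
#' north). Each flight carries a platform, date, sea state, altitude and
#' visibility; a configured fraction of flights is flown in conditions
#' violating one on-effort rule. Every whale group within the truncation
#' distance of a flown track line is detected with probability
#' `exp(-d^2 / (2 sigma^2))` where `sigma = exp(b0_platform +
#' b1 * seastate)`. Detected groups yield sighting records with the
#' recorded perpendicular distance and calf flag; duplicate,
#' verification-survey and off-effort-at-first-detection records are
#' injected at fixed configured rates so downstream filter accounting is
#' predictable.
#'
#' @param truth an [generate_whales()] result.
#' @param env the matching environment.
#' @param config the matching [sim_config()].
#' @return List of class `rw_surveys` with `segments` and `sightings`
#'   data frames (schemas documented in [read_segments()] /
#'   [read_sightings()]).
#' @export
generate_surveys <- function(truth, env, config = env$config) {
  if (config$detection$truncation_km <= 0)
    stop("truncation distance must be positive")
  set.seed(config$seed + 2L)
  grid <- attr(truth, "grid")
  geom <- grid_geometry(grid)
  tr <- transects(grid)
  W <- config$detection$truncation_km

  seg_rows <- list(); sgt_rows <- list()
  seg_n <- 0L; sgt_n <- 0L
  add_seg <- function(df) { seg_rows[[length(seg_rows) + 1L]] <<- df }
  add_sgt <- function(df) { sgt_rows[[length(sgt_rows) + 1L]] <<- df }

  for (s in seq_len(config$n_seasons)) {
    year <- config$first_season_year + s - 1L
    periods <- semimonth_periods(year)
    for (sm in 1:8) {
      days <- seq(periods$start[sm], periods$end[sm], by = "day")
      groups <- truth[truth$season_start_year == year &
                        truth$semimonth == sm & truth$n_whales > 0L, ]
      if (nrow(groups)) {
        gz <- grid$zone[match(groups$cell_id, grid$cell_id)]
        guv <- point_uv(geom, groups$group_x, groups$group_y)
      }
      zones <- c(rep("S", config$flights_south),
                 rep("N", config$flights_north))
      platforms <- ifelse(zones == "S",
                          rep(c("Skymaster", "TwinOtter"),
                              length.out = config$flights_south),
                          "Skymaster")
      for (f in seq_along(zones)) {
        zone <- zones[f]
        platform <- platforms[f]
        date <- days[sample.int(length(days), 1L)]
        seastate <- sample(0:3, 1L, prob = c(0.2, 0.3, 0.3, 0.2))
        altitude <- round(stats::rnorm(1, 305, 12))
        visibility <- round(stats::runif(1, 4, 10), 1)
        if (stats::runif(1) < config$bad_flight_rate) {
          bad <- sample(c("seastate", "altitude", "visibility"), 1L)
          if (bad == "seastate") seastate <- 4L
          if (bad == "altitude") altitude <- 380
          if (bad == "visibility") visibility <- 3.0
        }
        survey_id <- sprintf("%d-%02d-%s%d", year, sm, zone, f)
        tz <- tr[tr$zone == zone, , drop = FALSE]
        # transit leg from the coast to the first transect
        add_seg(data.frame(
          survey_id = survey_id, platform = platform, date = date,
          x0 = tz$x0[1], y0 = max(tz$y0[1] - 2, geom$extent_north[1]),
          x1 = tz$x0[1], y1 = tz$y0[1],
          seastate = seastate, altitude_m = altitude,
          visibility_km = visibility, status = "transit",
          is_verification = FALSE, stringsAsFactors = FALSE))
        add_seg(data.frame(
          survey_id = survey_id, platform = platform, date = date,
          x0 = tz$x0, y0 = tz$y0, x1 = tz$x1, y1 = tz$y1,
          seastate = seastate, altitude_m = altitude,
          visibility_km = visibility, status = "on_transect",
          is_verification = FALSE, stringsAsFactors = FALSE))
        if (!nrow(groups)) next
        inz <- which(gz == zone)
        if (!length(inz)) next
        # perpendicular distance to the transect bisecting the group's
        # cell row
        row_g <- grid$row[match(groups$cell_id[inz], grid$cell_id)]
        size <- if (zone == "S") geom$cell_size_south else geom$cell_size_north
        vline <- (row_g - 0.5) * size
        vpt <- if (zone == "S") groups$group_y[inz] -
          geom$extent_north[1] else guv[inz, "v"]
        d <- abs(vpt - vline)
        sigma <- exp(config$detection[[platform]]["b0"] +
                       config$detection[[platform]]["b1"] * seastate)
        pdet <- ifelse(d <= W, exp(-d^2 / (2 * sigma^2)), 0)
        hit <- stats::runif(length(inz)) < pdet
        if (!any(hit)) next
        gi <- inz[hit]
        off_eff <- stats::runif(length(gi)) < config$offeffort_sighting_rate
        sgt <- data.frame(
          survey_id = survey_id, date = date,
          x = groups$group_x[gi], y = groups$group_y[gi],
          group_size = groups$group_size[gi],
          calf_present = groups$calf_present[gi],
          perp_distance_km = d[hit],
          platform = platform, seastate = seastate,
          altitude_m = altitude, visibility_km = visibility,
          status = ifelse(off_eff, "transit", "on_transect"),
          is_duplicate = FALSE, is_verification = FALSE,
          stringsAsFactors = FALSE)
        add_sgt(sgt)
        # circling segments at each sighting (off-effort by status)
        add_seg(data.frame(
          survey_id = survey_id, platform = platform, date = date,
          x0 = sgt$x, y0 = sgt$y, x1 = sgt$x + 0.7, y1 = sgt$y + 0.7,
          seastate = seastate, altitude_m = altitude,
          visibility_km = visibility, status = "circling",
          is_verification = FALSE, stringsAsFactors = FALSE))
        # injected duplicates (photo-identified re-sights, same survey)
        dup <- stats::runif(nrow(sgt)) < config$duplicate_rate
        if (any(dup)) {
          d2 <- sgt[dup, , drop = FALSE]
          d2$x <- d2$x + stats::runif(nrow(d2), -0.2, 0.2)
          d2$y <- d2$y + stats::runif(nrow(d2), -0.2, 0.2)
          d2$is_duplicate <- TRUE
          add_sgt(d2)
        }
        # verification surveys re-locating a reported sighting
        ver <- stats::runif(nrow(sgt)) < config$verification_rate
        if (any(ver)) {
          v2 <- sgt[ver, , drop = FALSE]
          v2$survey_id <- paste0(v2$survey_id, "-V")
          v2$is_verification <- TRUE
          v2$status <- "on_transect"
          add_sgt(v2)
          add_seg(data.frame(
            survey_id = v2$survey_id, platform = platform, date = date,
            x0 = v2$x - 3, y0 = v2$y, x1 = v2$x + 3, y1 = v2$y,
            seastate = seastate, altitude_m = altitude,
            visibility_km = visibility, status = "on_transect",
            is_verification = TRUE, stringsAsFactors = FALSE))
        }
      }
    }
  }
  segments <- do.call(rbind, seg_rows)
  segments$seg_id <- seq_len(nrow(segments))
  segments <- segments[, c("seg_id", "survey_id", "platform", "date",
                           "x0", "y0", "x1", "y1", "seastate",
                           "altitude_m", "visibility_km", "status",
                           "is_verification")]
  sightings <- if (length(sgt_rows)) do.call(rbind, sgt_rows) else
    data.frame(survey_id = character(0), date = as.Date(character(0)),
               x = numeric(0), y = numeric(0), group_size = integer(0),
               calf_present = logical(0), perp_distance_km = numeric(0),
               platform = character(0), seastate = integer(0),
               altitude_m = numeric(0), visibility_km = numeric(0),
               status = character(0), is_duplicate = logical(0),
               is_verification = logical(0))
  sightings$sighting_id <- seq_len(nrow(sightings))
  sightings <- sightings[, c("sighting_id", "survey_id", "date", "x", "y",
                             "group_size", "calf_present",
                             "perp_distance_km", "platform", "seastate",
                             "altitude_m", "visibility_km", "status",
                             "is_duplicate", "is_verification")]
  rownames(segments) <- rownames(sightings) <- NULL
  structure(list(segments = segments, sightings = sightings),
            class = "rw_surveys")
}
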