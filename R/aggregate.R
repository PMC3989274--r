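#' Aggregate effort and sightings into semimonthly sampling units
#'
#' A sampling unit is one grid cell summarised over one semimonthly
#' period. Each on-effort segment is clipped to the cells it crosses;
#' its searched swath area (track length times twice the effective
#' search width minus any platform blind spot, via [searched_area()])
#' is apportioned proportionally to in-cell track length and summed per
#' cell and semimonth. The whale count of a unit is the sum of group
#' sizes of retained sightings located in the cell during the period.
#' Units with survey effort above `max_effort_km2` (340 km^2, the
#' dotplot outlier rule) are flagged excluded rather than dropped, so
#' filter accounting stays auditable.
#'
#' @param segments,sightings on-effort tables from [filter_on_effort()].
#' @param detections named list of [fit_detection()] models by platform.
#' @param grid sampling grid from [build_grid()].
#' @param max_effort_km2 effort-outlier threshold (km^2).
#' @return Data frame of class `rw_units`, one row per surveyed
#'   cell-semimonth: `cell_id`, `season_start_year`, `season`,
#'   `semimonth`, `year` (season factor label), `effort_km2`, `whales`,
#'   `sightings`, `northing_km`, `easting_km`, `excluded`, `reason`.
#'   Sightings falling outside every grid cell are reported via the
#'   `unassigned_sightings` attribute (with a warning).
#' @export
aggregate_units <- function(segments, sightings, detections, grid,
                            max_effort_km2 = 340) {
  sm_seg <- assign_semimonth(segments$date)
  esw_cache <- new.env()
  seg_esw <- vapply(seq_len(nrow(segments)), function(i) {
    key <- paste(segments$platform[i], segments$seastate[i])
    if (is.null(esw_cache[[key]])) {
      m <- detections[[segments$platform[i]]]
      if (is.null(m)) stop("no detection model for platform ",
                           segments$platform[i])
      esw_cache[[key]] <- effective_search_width(m, segments$seastate[i])
    }
    esw_cache[[key]]
  }, numeric(1))

  # fixed track lines repeat across flights: cache clips by geometry
  clip_cache <- new.env()
  pieces <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    gkey <- paste(segments$x0[i], segments$y0[i], segments$x1[i],
                  segments$y1[i])
    cl <- clip_cache[[gkey]]
    if (is.null(cl)) {
      cl <- clip_segment_to_cells(grid, segments$x0[i], segments$y0[i],
                                  segments$x1[i], segments$y1[i])
      cl <- cl[!is.na(cl$cell_id), , drop = FALSE]
      clip_cache[[gkey]] <- cl
    }
    if (!nrow(cl)) next
    m <- detections[[segments$platform[i]]]
    cl$effort <- searched_area(cl$length, seg_esw[i], m)
    cl$season_start_year <- sm_seg$season_start_year[i]
    cl$semimonth <- sm_seg$semimonth[i]
    pieces[[i]] <- cl[, c("cell_id", "season_start_year", "semimonth",
                          "effort")]
  }
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces) || !nrow(pieces))
    stop("no on-effort segment overlaps the sampling grid")
  eff <- stats::aggregate(effort ~ cell_id + season_start_year + semimonth,
                          data = pieces, sum)

  # whale counts from retained sightings
  unassigned <- NULL
  if (nrow(sightings)) {
    sm_sgt <- assign_semimonth(sightings$date)
    cid <- assign_cells(grid, sightings$x, sightings$y)
    if (anyNA(cid)) {
      unassigned <- sightings[is.na(cid), , drop = FALSE]
      warning(nrow(unassigned),
              " sighting(s) outside all grid cells were not aggregated")
    }
    sgt <- data.frame(cell_id = cid,
                      season_start_year = sm_sgt$season_start_year,
                      semimonth = sm_sgt$semimonth,
                      whales = sightings$group_size,
                      n = 1L)[!is.na(cid), , drop = FALSE]
    if (nrow(sgt)) {
      wh <- stats::aggregate(cbind(whales, n) ~ cell_id +
                               season_start_year + semimonth,
                             data = sgt, sum)
    } else wh <- NULL
  } else wh <- NULL

  units <- eff
  names(units)[names(units) == "effort"] <- "effort_km2"
  if (!is.null(wh)) {
    units <- merge(units, wh, all.x = TRUE,
                   by = c("cell_id", "season_start_year", "semimonth"))
  } else {
    units$whales <- 0L; units$n <- 0L
  }
  units$whales[is.na(units$whales)] <- 0L
  units$n[is.na(units$n)] <- 0L
  names(units)[names(units) == "n"] <- "sightings"
  # sightings in cell-periods with no surveyed effort cannot form a
  # sampling unit; report them rather than dropping silently
  if (!is.null(wh)) {
    lost <- sum(wh$whales) - sum(units$whales)
    if (lost > 0) {
      warning(lost, " whale(s) sighted in cell-periods without ",
              "on-effort segments were not aggregated")
      attr(units, "unsurveyed_whales") <- lost
    }
  }
  gi <- match(units$cell_id, grid$cell_id)
  units$northing_km <- grid$cy[gi]
  units$easting_km <- grid$cx[gi]
  units$season <- paste0(units$season_start_year, "/",
                         units$season_start_year + 1L)
  units$year <- units$season
  units$excluded <- units$effort_km2 > max_effort_km2
  units$reason <- ifelse(units$excluded, "effort_outlier", NA_character_)
  units <- units[order(units$season_start_year, units$semimonth,
                       units$cell_id), ]
  rownames(units) <- NULL
  attr(units, "unassigned_sightings") <- unassigned
  class(units) <- c("rw_units", "data.frame")
  units
}

#' Join environmental covariates onto sampling units
#'
#' Attaches static covariates (mean depth with the above-sea-level and
#' 70 m validity rules, mean Horn slope, distance from the cell centre
#' to the shoreline) and dynamic ones (cloud-masked semimonthly SST
#' composite mean, signed distance to the 22 C isotherm). Units whose
#' depth is invalid or whose SST is fully cloud-masked are flagged
#' excluded with a reason code.
#'
#' @param units an [aggregate_units()] table.
#' @param env an environment (`rw_environment` or a compatible list
#'   with `bathy`, `shoreline`, `images`).
#' @param grid the sampling grid.
#' @param iso_level isotherm level (C).
#' @param max_depth depth exclusion threshold (m).
#' @return The units table with covariate columns `depth_m`,
#'   `slope_deg`, `dist_shore_km`, `sst_c`, `dist_iso_km` and updated
#'   `excluded`/`reason`.
#' @export
add_unit_covariates <- function(units, env, grid, iso_level = 22,
                                max_depth = 70) {
  map <- pixel_cell_map(env$bathy, grid)
  dep <- cell_depth(env$bathy, grid, grid$cell_id, max_depth, map)
  slo <- cell_slope(env$bathy, grid, grid$cell_id, map)
  dsh <- distance_to_shore(grid$cx, grid$cy, env$shoreline)
  gi <- match(units$cell_id, grid$cell_id)
  units$depth_m <- dep$depth_m[gi]
  units$slope_deg <- slo$slope_deg[gi]
  units$dist_shore_km <- dsh[gi]

  units$sst_c <- NA_real_
  units$dist_iso_km <- NA_real_
  key <- paste(units$season_start_year, units$semimonth)
  img_key <- vapply(env$images, function(im)
    paste(im$season_start_year, im$semimonth), character(1))
  for (k in unique(key)) {
    imgs <- env$images[img_key == k]
    if (!length(imgs)) next
    comp <- composite_sst(imgs)
    sstc <- cell_sst(comp, grid, grid$cell_id, map)
    iso <- extract_isotherm(comp, iso_level)
    rows <- which(key == k)
    gi_k <- match(units$cell_id[rows], grid$cell_id)
    units$sst_c[rows] <- sstc$sst_c[gi_k]
    units$dist_iso_km[rows] <- isotherm_distance(
      grid$cx[gi_k], grid$cy[gi_k], sstc$sst_c[gi_k], iso, iso_level)
  }

  add_reason <- function(units, bad, code) {
    bad <- bad & !units$excluded
    units$excluded <- units$excluded | bad
    units$reason[bad] <- code
    units
  }
  units <- add_reason(units, !dep$valid[gi], "invalid_depth")
  units <- add_reason(units, is.na(units$sst_c), "missing_SST")
  units <- add_reason(units, is.na(units$dist_iso_km) & !is.na(units$sst_c),
                      "missing_isotherm")
  units
}
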