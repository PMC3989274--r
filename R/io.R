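#' Pipeline configuration defaults
#'
#' Every configurable processing threshold with its default: Beaufort
#' sea state at most 3, altitude at most 365 m, visibility at least
#' 3.7 km, sampling-unit effort outliers above 340 km^2, depth
#' exclusions above sea level or deeper than 70 m, grid cell sizes
#' 5.56 and 7.52 km, prediction reference effort 250 km^2, 22 C
#' isotherm, basis dimension 3, five cross-validation repeats.
#'
#' @param ... overrides of any default.
#' @return Named list of class `rw_config`. Overriding prints a diff
#'   against the defaults via [print.rw_config()].
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    max_seastate = 3, max_altitude_m = 365, min_visibility_km = 3.7,
    max_effort_km2 = 340, max_depth_m = 70,
    cell_size_south = 5.56, cell_size_north = 7.52,
    effort_ref_km2 = 250, iso_level_c = 22,
    basis_k = 3, cv_repeats = 5, seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown configuration field(s): ",
                        paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (any(unlist(cfg[c("max_seastate", "max_altitude_m",
                       "min_visibility_km", "max_effort_km2",
                       "max_depth_m", "effort_ref_km2")]) <= 0))
    stop("thresholds must be positive")
  attr(cfg, "overridden") <- names(over)
  class(cfg) <- "rw_config"
  cfg
}

#' @export
print.rw_config <- function(x, ...) {
  cat("Pipeline configuration")
  ov <- attr(x, "overridden")
  if (length(ov)) cat(" (overridden: ", paste(ov, collapse = ", "), ")",
                      sep = "")
  cat("\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

seg_cols <- c("seg_id", "survey_id", "platform", "date", "x0", "y0",
              "x1", "y1", "seastate", "altitude_m", "visibility_km",
              "status", "is_verification")
sgt_cols <- c("sighting_id", "survey_id", "date", "x", "y", "group_size",
              "calf_present", "perp_distance_km", "platform", "seastate",
              "altitude_m", "visibility_km", "status", "is_duplicate",
              "is_verification")

#' Read and write survey tables
#'
#' CSV readers/writers for the documented track-segment and sighting
#' schemas (the formats [generate_surveys()] emits). Dates are
#' ISO-8601. Rows that fail to parse are collected on the `bad_rows`
#' attribute with their row numbers, never silently dropped; missing
#' mandatory columns are an error. An empty file yields an empty table
#' with a warning.
#'
#' @param path CSV file path.
#' @return Data frame in the documented schema.
#' @export
read_segments <- function(path) {
  read_survey_csv(path, seg_cols, "segments")
}

#' @rdname read_segments
#' @export
read_sightings <- function(path) {
  read_survey_csv(path, sgt_cols, "sightings")
}

read_survey_csv <- function(path, cols, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    warning("empty ", what, " file: ", path)
    out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)),
                                  cols))
    return(out)
  }
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing mandatory column(s) in ", what, ": ",
         paste(miss, collapse = ", "))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) | !is.finite(suppressWarnings(
    if ("x" %in% cols) as.numeric(df$x) else as.numeric(df$x0))))
  out <- df[setdiff(seq_len(nrow(df)), bad), cols, drop = FALSE]
  out$date <- as.Date(out$date)
  if (length(bad)) {
    warning(length(bad), " unparseable row(s) in ", what,
            " reported on attr(,'bad_rows')")
    attr(out, "bad_rows") <- df[bad, , drop = FALSE]
    attr(out, "bad_row_numbers") <- bad
  }
  rownames(out) <- NULL
  out
}

#' @rdname read_segments
#' @param x table to write.
#' @export
write_segments <- function(x, path) {
  utils::write.csv(x[, seg_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_segments
#' @export
write_sightings <- function(x, path) {
  utils::write.csv(x[, sgt_cols], path, row.names = FALSE)
  invisible(path)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange for bathymetry and SST composites
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA header, rows from
#' north to south).
#'
#' @param raster an [raster_grid()].
#' @param path file path.
#' @param nodata NODATA sentinel.
#' @return `read_ascii_grid` returns an `rw_raster`.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  res <- raster_res(raster)
  if (abs(res[1] - res[2]) > 1e-9)
    stop("ESRI ASCII grids require square pixels")
  z <- raster$z
  z[!is.finite(z)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nrow(z)), paste("nrows", ncol(z)),
    paste("xllcorner", format(min(raster$x) - res[1] / 2, digits = 12)),
    paste("yllcorner", format(min(raster$y) - res[1] / 2, digits = 12)),
    paste("cellsize", format(res[1], digits = 12)),
    paste("NODATA_value", nodata)), con)
  for (j in rev(seq_len(ncol(z))))
    writeLines(paste(format(z[, j], trim = TRUE, digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- utils::read.table(path, nrows = 6,
                           col.names = c("key", "value"),
                           stringsAsFactors = FALSE)
  vals <- stats::setNames(as.numeric(hdr$value), tolower(hdr$key))
  nc <- vals[["ncols"]]; nr <- vals[["nrows"]]
  cs <- vals[["cellsize"]]
  dat <- scan(path, skip = 6, quiet = TRUE)
  z <- matrix(NA_real_, nc, nr)
  for (j in seq_len(nr)) {
    z[, nr - j + 1L] <- dat[((j - 1) * nc + 1):(j * nc)]
  }
  z[z == vals[["nodata_value"]]] <- NA_real_
  raster_grid(vals[["xllcorner"]] + (seq_len(nc) - 0.5) * cs,
              vals[["yllcorner"]] + (seq_len(nr) - 0.5) * cs, z)
}

#' Write vector geometry as GeoJSON
#'
#' `write_shoreline_geojson` writes the shoreline polyline;
#' `write_grid_geojson` writes the sampling-grid cell polygons with
#' their ids. Coordinates are the projected km used throughout.
#'
#' @param shoreline vertex matrix.
#' @param grid a sampling grid.
#' @param path file path.
#' @export
write_shoreline_geojson <- function(shoreline, path) {
  gj <- list(type = "Feature",
             geometry = list(type = "LineString",
                             coordinates = unname(apply(shoreline, 1,
                                                        c, simplify = FALSE))),
             properties = list(name = "shoreline"))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' @rdname write_shoreline_geojson
#' @export
write_grid_geojson <- function(grid, path) {
  polys <- cell_polygons(grid)
  feats <- lapply(grid$cell_id, function(cid) {
    p <- polys[[cid]]
    ring <- unname(apply(rbind(p, p[1, , drop = FALSE]), 1, c,
                         simplify = FALSE))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(cell_id = cid,
                           zone = grid$zone[grid$cell_id == cid]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Write the ground truth and its generating parameters
#'
#' The realised truth table as CSV plus a JSON sidecar with the true
#' response parameters, so parameter-recovery checks can reload both.
#'
#' @param truth an [generate_whales()] result.
#' @param config the generating [sim_config()].
#' @param csv_path,json_path output paths.
#' @export
write_truth <- function(truth, config, csv_path, json_path) {
  utils::write.csv(as.data.frame(truth), csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, n_seasons = config$n_seasons,
         true_effects = config$true_effects,
         group_size_mean = config$group_size_mean,
         detection = config$detection),
    json_path, auto_unbox = TRUE, digits = 10)
  invisible(csv_path)
}

#' Structured run report
#'
#' Collects per-stage accounting into one machine-readable report:
#' filter counts, detection coefficients and effective-search-width
#' tables, stepwise records, hurdle summaries, the Moran table and the
#' calf tables. Written as JSON plus a human-readable text digest.
#'
#' @param pipeline a [run_pipeline()] result.
#' @param json_path,text_path output paths (optional).
#' @return The report list, invisibly when writing.
#' @export
write_report <- function(pipeline, json_path = NULL, text_path = NULL) {
  det <- lapply(pipeline$detections, function(m)
    list(platform = m$platform, b0 = m$b0, b1 = m$b1, W = m$W,
         blind_spot_km = m$blind_spot_km, n = m$n,
         esw_table = m$esw_table))
  report <- list(
    seed = pipeline$config$seed,
    filter = pipeline$filtered$report,
    detection = det,
    units = list(
      n = nrow(pipeline$units),
      n_excluded = sum(pipeline$units$excluded),
      exclusion_reasons = as.list(table(pipeline$units$reason[
        pipeline$units$excluded])),
      total_effort_km2 = sum(pipeline$units$effort_km2),
      total_whales = sum(pipeline$units$whales)),
    stepwise = lapply(pipeline$stepwise, function(s)
      if (is.null(s)) NULL else s$steps),
    hurdle = unclass(summary(pipeline$hurdle)),
    moran = pipeline$moran,
    calves = list(habitat = pipeline$calf_habitat,
                  northing = pipeline$calf_northing)
  )
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE,
                         digits = 10, force = TRUE)
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    sink(con)
    cat("Wintering-habitat pipeline report (seed ", report$seed, ")\n\n",
        sep = "")
    print(pipeline$filtered)
    for (m in pipeline$detections) print(m)
    cat(sprintf("\nSampling units: %d (%d excluded), %.0f km2 effort, %d whales\n",
                report$units$n, report$units$n_excluded,
                report$units$total_effort_km2, report$units$total_whales))
    print(summary(pipeline$hurdle))
    sink()
    close(con)
  }
  invisible(report)
}
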