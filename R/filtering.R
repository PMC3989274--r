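#' Filter survey records to on-effort
#'
#' Retains track segments meeting all four on-effort conditions --
#' Beaufort sea state at most 3, altitude at most 365 m, visibility at
#' least 3.7 km, and flying along a designated track line (not in
#' transit or circling a whale) -- and excludes verification-survey
#' effort. Boundary values are inclusive. Sightings are retained when
#' the survey status at the time of the initial sighting was on-effort
#' under the same conditions, excluding verification and
#' photo-identified duplicate records.
#'
#' @param segments segment table (see [read_segments()] schema).
#' @param sightings sighting table (see [read_sightings()] schema).
#' @param max_seastate,max_altitude_m,min_visibility_km on-effort
#'   thresholds (defaults 3, 365 m, 3.7 km).
#' @return List of class `rw_filter`: `segments`, `sightings` (the
#'   retained rows) and `report`, a data frame counting removals per
#'   rule for each table (a record violating several rules is counted
#'   under each).
#' @export
filter_on_effort <- function(segments, sightings, max_seastate = 3,
                             max_altitude_m = 365,
                             min_visibility_km = 3.7) {
  known_status <- c("on_transect", "transit", "circling")
  bad_seg <- !segments$status %in% known_status
  if (any(bad_seg))
    stop("unknown segment status at rows: ",
         paste(utils::head(which(bad_seg), 10), collapse = ", "))
  bad_sgt <- !sightings$status %in% known_status
  if (any(bad_sgt))
    stop("unknown sighting status at rows: ",
         paste(utils::head(which(bad_sgt), 10), collapse = ", "))

  seg_rules <- cbind(
    seastate = segments$seastate > max_seastate,
    altitude = segments$altitude_m > max_altitude_m,
    visibility = segments$visibility_km < min_visibility_km,
    off_transect = segments$status != "on_transect",
    verification = as.logical(segments$is_verification)
  )
  keep_seg <- rowSums(seg_rules) == 0

  sgt_rules <- cbind(
    seastate = sightings$seastate > max_seastate,
    altitude = sightings$altitude_m > max_altitude_m,
    visibility = sightings$visibility_km < min_visibility_km,
    off_transect = sightings$status != "on_transect",
    verification = as.logical(sightings$is_verification),
    duplicate = as.logical(sightings$is_duplicate)
  )
  keep_sgt <- rowSums(sgt_rules) == 0

  report <- rbind(
    data.frame(table = "segments", rule = colnames(seg_rules),
               removed = colSums(seg_rules), stringsAsFactors = FALSE),
    data.frame(table = "segments", rule = "retained",
               removed = sum(keep_seg), stringsAsFactors = FALSE),
    data.frame(table = "sightings", rule = colnames(sgt_rules),
               removed = colSums(sgt_rules), stringsAsFactors = FALSE),
    data.frame(table = "sightings", rule = "retained",
               removed = sum(keep_sgt), stringsAsFactors = FALSE)
  )
  rownames(report) <- NULL
  structure(list(segments = segments[keep_seg, , drop = FALSE],
                 sightings = sightings[keep_sgt, , drop = FALSE],
                 report = report),
            class = "rw_filter")
}

#' @export
print.rw_filter <- function(x, ...) {
  cat("On-effort filter:", nrow(x$segments), "segments and",
      nrow(x$sightings), "sightings retained\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
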