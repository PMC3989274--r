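#' Run the full wintering-habitat pipeline on synthetic surveys
#'
#' End-to-end driver used by the examples and the acceptance script:
#' generates environment, latent whales and detection-thinned surveys
#' from a simulator configuration, filters to on-effort, fits
#' per-platform detection functions, aggregates effort-corrected
#' semimonthly sampling units with environmental covariates, fits the
#' hurdle model (optionally after forward stepwise selection), builds
#' the constant-effort hindcast map, and computes residual Moran's I
#' and the calf-segregation tables.
#'
#' @param sim an [sim_config()] object.
#' @param config processing thresholds ([pipeline_config()]).
#' @param stepwise run forward stepwise selection per component
#'   (slower) instead of fitting the default term sets?
#' @param aspe compute cross-validated ASPE at each accepted stepwise
#'   step?
#' @return List of class `rw_pipeline` with elements `env`, `truth`,
#'   `surveys`, `filtered`, `detections`, `grid`, `units`, `stepwise`
#'   (NULL unless requested), `hurdle`, `map`, `moran`,
#'   `calf_habitat`, `calf_northing`, `config`, `sim`.
#' @export
run_pipeline <- function(sim = sim_config(),
                         config = pipeline_config(seed = sim$seed),
                         stepwise = FALSE, aspe = FALSE) {
  env <- generate_environment(sim)
  truth <- generate_whales(env, sim)
  surveys <- generate_surveys(truth, env, sim)
  grid <- attr(truth, "grid")

  filtered <- filter_on_effort(surveys$segments, surveys$sightings,
                               config$max_seastate, config$max_altitude_m,
                               config$min_visibility_km)
  detections <- fit_detection_by_platform(filtered$sightings,
                                          truncation = sim$detection$truncation_km)
  units <- aggregate_units(filtered$segments, filtered$sightings,
                           detections, grid, config$max_effort_km2)
  units <- add_unit_covariates(units, env, grid, config$iso_level_c,
                               config$max_depth_m)

  steps <- NULL
  if (stepwise) {
    dat <- units[!units$excluded, , drop = FALSE]
    dat <- dat[stats::complete.cases(
      dat[, c("effort_km2", "sst_c", "dist_shore_km", "depth_m",
              "dist_iso_km")]), , drop = FALSE]
    dat$presence <- as.numeric(dat$whales > 0)
    cand <- c("mig", "dist_shore", "year", "effort", "sst", "depth",
              "dist_iso")
    sel_p <- stepwise_select(dat, "presence", cand, "quasibinomial",
                             k = config$basis_k, aspe = aspe,
                             cv_repeats = config$cv_repeats,
                             cv_seed = config$seed)
    pos <- dat[dat$whales > 0, , drop = FALSE]
    sel_a <- stepwise_select(pos, "whales", cand, "Gamma",
                             k = config$basis_k, aspe = aspe,
                             cv_repeats = config$cv_repeats,
                             cv_seed = config$seed)
    steps <- list(presence = sel_p, abundance = sel_a)
    hurdle <- fit_hurdle(units,
                         presence_terms = sel_p$selected,
                         abundance_terms = sel_a$selected,
                         k = config$basis_k,
                         effort_ref = config$effort_ref_km2)
  } else {
    hurdle <- fit_hurdle(units, k = config$basis_k,
                         effort_ref = config$effort_ref_km2)
  }

  map <- stats::predict(hurdle)
  moran <- moran_by_semimonth(hurdle, hurdle$data)

  calves <- filtered$sightings
  calf_habitat <- calf_northing <- NULL
  if (nrow(calves) && any(calves$calf_present) &&
      any(!calves$calf_present)) {
    rec <- extract_sighting_env(calves, env, config$iso_level_c)
    calf_habitat <- calf_habitat_table(rec)
    calf_northing <- semimonth_northing_comparisons(rec)
  }

  structure(list(env = env, truth = truth, surveys = surveys,
                 filtered = filtered, detections = detections,
                 grid = grid, units = units, stepwise = steps,
                 hurdle = hurdle, map = map, moran = moran,
                 calf_habitat = calf_habitat,
                 calf_northing = calf_northing,
                 config = config, sim = sim),
            class = "rw_pipeline")
}

#' @export
print.rw_pipeline <- function(x, ...) {
  cat("Wintering-habitat pipeline run\n")
  cat(sprintf("  %d segments / %d sightings on-effort; %d sampling units\n",
              nrow(x$filtered$segments), nrow(x$filtered$sightings),
              nrow(x$units)))
  print(x$hurdle)
  invisible(x)
}
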