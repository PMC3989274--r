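test_that("the generator is deterministic given the configuration", {
  cfg <- tiny_config(seed = 42)
  e1 <- generate_environment(cfg); e2 <- generate_environment(cfg)
  expect_identical(e1$images[[5]]$values, e2$images[[5]]$values)
  expect_identical(e1$images[[5]]$cloud, e2$images[[5]]$cloud)
  t1 <- generate_whales(e1, cfg); t2 <- generate_whales(e2, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  s1 <- generate_surveys(t1, e1, cfg); s2 <- generate_surveys(t2, e2, cfg)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$sightings, s2$sightings)
})

test_that("cloud masks honour the configured cover fraction", {
  cfg0 <- tiny_config(cloud_fraction = 0)
  env0 <- generate_environment(cfg0)
  expect_true(all(!vapply(env0$images, function(im) any(im$cloud),
                          logical(1))))
  cfg5 <- tiny_config(cloud_fraction = 0.5)
  env5 <- generate_environment(cfg5)
  fr <- vapply(env5$images, function(im) mean(im$cloud), numeric(1))
  expect_true(all(abs(fr - 0.5) < 0.05))
  expect_error(tiny_config(cloud_fraction = 1.4), "\\[0, 1\\]")
})

test_that("a season anomaly shifts the domain-mean SST by its value", {
  cfg <- sim_config(seed = 3, n_seasons = 2, extent_north = c(0, 60),
                    zone_split_north = 30, images_per_semimonth = 4L,
                    sst_anomaly_per_season = c(0, 2))
  env <- generate_environment(cfg)
  mean_by_season <- tapply(
    vapply(env$images, function(im) mean(im$values), numeric(1)),
    vapply(env$images, `[[`, 0L, "season_start_year"), mean)
  expect_equal(unname(diff(mean_by_season)), 2, tolerance = 0.1)
})

test_that("removing the warm band removes the 22 C isotherm", {
  cfg <- tiny_config(gulf_stream_width_km = 0, sst_noise_sd = 0.2)
  env <- generate_environment(cfg)
  # all SST stays below base + anomaly + noise bound, far below 22
  mx <- max(vapply(env$images, function(im) max(im$values), numeric(1)))
  expect_lt(mx, cfg$sst_base_start + max(cfg$sst_anomaly_per_season) + 2)
  comp <- composite_sst(env$images[1:4])
  expect_equal(nrow(extract_isotherm(comp, 22)), 0)
})

test_that("null effect amplitudes give constant occurrence probability", {
  cfg <- tiny_config(true_effects = list(
    sst_amp = 0, shore_amp = 0, depth_amp = 0, iso_amp = 0, mig_amp = 0,
    season_intercepts = 0, intercept = -2))
  env <- generate_environment(cfg)
  truth <- generate_whales(env, cfg)
  covered <- truth$p_occ > 0   # edge cells without coverage carry p = 0
  expect_true(all(abs(truth$p_occ[covered] - plogis(-2)) < 1e-12))
})

test_that("occurrence peaks in the configured SST band", {
  w <- std_world()
  truth <- w$truth
  ok <- truth$p_occ > 0 & !is.na(truth$sst_true)
  expect_gt(sum(ok), 5000)
  bins <- cut(truth$sst_true[ok], seq(8, 24, 1))
  freq <- tapply(truth$n_whales[ok] > 0, bins, mean)
  freq <- freq[!is.na(freq) & table(bins) > 50]
  peak_bin <- names(freq)[which.max(freq)]
  expect_true(peak_bin %in% c("(12,13]", "(13,14]", "(14,15]"))
})

test_that("a higher season intercept yields more whales", {
  # paired seasons identical except for a +1 intercept
  more <- 0L
  for (r in 1:100) {
    cfg <- sim_config(seed = 1000 + r, n_seasons = 2,
                      extent_north = c(0, 30), zone_split_north = 30,
                      images_per_semimonth = 2L,
                      sst_anomaly_per_season = c(0, 0),
                      true_effects = list(season_intercepts = c(0, 1),
                                          intercept = -4))
    env <- generate_environment(cfg)
    truth <- generate_whales(env, cfg)
    tot <- tapply(truth$n_whales, truth$season_start_year, sum)
    more <- more + (tot[2] > tot[1])
  }
  expect_gte(more, 95)
})

test_that("perfect detection sees every in-swath group", {
  cfg <- sim_config(seed = 1, n_seasons = 1, extent_north = c(0, 60),
                    zone_split_north = 30, images_per_semimonth = 4L,
                    detection = list(Skymaster = c(b0 = 10, b1 = 0),
                                     TwinOtter = c(b0 = 10, b1 = 0)),
                    true_effects = list(intercept = -1),
                    bad_flight_rate = 0, duplicate_rate = 0,
                    verification_rate = 0, offeffort_sighting_rate = 0,
                    flights_south = 1L, flights_north = 1L)
  env <- generate_environment(cfg)
  truth <- generate_whales(env, cfg)
  sur <- generate_surveys(truth, env, cfg)
  # every occupied cell-period in a flown zone yields >= 1 sighting
  grid <- attr(truth, "grid")
  occ <- truth[truth$n_whales > 0, ]
  halfw <- grid$size[match(occ$cell_id, grid$cell_id)] / 2
  in_swath <- halfw <= cfg$detection$truncation_km  # all (2.78, 3.76 <= 3?)
  got <- paste(occ$cell_id, occ$semimonth) %in%
    paste(assign_cells(grid, sur$sightings$x, sur$sightings$y),
          assign_semimonth(sur$sightings$date)$semimonth)
  expect_true(all(got[grid$zone[match(occ$cell_id, grid$cell_id)] == "S"]))
})

test_that("zero whales still produce survey effort but no sightings", {
  cfg <- tiny_config(true_effects = list(intercept = -50))
  env <- generate_environment(cfg)
  truth <- generate_whales(env, cfg)
  expect_equal(sum(truth$n_whales), 0)
  sur <- generate_surveys(truth, env, cfg)
  expect_equal(nrow(sur$sightings), 0L)
  expect_gt(nrow(sur$segments), 0L)
})

test_that("higher sea state lowers detection frequency when b1 < 0", {
  # saturate occupancy so every cell-period is an exposure
  cfg <- sim_config(seed = 6, n_seasons = 1, extent_north = c(0, 60),
                    zone_split_north = 60, images_per_semimonth = 2L,
                    flights_south = 10L, flights_north = 0L,
                    bad_flight_rate = 0, duplicate_rate = 0,
                    verification_rate = 0, offeffort_sighting_rate = 0,
                    detection = list(Skymaster = c(b0 = 0, b1 = -0.4),
                                     TwinOtter = c(b0 = 0, b1 = -0.4)),
                    true_effects = list(intercept = 5))
  env <- generate_environment(cfg)
  truth <- generate_whales(env, cfg)
  sur <- generate_surveys(truth, env, cfg)
  n_cells <- length(unique(truth$cell_id))
  flights <- unique(sur$segments[, c("survey_id", "seastate")])
  exposures <- tapply(rep(n_cells, nrow(flights)), flights$seastate, sum)
  dets <- table(factor(sur$sightings$seastate,
                       levels = names(exposures)))
  rate <- as.numeric(dets) / as.numeric(exposures)
  expect_gt(sum(exposures[c("0", "3")]), 2000)
  expect_lt(rate[names(exposures) == "3"], rate[names(exposures) == "0"])
})

test_that("recorded distances follow the generating half-normal law", {
  # single-pass surveys so detections are independent draws, then a
  # probability integral transform across platform/sea-state strata
  cfg <- sim_config(seed = 2, n_seasons = 1, images_per_semimonth = 2L,
                    flights_south = 1L, flights_north = 1L,
                    bad_flight_rate = 0, duplicate_rate = 0,
                    verification_rate = 0, offeffort_sighting_rate = 0,
                    true_effects = list(intercept = 0))
  env <- generate_environment(cfg)
  truth <- generate_whales(env, cfg)
  sur <- generate_surveys(truth, env, cfg)
  sgt <- sur$sightings
  grid <- attr(truth, "grid")
  cid <- assign_cells(grid, sgt$x, sgt$y)
  halfw <- grid$size[match(cid, grid$cell_id)] / 2
  det <- cfg$detection
  b <- t(vapply(sgt$platform, function(p) det[[p]], numeric(2)))
  sigma <- exp(b[, 1] + b[, 2] * sgt$seastate)
  Wi <- pmin(halfw, det$truncation_km)
  cdf <- (pnorm(sgt$perp_distance_km / sigma) - 0.5) /
    (pnorm(Wi / sigma) - 0.5)
  cdf <- cdf[!is.na(cdf)]
  expect_gt(length(cdf), 1000)
  expect_true(all(cdf >= 0 & cdf <= 1))
  ks <- suppressWarnings(ks.test(cdf, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("realized positive counts match the latent group-size means", {
  cfg <- sim_config(seed = 4, n_seasons = 2, images_per_semimonth = 2L,
                    true_effects = list(intercept = 0.5))
  env <- generate_environment(cfg)
  truth <- generate_whales(env, cfg)
  occ <- truth[truth$n_whales > 0, ]
  expect_gt(nrow(occ), 5000)
  expect_lt(abs(mean(occ$n_whales) / mean(occ$mu_pos) - 1), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_config(sst_base_start = NaN), "non-finite")
  expect_error(tiny_config(detection = list(truncation_km = -1)),
               "positive")
})
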