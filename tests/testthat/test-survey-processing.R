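# hand-built fixtures with exactly known filter outcomes

mk_segments <- function(n, ...) {
  n1 <- max(n, 1L)
  base <- data.frame(
    seg_id = seq_len(n1), survey_id = "s1", platform = "TwinOtter",
    date = as.Date("2010-01-10"), x0 = 0, y0 = 2.78, x1 = 10, y1 = 2.78,
    seastate = 1L, altitude_m = 300, visibility_km = 8,
    status = "on_transect", is_verification = FALSE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]][seq_along(over[[nm]])] <- over[[nm]]
  base[seq_len(n), , drop = FALSE]
}

mk_sightings <- function(n, ...) {
  n1 <- max(n, 1L)
  base <- data.frame(
    sighting_id = seq_len(n1), survey_id = "s1",
    date = as.Date("2010-01-10"), x = 3, y = 2.5, group_size = 2L,
    calf_present = FALSE, perp_distance_km = 0.4,
    platform = "TwinOtter", seastate = 1L, altitude_m = 300,
    visibility_km = 8, status = "on_transect", is_duplicate = FALSE,
    is_verification = FALSE, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]][seq_along(over[[nm]])] <- over[[nm]]
  base[seq_len(n), , drop = FALSE]
}

test_that("on-effort rules are applied with inclusive boundaries", {
  segs <- mk_segments(2, seastate = c(4L, 3L))
  segs$altitude_m[2] <- 365; segs$visibility_km[2] <- 3.7
  fl <- filter_on_effort(segs, mk_sightings(0))
  expect_equal(fl$segments$seg_id, 2L)   # boundary values retained
  rep_seg <- fl$report[fl$report$table == "segments", ]
  expect_equal(rep_seg$removed[rep_seg$rule == "seastate"], 1)
})

test_that("a fixture with 3 single-rule violations keeps 7 of 10 segments", {
  segs <- mk_segments(10)
  segs$seastate[2] <- 4L
  segs$altitude_m[5] <- 400
  segs$visibility_km[8] <- 3.0
  fl <- filter_on_effort(segs, mk_sightings(0))
  expect_equal(nrow(fl$segments), 7L)
  rep_seg <- fl$report[fl$report$table == "segments", ]
  expect_equal(rep_seg$removed[rep_seg$rule == "retained"], 7)
  expect_equal(sum(rep_seg$removed[rep_seg$rule %in%
                                     c("seastate", "altitude",
                                       "visibility")]), 3)
})

test_that("sightings are filtered on initial status, duplicates and verification", {
  sgt <- mk_sightings(6, status = c("on_transect", "transit", "circling"))
  sgt$is_duplicate[4] <- TRUE
  sgt$is_verification[5] <- TRUE
  sgt$seastate[6] <- 5L
  fl <- filter_on_effort(mk_segments(1), sgt)
  expect_equal(fl$sightings$sighting_id, 1L)
  expect_error(filter_on_effort(mk_segments(1, status = "parked"),
                                mk_sightings(0)),
               "unknown segment status")
})

test_that("filtering is idempotent", {
  segs <- mk_segments(10, seastate = c(4L, 4L))
  sgt <- mk_sightings(5, status = c("transit"))
  f1 <- filter_on_effort(segs, sgt)
  f2 <- filter_on_effort(f1$segments, f1$sightings)
  expect_identical(f1$segments, f2$segments)
  expect_identical(f1$sightings, f2$sightings)
})

grd <- build_grid(extent_east = c(0, 55.6), extent_north = c(0, 60),
                  zone_split_north = 30)
otter <- structure(list(platform = "TwinOtter", b0 = 0.4, b1 = -0.1,
                        W = 3, blind_spot_km = 0), class = "rw_detection")
sky <- structure(list(platform = "Skymaster", b0 = 0.4, b1 = -0.1,
                      W = 3, blind_spot_km = 0.186), class = "rw_detection")
models <- list(TwinOtter = otter, Skymaster = sky)

test_that("unit effort is additive over segments in a cell-period", {
  # two short segments inside the first cell with swath areas 13 and 14
  esw1 <- effective_search_width(otter, 1L)
  segs <- mk_segments(2)
  segs$x1 <- c(13, 14) / (2 * esw1)    # both shorter than 5.56 km
  units <- aggregate_units(segs, mk_sightings(0), models, grd)
  expect_equal(nrow(units), 1L)
  expect_equal(units$effort_km2, 27, tolerance = 1e-9)
  expect_equal(units$cell_id, "S-r01-c+01")
})

test_that("effort conservation holds on a mixed-platform fixture", {
  set.seed(21)
  segs <- mk_segments(12)
  segs$platform <- rep(c("TwinOtter", "Skymaster"), 6)
  segs$seastate <- rep(0:3, 3)
  segs$x0 <- runif(12, 0, 40); segs$x1 <- runif(12, 0, 40)
  segs$y0 <- runif(12, 0, 55); segs$y1 <- segs$y0 + runif(12, -4, 4)
  segs$y0 <- pmin(segs$y0, 59); segs$y1 <- pmin(segs$y1, 59)
  units <- aggregate_units(segs, mk_sightings(0), models, grd)
  # independent total: whole-segment swath area per platform/sea state
  lens <- sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2)
  esw <- mapply(function(p, s) effective_search_width(models[[p]], s),
                segs$platform, segs$seastate)
  bs <- ifelse(segs$platform == "Skymaster", 0.186, 0)
  expect_equal(sum(units$effort_km2), sum(lens * 2 * (esw - bs)),
               tolerance = 1e-6)
})

test_that("units above 340 km2 effort are flagged as outliers", {
  esw1 <- effective_search_width(otter, 1L)
  segs <- mk_segments(1)
  segs$x1 <- 341 / (2 * esw1)   # stays within row 1, cells 1..n
  segs$y1 <- segs$y0
  # squeeze all area into one cell by looping the segment inside it
  segs <- mk_segments(70)       # 70 passes over the same 5 km piece
  segs$x0 <- 0; segs$x1 <- 341 / (2 * esw1) / 70
  units <- aggregate_units(segs, mk_sightings(0), models, grd)
  expect_equal(sum(units$effort_km2), 341, tolerance = 1e-9)
  expect_true(units$excluded[1])
  expect_equal(units$reason[1], "effort_outlier")
})

test_that("whale counts sum retained group sizes per cell-period", {
  segs <- mk_segments(1)
  sgt <- mk_sightings(4, x = c(1, 2, 9, 40), y = c(1, 2, 3, 50))
  sgt$group_size <- c(2L, 3L, 1L, 5L)
  sgt$date[4] <- as.Date("2010-02-20")
  # sighting 4 falls in a cell-period with no effort: reported
  expect_warning(units <- aggregate_units(segs, sgt, models, grd),
                 "without on-effort segments")
  u1 <- units[units$cell_id == "S-r01-c+01" & units$semimonth == 3, ]
  expect_equal(u1$whales, 5L)       # groups of 2 and 3
  expect_equal(u1$sightings, 2L)
  expect_equal(sum(units$whales) + attr(units, "unsurveyed_whales"),
               sum(sgt$group_size))
})

test_that("sightings outside the grid are reported, not dropped silently", {
  segs <- mk_segments(1)
  sgt <- mk_sightings(2, x = c(3, 300), y = c(2, 500))
  expect_warning(units <- aggregate_units(segs, sgt, models, grd),
                 "outside all grid cells")
  expect_equal(nrow(attr(units, "unassigned_sightings")), 1L)
})
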