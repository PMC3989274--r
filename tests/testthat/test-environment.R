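# small axis-aligned grid world for covariate checks
mk_grid <- function() build_grid(extent_east = c(0, 22.24),
                                 extent_north = c(0, 22.24),
                                 zone_split_north = 22.24)
mk_raster <- function(z_fun, px = 1.112, xmax = 22.24, ymax = 22.24) {
  x <- seq(px / 2, xmax, by = px)
  y <- seq(px / 2, ymax, by = px)
  raster_grid(x, y, outer(x, y, z_fun))
}

test_that("cell depth applies the exclusion rules", {
  grd <- mk_grid()
  r <- mk_raster(function(x, y) 20 + 0 * x)
  d <- cell_depth(r, grd, grd$cell_id[1])
  expect_equal(d$depth_m, 20)
  expect_true(d$valid)

  r71 <- mk_raster(function(x, y) 71 + 0 * x)
  d71 <- cell_depth(r71, grd, grd$cell_id[1])
  expect_false(d71$valid)
  expect_equal(d71$reason, "depth>70")

  rneg <- mk_raster(function(x, y) -3 + 0 * x)
  dneg <- cell_depth(rneg, grd, grd$cell_id[1])
  expect_false(dneg$valid)
  expect_equal(dneg$reason, "above_sea_level")

  # half the pixels 10 m, half 30 m -> mean 20 m
  rh <- mk_raster(function(x, y) ifelse(x < 11.12, 10, 30))
  dh <- cell_depth(rh, grd, "S-r01-c+01")
  # the first cell spans x in (0, 5.56]: uniform 10 there
  expect_equal(dh$depth_m, 10)
  whole <- mk_raster(function(x, y) ifelse(y < 11.12, 10, 30))
  # column of cells averages to 20 over the full grid
  dcol <- cell_depth(whole, grd, c("S-r01-c+01", "S-r04-c+01"))
  expect_equal(dcol$depth_m, c(10, 30))
})

test_that("Horn slope matches analytic planes and a brute-force oracle", {
  grd <- mk_grid()
  flat <- mk_raster(function(x, y) 15 + 0 * x)
  expect_equal(unique(as.vector(slope_raster(flat)[2:18, 2:18])), 0)

  # plane rising 1 m per 100 m -> atan(0.01) everywhere
  plane <- mk_raster(function(x, y) 0.01 * (x * 1000))
  sl <- slope_raster(plane)
  expect_equal(unique(round(as.vector(sl[2:18, 2:18]), 10)),
               round(atan(0.01) * 180 / pi, 10))

  set.seed(77)
  z <- matrix(rnorm(15 * 12), 15, 12)
  r <- raster_grid(seq_len(15) * 2, seq_len(12) * 2, z)
  sl2 <- slope_raster(r)
  # independent per-pixel double-loop oracle
  for (i in 2:14) for (j in 2:11) {
    gx <- ((z[i + 1, j - 1] + 2 * z[i + 1, j] + z[i + 1, j + 1]) -
           (z[i - 1, j - 1] + 2 * z[i - 1, j] + z[i - 1, j + 1])) / (8 * 2000)
    gy <- ((z[i - 1, j + 1] + 2 * z[i, j + 1] + z[i + 1, j + 1]) -
           (z[i - 1, j - 1] + 2 * z[i, j - 1] + z[i + 1, j - 1])) / (8 * 2000)
    expect_equal(sl2[i, j], atan(sqrt(gx^2 + gy^2)) * 180 / pi,
                 tolerance = 1e-9)
  }
  expect_error(slope_raster(raster_grid(1, 1, matrix(1))), "3x3")
})

test_that("distance to shore is an exact point-to-polyline minimum", {
  shore <- cbind(x = c(0, 0), y = c(-100, 100))
  expect_equal(distance_to_shore(17.6, 5, shore), 17.6)
  expect_equal(distance_to_shore(0, 50, shore), 0)

  set.seed(12)
  poly <- cbind(x = cumsum(runif(8, -3, 3)), y = seq(0, 70, length.out = 8))
  px <- runif(40, 0, 50); py <- runif(40, 0, 70)
  d <- distance_to_shore(px, py, poly)
  # brute force over dense samples along every polyline segment
  for (k in seq_along(px)) {
    dd <- Inf
    for (s in 1:7) {
      t <- seq(0, 1, length.out = 2000)
      sx <- poly[s, 1] + t * (poly[s + 1, 1] - poly[s, 1])
      sy <- poly[s, 2] + t * (poly[s + 1, 2] - poly[s, 2])
      dd <- min(dd, sqrt((px[k] - sx)^2 + (py[k] - sy)^2))
    }
    expect_equal(d[k], dd, tolerance = 1e-5)
  }
  expect_error(distance_to_shore(1, 1, poly[0, , drop = FALSE]), "empty")
})

test_that("SST compositing averages cloud-free observations only", {
  x <- seq(0.5, 9.5); y <- seq(0.5, 7.5)
  mk_im <- function(v, cloud = FALSE) {
    list(x = x, y = y, values = matrix(v, 10, 8),
         cloud = matrix(cloud, 10, 8))
  }
  const <- composite_sst(list(mk_im(14), mk_im(14), mk_im(14)))
  expect_true(all(const$mean == 14))
  expect_true(all(const$n_valid == 3))

  # one pixel observed on 3 of 8 days with values 12, 14, 16
  ims <- c(lapply(c(12, 14, 16), mk_im),
           lapply(c(99, 99, 99, 99, 99), mk_im, cloud = TRUE))
  cp <- composite_sst(ims)
  expect_true(all(cp$mean == 14))
  expect_true(all(cp$n_valid == 3))
  # image order is irrelevant
  cp2 <- composite_sst(rev(ims))
  expect_identical(cp$mean, cp2$mean)

  # fully clouded pixels are missing, never zero
  allc <- composite_sst(lapply(1:3, function(i) mk_im(10, cloud = TRUE)))
  expect_true(all(is.na(allc$mean)))

  # composite equals brute-force accumulation on a random stack
  set.seed(3)
  ims3 <- lapply(1:6, function(i)
    list(x = x, y = y, values = matrix(rnorm(80, 15), 10, 8),
         cloud = matrix(runif(80) < 0.4, 10, 8)))
  cp3 <- composite_sst(ims3)
  for (i in c(1, 5, 10)) for (j in c(1, 4, 8)) {
    vals <- vapply(ims3, function(im)
      if (im$cloud[i, j]) NA_real_ else im$values[i, j], numeric(1))
    expect_equal(cp3$mean[i, j], mean(vals, na.rm = TRUE))
  }
  bad <- list(list(x = x, y = y, values = matrix(1, 5, 5),
                   cloud = matrix(FALSE, 5, 5)))
  expect_error(composite_sst(c(ims3, bad)), "mismatched")
})

test_that("the 22 C isotherm is extracted and signed correctly", {
  # linear field 18 -> 26 C across 80 km: contour at the 22 C line
  x <- seq(0.5, 79.5); y <- seq(0.5, 39.5)
  sst <- raster_grid(x, y, outer(18 + 8 * x / 80, rep(1, 40)))
  iso <- extract_isotherm(sst, 22)
  expect_gt(nrow(iso), 0)
  expect_true(all(abs(c(iso[, "x1"], iso[, "x2"]) - 40) < 0.5))

  d_cold <- isotherm_distance(30, 20, sst = 21, iso)
  d_warm <- isotherm_distance(50, 20, sst = 23, iso)
  expect_equal(d_cold, 10, tolerance = 0.5)
  expect_equal(d_warm, -10, tolerance = 0.5)
  # exactly 22 C: sign non-negative by convention
  d_on <- isotherm_distance(40, 20, sst = 22, iso)
  expect_gte(d_on, 0)
  expect_lt(d_on, 0.5)

  # uniform cold field: no isotherm, distance missing
  flat <- raster_grid(x, y, matrix(15, 80, 40))
  expect_equal(nrow(extract_isotherm(flat, 22)), 0)
  expect_true(is.na(isotherm_distance(10, 10, 15, extract_isotherm(flat, 22))))

  # contour crossings sit where interpolated SST = 22
  expect_true(all(abs(18 + 8 * iso[, "x1"] / 80 - 22) < 0.06))
})

test_that("distances are metrics: non-negative, zero on the geometry", {
  shore <- cbind(x = c(3, 8, 12), y = c(0, 10, 30))
  set.seed(8)
  px <- runif(50, 0, 20); py <- runif(50, 0, 30)
  d <- distance_to_shore(px, py, shore)
  expect_true(all(d >= 0))
  expect_equal(distance_to_shore(8, 10, shore), 0)
  # triangle consistency against vertex distances
  dv <- distance_to_shore(px, py, shore[2, , drop = FALSE])
  expect_true(all(d <= dv + 1e-9))
})
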