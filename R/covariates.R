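#' Raster grid constructor
#'
#' Lightweight regular-raster container used for bathymetry and SST
#' fields: pixel-centre coordinate vectors and a value matrix `z` with
#' `z[i, j]` at `(x[i], y[j])` (the `image()` convention).
#'
#' @param x,y strictly increasing pixel-centre coordinates (km).
#' @param z numeric matrix, `length(x)` rows by `length(y)` columns.
#' @return A list of class `rw_raster`.
#' @export
raster_grid <- function(x, y, z) {
  if (!is.matrix(z) || nrow(z) != length(x) || ncol(z) != length(y))
    stop("z must be a length(x) by length(y) matrix")
  if (length(x) > 1 && any(diff(x) <= 0)) stop("x must be increasing")
  if (length(y) > 1 && any(diff(y) <= 0)) stop("y must be increasing")
  structure(list(x = x, y = y, z = z), class = "rw_raster")
}

raster_res <- function(r) {
  dx <- if (length(r$x) > 1) r$x[2] - r$x[1] else 1
  dy <- if (length(r$y) > 1) r$y[2] - r$y[1] else dx
  c(dx, dy)
}

# map every pixel centre to a sampling-grid cell (NA outside the grid)
pixel_cell_map <- function(raster, grid) {
  pts <- expand.grid(x = raster$x, y = raster$y)
  matrix(assign_cells(grid, pts$x, pts$y),
         nrow = length(raster$x), ncol = length(raster$y))
}

# mean of in-cell pixels with a minimum-coverage rule
cell_raster_mean <- function(raster, grid, cells, map = NULL,
                             min_coverage = 0.5) {
  if (is.null(map)) map <- pixel_cell_map(raster, grid)
  vals <- raster$z
  px_area <- prod(raster_res(raster))
  idx <- match(cells, grid$cell_id)
  vapply(seq_along(cells), function(k) {
    sel <- which(map == cells[k])
    if (!length(sel)) return(NA_real_)
    v <- vals[sel]
    v <- v[is.finite(v)]
    cov <- length(v) * px_area / grid$size[idx[k]]^2
    if (!length(v) || cov < min_coverage) return(NA_real_)
    mean(v)
  }, numeric(1))
}

#' Mean cell depth with validity rule
#'
#' Mean bottom depth (m, positive down) of all bathymetry pixels inside
#' each cell. Cells whose mean depth is above sea level or deeper than
#' `max_depth` (70 m by default) are flagged invalid and are excluded
#' from habitat modelling downstream.
#'
#' @param bathy an [raster_grid()] of depths (m, positive down).
#' @param grid sampling grid.
#' @param cells cell ids (default all).
#' @param max_depth exclusion threshold (m).
#' @param map optional precomputed [pixel_cell_map()].
#' @return Data frame: `cell_id`, `depth_m`, `valid`, `reason`.
#' @export
cell_depth <- function(bathy, grid, cells = grid$cell_id, max_depth = 70,
                       map = NULL) {
  d <- cell_raster_mean(bathy, grid, cells, map)
  reason <- rep(NA_character_, length(d))
  reason[is.na(d)] <- "no_pixels"
  reason[!is.na(d) & d <= 0] <- "above_sea_level"
  reason[!is.na(d) & d > max_depth] <- "depth>70"
  data.frame(cell_id = cells, depth_m = d, valid = is.na(reason),
             reason = reason, stringsAsFactors = FALSE)
}

#' Per-pixel slope (Horn operator)
#'
#' 3x3 finite-difference gradient of Horn (the common GIS
#' implementation); border pixels get `NA`.
#'
#' @param bathy an [raster_grid()] of depths (m).
#' @return Matrix of slopes in degrees, same shape as `bathy$z`.
#' @export
slope_raster <- function(bathy) {
  z <- bathy$z
  nx <- nrow(z); ny <- ncol(z)
  if (nx < 3 || ny < 3) stop("grid too small for a 3x3 slope operator")
  res <- raster_res(bathy) * 1000   # m per pixel
  out <- matrix(NA_real_, nx, ny)
  i <- 2:(nx - 1); j <- 2:(ny - 1)
  gx <- ((z[i + 1, j - 1] + 2 * z[i + 1, j] + z[i + 1, j + 1]) -
         (z[i - 1, j - 1] + 2 * z[i - 1, j] + z[i - 1, j + 1])) / (8 * res[1])
  gy <- ((z[i - 1, j + 1] + 2 * z[i, j + 1] + z[i + 1, j + 1]) -
         (z[i - 1, j - 1] + 2 * z[i, j - 1] + z[i + 1, j - 1])) / (8 * res[2])
  out[i, j] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  out
}

#' Mean cell slope
#'
#' @inheritParams cell_depth
#' @return Data frame: `cell_id`, `slope_deg`.
#' @export
cell_slope <- function(bathy, grid, cells = grid$cell_id, map = NULL) {
  sr <- raster_grid(bathy$x, bathy$y, slope_raster(bathy))
  data.frame(cell_id = cells,
             slope_deg = cell_raster_mean(sr, grid, cells, map),
             stringsAsFactors = FALSE)
}

#' Distance from points to a shoreline polyline
#'
#' Minimum Euclidean distance from each point to any segment of the
#' polyline (km, always non-negative).
#'
#' @param x,y point coordinates (km).
#' @param shoreline two-column matrix of polyline vertices (km).
#' @return Numeric vector of distances (km).
#' @export
distance_to_shore <- function(x, y, shoreline) {
  if (is.null(dim(shoreline)) || nrow(shoreline) < 1)
    stop("shoreline polyline is empty")
  if (nrow(shoreline) == 1)
    return(sqrt((x - shoreline[1, 1])^2 + (y - shoreline[1, 2])^2))
  d <- rep(Inf, length(x))
  for (s in seq_len(nrow(shoreline) - 1L)) {
    d <- pmin(d, point_segment_distance(x, y,
                                        shoreline[s, 1], shoreline[s, 2],
                                        shoreline[s + 1, 1],
                                        shoreline[s + 1, 2]))
  }
  d
}

point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  if (L2 < 1e-18) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
  sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2)
}

#' Composite daily SST images over a semimonth
#'
#' Per-pixel mean over cloud-free observations. Pixels with zero valid
#' observations are missing (`NA`), never zero. The composite is
#' invariant to the ordering of the daily images.
#'
#' @param images list of daily images, each a list with `values` (a
#'   matrix, C) and `cloud` (a logical matrix, `TRUE` = cloud-masked);
#'   all images must share the raster geometry `x`, `y`.
#' @param x,y pixel-centre coordinates; taken from the first image if it
#'   carries them.
#' @return List of class `rw_sst_composite`: `x`, `y`, `mean` matrix,
#'   `n_valid` matrix, `n_images`.
#' @export
composite_sst <- function(images, x = NULL, y = NULL) {
  if (!length(images)) stop("need at least one daily image")
  if (is.null(x)) x <- images[[1]]$x
  if (is.null(y)) y <- images[[1]]$y
  dims <- dim(images[[1]]$values)
  sum_v <- matrix(0, dims[1], dims[2])
  n_v <- matrix(0L, dims[1], dims[2])
  for (im in images) {
    if (!all(dim(im$values) == dims) || !all(dim(im$cloud) == dims))
      stop("mismatched raster geometry in daily images")
    valid <- !im$cloud & is.finite(im$values)
    sum_v[valid] <- sum_v[valid] + im$values[valid]
    n_v <- n_v + valid
  }
  m <- sum_v / n_v
  m[n_v == 0L] <- NA_real_
  structure(list(x = x, y = y, mean = m, n_valid = n_v,
                 n_images = length(images)),
            class = "rw_sst_composite")
}

#' Mean composite SST per cell
#'
#' Cell value is the mean of non-missing composite pixels inside the
#' cell; `NA` when every in-cell pixel is cloud-masked for the whole
#' period (such sampling units are later flagged `missing_SST`).
#'
#' @param composite an [composite_sst()] result.
#' @inheritParams cell_depth
#' @return Data frame: `cell_id`, `sst_c`.
#' @export
cell_sst <- function(composite, grid, cells = grid$cell_id, map = NULL) {
  r <- raster_grid(composite$x, composite$y, composite$mean)
  # no minimum-coverage rule for SST: any cloud-free pixel informs a cell
  if (is.null(map)) map <- pixel_cell_map(r, grid)
  v <- vapply(cells, function(cid) {
    sel <- which(map == cid)
    vv <- r$z[sel]
    vv <- vv[is.finite(vv)]
    if (!length(vv)) NA_real_ else mean(vv)
  }, numeric(1))
  data.frame(cell_id = cells, sst_c = unname(v), stringsAsFactors = FALSE)
}

#' Extract an SST isotherm by marching squares
#'
#' Linear edge interpolation on the composite grid; ambiguous saddle
#' squares are resolved with the cell-centre mean.
#'
#' @param composite an [composite_sst()] result (or `rw_raster`).
#' @param level contour level, C (22 by default: the winter Gulf Stream
#'   boundary proxy).
#' @return A matrix with columns `x1, y1, x2, y2` of contour segments
#'   (km); zero rows when the isotherm is absent from the domain.
#' @export
extract_isotherm <- function(composite, level = 22) {
  z <- if (!is.null(composite$mean)) composite$mean else composite$z
  x <- composite$x; y <- composite$y
  nx <- nrow(z); ny <- ncol(z)
  segs <- list()
  edge_pt <- function(xa, ya, za, xb, yb, zb) {
    t <- (level - za) / (zb - za)
    c(xa + t * (xb - xa), ya + t * (yb - ya))
  }
  for (i in seq_len(nx - 1L)) {
    col_a <- z[i, ]; col_b <- z[i + 1L, ]
    for (j in seq_len(ny - 1L)) {
      zA <- col_a[j]; zB <- col_b[j]; zC <- col_b[j + 1L]; zD <- col_a[j + 1L]
      if (anyNA(c(zA, zB, zC, zD))) next
      case <- (zA >= level) + 2L * (zB >= level) + 4L * (zC >= level) +
        8L * (zD >= level)
      if (case == 0L || case == 15L) next
      xA <- x[i]; xB <- x[i + 1L]; yA <- y[j]; yD <- y[j + 1L]
      ab <- function() edge_pt(xA, yA, zA, xB, yA, zB)
      bc <- function() edge_pt(xB, yA, zB, xB, yD, zC)
      cd <- function() edge_pt(xB, yD, zC, xA, yD, zD)
      da <- function() edge_pt(xA, yD, zD, xA, yA, zA)
      add <- function(p, q) segs[[length(segs) + 1L]] <<- c(p, q)
      if (case == 1L || case == 14L) add(ab(), da())
      else if (case == 2L || case == 13L) add(ab(), bc())
      else if (case == 3L || case == 12L) add(da(), bc())
      else if (case == 4L || case == 11L) add(bc(), cd())
      else if (case == 6L || case == 9L) add(ab(), cd())
      else if (case == 7L || case == 8L) add(da(), cd())
      else {
        centre_high <- mean(c(zA, zB, zC, zD)) >= level
        a_high <- case == 5L   # high corners on the A-C diagonal
        if (a_high == centre_high) {
          add(ab(), bc()); add(cd(), da())
        } else {
          add(ab(), da()); add(bc(), cd())
        }
      }
    }
  }
  out <- if (length(segs)) do.call(rbind, segs)
    else matrix(numeric(0), ncol = 4)
  colnames(out) <- c("x1", "y1", "x2", "y2")
  out
}

#' Signed distance to the 22 C isotherm
#'
#' Distance from each point to the nearest isotherm segment, with a
#' negative sign for points whose SST exceeds the contour level (east or
#' south of the winter Gulf Stream boundary). Points at exactly the
#' contour level get a non-negative (zero-ward) sign by convention.
#' Missing (`NA`) when the domain holds no isotherm or the point SST is
#' unknown.
#'
#' @param x,y point coordinates (km).
#' @param sst SST at the points (C), used only for the sign.
#' @param isotherm segment matrix from [extract_isotherm()].
#' @param level contour level (C).
#' @return Signed distances (km).
#' @export
isotherm_distance <- function(x, y, sst, isotherm, level = 22) {
  n <- length(x)
  if (is.null(isotherm) || nrow(isotherm) == 0)
    return(rep(NA_real_, n))
  d <- rep(Inf, n)
  for (s in seq_len(nrow(isotherm))) {
    d <- pmin(d, point_segment_distance(x, y,
                                        isotherm[s, 1], isotherm[s, 2],
                                        isotherm[s, 3], isotherm[s, 4]))
  }
  sign <- ifelse(!is.na(sst) & sst > level, -1, 1)
  out <- sign * d
  out[is.na(sst)] <- NA_real_
  out
}
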