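#' Build the composite sampling grid
#'
#' Constructs the two-zone sampling grid used to aggregate survey effort
#' and sightings: square cells oriented east-west in the southern zone
#' (default 5.56 km, matching the 3-nautical-mile transect spacing) and
#' larger cells rotated to the northwest-southeast transect azimuth in
#' the northern zone (default 7.52 km). Cell rows are centred on the
#' track lines so that all effort in a cell is associated with a single
#' transect.
#'
#' The zone boundary is snapped to a whole number of southern rows so
#' that the two zones tile the study area without gaps. Northern cells
#' are indexed in a rotated frame (u along-track, v across-track from
#' the zone origin); every cell whose square intersects the study area
#' is included, so in-area points always map to exactly one cell.
#'
#' @param extent_east,extent_north study-area extent in projected km.
#' @param zone_split_north nominal northing of the zone boundary (km).
#' @param cell_size_south,cell_size_north cell sizes (km).
#' @param north_azimuth transect azimuth of the northern zone, degrees
#'   clockwise from north.
#' @return A data frame of class `rw_grid` with columns `cell_id`,
#'   `zone` ("S"/"N"), `row`, `col`, `cx`, `cy` (cell centre, km) and
#'   `size`, plus geometry attributes used by [assign_cells()] and
#'   [clip_segment_to_cells()].
#' @export
build_grid <- function(extent_east = c(0, 55.6), extent_north = c(0, 240),
                       zone_split_north = 120, cell_size_south = 5.56,
                       cell_size_north = 7.52, north_azimuth = 135) {
  cs <- cell_size_south; cn <- cell_size_north
  n_s_rows <- floor((zone_split_north - extent_north[1]) / cs + 1e-9)
  y_split <- extent_north[1] + n_s_rows * cs
  if (y_split > extent_north[2] + 1e-9)
    stop("zone boundary does not cover the transect layout")
  n_s_cols <- ceiling((extent_east[2] - extent_east[1]) / cs - 1e-9)

  south <- expand.grid(row = seq_len(n_s_rows), col = seq_len(n_s_cols))
  south$zone <- "S"
  south$cx <- extent_east[1] + (south$col - 0.5) * cs
  south$cy <- extent_north[1] + (south$row - 0.5) * cs
  south$size <- cs

  a <- north_azimuth * pi / 180
  along <- c(sin(a), cos(a))      # unit vector along transects
  perp <- c(-cos(a), sin(a))      # unit vector across transects
  origin <- c(extent_east[1], y_split)

  north <- NULL
  if (y_split < extent_north[2] - 1e-9) {
    corners <- rbind(c(extent_east[1], y_split),
                     c(extent_east[2], y_split),
                     c(extent_east[1], extent_north[2]),
                     c(extent_east[2], extent_north[2]))
    cu <- (corners[, 1] - origin[1]) * along[1] +
          (corners[, 2] - origin[2]) * along[2]
    cv <- (corners[, 1] - origin[1]) * perp[1] +
          (corners[, 2] - origin[2]) * perp[2]
    rows <- seq_len(ceiling(max(cv) / cn - 1e-9))
    cols <- seq(floor(min(cu) / cn + 1e-9) + 1L, ceiling(max(cu) / cn - 1e-9))
    cand <- expand.grid(row = rows, col = cols)
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      rect_intersects_cell(extent_east, c(y_split, extent_north[2]),
                           origin, along, perp, cn,
                           cand$row[i], cand$col[i])
    }, logical(1))
    north <- cand[keep, , drop = FALSE]
    if (nrow(north)) {
      uc <- (north$col - 0.5) * cn
      vc <- (north$row - 0.5) * cn
      north$zone <- "N"
      north$cx <- origin[1] + uc * along[1] + vc * perp[1]
      north$cy <- origin[2] + uc * along[2] + vc * perp[2]
      north$size <- cn
    }
  }

  grid <- rbind(south[, c("zone", "row", "col", "cx", "cy", "size")],
                if (!is.null(north) && nrow(north))
                  north[, c("zone", "row", "col", "cx", "cy", "size")])
  grid$cell_id <- sprintf("%s-r%02d-c%+03d", grid$zone, grid$row, grid$col)
  grid <- grid[order(grid$cell_id), c("cell_id", "zone", "row", "col",
                                      "cx", "cy", "size")]
  rownames(grid) <- NULL
  attr(grid, "geometry") <- list(
    extent_east = extent_east, extent_north = extent_north,
    y_split = y_split, cell_size_south = cs, cell_size_north = cn,
    north_azimuth = north_azimuth, origin = origin,
    along = along, perp = perp,
    n_s_rows = n_s_rows, n_s_cols = n_s_cols
  )
  class(grid) <- c("rw_grid", "data.frame")
  grid
}

# separating-axis intersection test between the study-area rectangle and
# a rotated grid cell (both convex quadrilaterals)
rect_intersects_cell <- function(xr, yr, origin, along, perp, size,
                                 row, col) {
  u0 <- (col - 1) * size; u1 <- col * size
  v0 <- (row - 1) * size; v1 <- row * size
  cu <- c(u0, u1, u1, u0); cv <- c(v0, v0, v1, v1)
  px <- origin[1] + cu * along[1] + cv * perp[1]
  py <- origin[2] + cu * along[2] + cv * perp[2]
  eps <- 1e-9
  if (max(px) < xr[1] - eps || min(px) > xr[2] + eps ||
      max(py) < yr[1] - eps || min(py) > yr[2] + eps) return(FALSE)
  # axes of the rotated square: project rectangle corners onto u and v
  rx <- c(xr[1], xr[2], xr[2], xr[1]); ry <- c(yr[1], yr[1], yr[2], yr[2])
  ru <- (rx - origin[1]) * along[1] + (ry - origin[2]) * along[2]
  rv <- (rx - origin[1]) * perp[1] + (ry - origin[2]) * perp[2]
  if (max(ru) < u0 - eps || min(ru) > u1 + eps ||
      max(rv) < v0 - eps || min(rv) > v1 + eps) return(FALSE)
  TRUE
}

grid_geometry <- function(grid) attr(grid, "geometry")

# right-closed interval index: t in ((i-1)*size, i*size]; a point exactly
# on a shared edge gets the lower index (documented tie rule), and the
# domain origin (t = 0) belongs to the first cell.
.cell_index <- function(t, size) {
  i <- ceiling(t / size - 1e-9)
  i[abs(t) < 1e-9] <- pmax(1L, i[abs(t) < 1e-9])
  as.integer(i)
}

point_uv <- function(geom, x, y) {
  u <- (x - geom$origin[1]) * geom$along[1] +
       (y - geom$origin[2]) * geom$along[2]
  v <- (x - geom$origin[1]) * geom$perp[1] +
       (y - geom$origin[2]) * geom$perp[2]
  cbind(u = u, v = v)
}

#' Assign points to sampling-grid cells
#'
#' Points exactly on a shared cell edge are assigned to the cell with
#' the lower id; points on the zone boundary belong to the southern
#' zone. Points outside the study area (or in no grid cell) return `NA`.
#'
#' @param grid an [build_grid()] object.
#' @param x,y projected coordinates (km).
#' @return Character vector of cell ids.
#' @export
assign_cells <- function(grid, x, y) {
  geom <- grid_geometry(grid)
  out <- rep(NA_character_, length(x))
  inside <- x >= geom$extent_east[1] - 1e-9 &
            x <= geom$extent_east[2] + 1e-9 &
            y >= geom$extent_north[1] - 1e-9 &
            y <= geom$extent_north[2] + 1e-9
  south <- inside & y <= geom$y_split + 1e-9
  if (any(south)) {
    row <- .cell_index(y[south] - geom$extent_north[1],
                       geom$cell_size_south)
    col <- .cell_index(x[south] - geom$extent_east[1],
                       geom$cell_size_south)
    out[south] <- sprintf("S-r%02d-c%+03d", row, col)
  }
  northm <- inside & !south
  if (any(northm)) {
    uv <- point_uv(geom, x[northm], y[northm])
    row <- .cell_index(uv[, "v"], geom$cell_size_north)
    col <- as.integer(ceiling(uv[, "u"] / geom$cell_size_north - 1e-9))
    out[northm] <- sprintf("N-r%02d-c%+03d", row, col)
  }
  out[!is.na(out) & !(out %in% grid$cell_id)] <- NA_character_
  out
}

#' Cell polygons
#'
#' @param grid a sampling grid.
#' @param cell_ids cells to return (default all).
#' @return Named list of 4 x 2 corner matrices (counter-clockwise, km).
#' @export
cell_polygons <- function(grid, cell_ids = grid$cell_id) {
  geom <- grid_geometry(grid)
  idx <- match(cell_ids, grid$cell_id)
  if (anyNA(idx)) stop("unknown cell_id")
  out <- lapply(idx, function(i) {
    s <- grid$size[i]
    u0 <- (grid$col[i] - 1) * s; v0 <- (grid$row[i] - 1) * s
    cu <- c(u0, u0 + s, u0 + s, u0); cv <- c(v0, v0, v0 + s, v0 + s)
    if (grid$zone[i] == "S") {
      cbind(x = geom$extent_east[1] + cu, y = geom$extent_north[1] + cv)
    } else {
      cbind(x = geom$origin[1] + cu * geom$along[1] + cv * geom$perp[1],
            y = geom$origin[2] + cu * geom$along[2] + cv * geom$perp[2])
    }
  })
  names(out) <- cell_ids
  out
}

#' Transect lines bisecting each cell row
#'
#' One survey track line per cell row, clipped to the study area:
#' east-west lines in the southern zone, rotated lines in the north.
#'
#' @param grid a sampling grid.
#' @return Data frame with `zone`, `row`, and segment endpoints
#'   `x0, y0, x1, y1` (km).
#' @export
transects <- function(grid) {
  geom <- grid_geometry(grid)
  out <- list()
  for (r in sort(unique(grid$row[grid$zone == "S"]))) {
    yy <- geom$extent_north[1] + (r - 0.5) * geom$cell_size_south
    out[[length(out) + 1L]] <- data.frame(
      zone = "S", row = r, x0 = geom$extent_east[1], y0 = yy,
      x1 = geom$extent_east[2], y1 = yy)
  }
  for (r in sort(unique(grid$row[grid$zone == "N"]))) {
    # line v = (r - 1/2) * size in the rotated frame, clipped to the
    # northern sub-rectangle
    v <- (r - 0.5) * geom$cell_size_north
    base <- geom$origin + v * geom$perp
    hits <- clip_line_to_rect(base, geom$along,
                              geom$extent_east,
                              c(geom$y_split, geom$extent_north[2]))
    if (is.null(hits)) next
    out[[length(out) + 1L]] <- data.frame(
      zone = "N", row = r, x0 = hits[1, 1], y0 = hits[1, 2],
      x1 = hits[2, 1], y1 = hits[2, 2])
  }
  do.call(rbind, out)
}

# intersect the infinite line p(t) = base + t * dir with an axis-aligned
# rectangle; returns the two endpoints or NULL if it misses
clip_line_to_rect <- function(base, dir, xr, yr) {
  tmin <- -Inf; tmax <- Inf
  for (k in 1:2) {
    b <- base[k]; d <- dir[k]; lo <- c(xr[1], yr[1])[k]; hi <- c(xr[2], yr[2])[k]
    if (abs(d) < 1e-12) {
      if (b < lo - 1e-9 || b > hi + 1e-9) return(NULL)
    } else {
      t1 <- (lo - b) / d; t2 <- (hi - b) / d
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) return(NULL)
  rbind(base + tmin * dir, base + tmax * dir)
}

#' Clip a track segment to grid cells
#'
#' Splits a straight segment at every cell boundary it crosses and
#' returns the in-cell track length for each cell touched. Swath area is
#' later apportioned proportionally to in-cell length, which equals the
#' buffer-overlay answer for straight segments away from swath ends.
#'
#' @param grid a sampling grid.
#' @param x0,y0,x1,y1 segment endpoints (km).
#' @return Data frame with `cell_id` (`NA` for off-grid pieces) and
#'   `length` (km). Lengths sum exactly to the segment length.
#' @export
clip_segment_to_cells <- function(grid, x0, y0, x1, y1) {
  geom <- grid_geometry(grid)
  L <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (L < 1e-12)
    return(data.frame(cell_id = character(0), length = numeric(0)))
  # split at the zone boundary first
  tz <- numeric(0)
  if ((y0 - geom$y_split) * (y1 - geom$y_split) < 0)
    tz <- (geom$y_split - y0) / (y1 - y0)
  pieces <- list()
  bounds <- sort(unique(c(0, tz, 1)))
  for (i in seq_len(length(bounds) - 1L)) {
    ta <- bounds[i]; tb <- bounds[i + 1L]
    pa <- c(x0 + ta * (x1 - x0), y0 + ta * (y1 - y0))
    pb <- c(x0 + tb * (x1 - x0), y0 + tb * (y1 - y0))
    mid_y <- (pa[2] + pb[2]) / 2
    if (mid_y <= geom$y_split) {
      ua <- pa - c(geom$extent_east[1], geom$extent_north[1])
      ub <- pb - c(geom$extent_east[1], geom$extent_north[1])
      size <- geom$cell_size_south
    } else {
      ua <- drop(point_uv(geom, pa[1], pa[2]))
      ub <- drop(point_uv(geom, pb[1], pb[2]))
      size <- geom$cell_size_north
    }
    # crossings of integer cell boundaries in scaled coordinates
    ts <- c(0, 1)
    for (k in 1:2) {
      a <- ua[k] / size; b <- ub[k] / size
      if (abs(b - a) > 1e-12) {
        ints <- seq(ceiling(min(a, b)), floor(max(a, b)))
        ints <- ints[ints > min(a, b) + 1e-12 & ints < max(a, b) - 1e-12]
        if (length(ints)) ts <- c(ts, (ints - a) / (b - a))
      }
    }
    ts <- sort(unique(pmin(pmax(ts, 0), 1)))
    j <- seq_len(length(ts) - 1L)
    tm <- (ts[j] + ts[j + 1L]) / 2
    pieces[[length(pieces) + 1L]] <- data.frame(
      mx = pa[1] + tm * (pb[1] - pa[1]),
      my = pa[2] + tm * (pb[2] - pa[2]),
      length = (ts[j + 1L] - ts[j]) * (tb - ta) * L)
  }
  out <- do.call(rbind, pieces)
  out <- data.frame(cell_id = assign_cells(grid, out$mx, out$my),
                    length = out$length, stringsAsFactors = FALSE)
  na_len <- sum(out$length[is.na(out$cell_id)])
  ok <- out[!is.na(out$cell_id), , drop = FALSE]
  agg <- if (nrow(ok))
    stats::aggregate(length ~ cell_id, data = ok, sum)
  else data.frame(cell_id = character(0), length = numeric(0))
  # keep an NA (off-grid) row so callers can audit unassigned length
  if (na_len > 0)
    agg <- rbind(agg, data.frame(cell_id = NA_character_, length = na_len))
  rownames(agg) <- NULL
  agg
}
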