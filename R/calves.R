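#' Environmental conditions at exact sighting locations
#'
#' For demographic-segregation tests the original environmental layers
#' are sampled at the exact sighting points (not the sampling grid), to
#' maximise resolution: nearest-pixel bottom depth, daily SST at the
#' sighting date (missing when no image exists that day or the pixel is
#' cloud-masked), distance to shore from the point, and signed distance
#' to the semimonthly 22 C isotherm (sign and distance from the
#' semimonthly composite). Records with an estimated depth above sea
#' level are excluded (data-precision rule), as are sightings outside
#' the environmental layers; a `group_class` column of "other" (lone
#' calves, associated pairs) is excluded from both groups when present.
#'
#' @param sightings on-effort sighting table with `x`, `y`, `date`,
#'   `calf_present` (and optionally `group_class`).
#' @param env an `rw_environment` (or compatible list).
#' @param iso_level isotherm level (C).
#' @return Data frame of class `rw_sighting_env`: `sighting_id`,
#'   `calf_present`, `depth_m`, `dist_shore_km`, `sst_c`,
#'   `dist_iso_km`, `northing_km`, `semimonth`, `season`; attribute
#'   `n_excluded` counts dropped records by reason.
#' @export
extract_sighting_env <- function(sightings, env, iso_level = 22) {
  n0 <- nrow(sightings)
  if ("group_class" %in% names(sightings)) {
    keep <- sightings$group_class %in% c("calf", "no_calf")
    n_other <- sum(!keep)
    sightings <- sightings[keep, , drop = FALSE]
  } else n_other <- 0L
  bx <- env$bathy$x; by <- env$bathy$y
  ix <- pmin(pmax(findInterval(sightings$x, bx - (bx[2] - bx[1]) / 2), 1),
             length(bx))
  iy <- pmin(pmax(findInterval(sightings$y, by - (by[2] - by[1]) / 2), 1),
             length(by))
  inside <- sightings$x >= min(bx) - (bx[2] - bx[1]) / 2 &
    sightings$x <= max(bx) + (bx[2] - bx[1]) / 2 &
    sightings$y >= min(by) - (by[2] - by[1]) / 2 &
    sightings$y <= max(by) + (by[2] - by[1]) / 2
  n_outside <- sum(!inside)
  depth <- env$bathy$z[cbind(ix, iy)]
  depth[!inside] <- NA_real_

  sm <- assign_semimonth(sightings$date)
  dsh <- distance_to_shore(sightings$x, sightings$y, env$shoreline)

  # daily SST at the sighting date, cloud-masked
  sst <- rep(NA_real_, nrow(sightings))
  img_date <- vapply(env$images, function(im) as.character(im$date), "")
  for (i in seq_len(nrow(sightings))) {
    j <- which(img_date == as.character(sightings$date[i]))
    if (!length(j)) next
    im <- env$images[[j[1]]]
    if (!im$cloud[ix[i], iy[i]]) sst[i] <- im$values[ix[i], iy[i]]
  }

  # semimonthly composite for the isotherm and its sign
  diso <- rep(NA_real_, nrow(sightings))
  key <- paste(sm$season_start_year, sm$semimonth)
  img_key <- vapply(env$images, function(im)
    paste(im$season_start_year, im$semimonth), "")
  for (kk in unique(key)) {
    imgs <- env$images[img_key == kk]
    if (!length(imgs)) next
    comp <- composite_sst(imgs)
    iso <- extract_isotherm(comp, iso_level)
    rows <- which(key == kk)
    comp_sst <- comp$mean[cbind(ix[rows], iy[rows])]
    diso[rows] <- isotherm_distance(sightings$x[rows], sightings$y[rows],
                                    comp_sst, iso, iso_level)
  }

  out <- data.frame(
    sighting_id = if ("sighting_id" %in% names(sightings))
      sightings$sighting_id else seq_len(nrow(sightings)),
    calf_present = as.logical(sightings$calf_present),
    depth_m = depth, dist_shore_km = dsh, sst_c = sst,
    dist_iso_km = diso, northing_km = sightings$y,
    semimonth = sm$semimonth, season = sm$season,
    stringsAsFactors = FALSE)
  above <- !is.na(out$depth_m) & out$depth_m <= 0
  dropped_na <- is.na(out$depth_m)
  out <- out[!above & !dropped_na, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- c(other_group = n_other,
                               outside_layers = n_outside,
                               above_sea_level = sum(above))
  class(out) <- c("rw_sighting_env", "data.frame")
  out
}

#' Mann-Whitney two-sample test
#'
#' Rank-sum test with midranks for ties. `U` counts pairs where a
#' group-A value exceeds a group-B value (ties count one half). For
#' small samples (`n1 + n2 <=` `exact_threshold`) the two-sided p-value
#' is computed by exact enumeration of all group assignments of the
#' pooled values; otherwise by normal approximation with tie-corrected
#' variance and (by default) continuity correction,
#' `z = (U - n1 n2 / 2 -+ 1/2) / sd`.
#'
#' @param a,b numeric samples (both non-empty).
#' @param exact_threshold largest pooled size for exact enumeration.
#' @param continuity apply the 1/2 continuity correction in the normal
#'   approximation?
#' @return List of class `rw_mw`: `U`, `z`, `p`, `method`, `n1`, `n2`,
#'   group means and ranges.
#' @export
mann_whitney <- function(a, b, exact_threshold = 12, continuity = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (!n1 || !n2) stop("both groups must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(structure(list(U = n1 * n2 / 2, z = 0, p = 1,
                          method = "degenerate", n1 = n1, n2 = n2,
                          mean_a = mean(a), mean_b = mean(b),
                          range_a = range(a), range_b = range(b)),
                     class = "rw_mw"))
  }
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_threshold) {
    combs <- utils::combn(n1 + n2, n1)
    dev_obs <- abs(U - n1 * n2 / 2)
    us <- apply(combs, 2, function(idx)
      sum(rk[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - n1 * n2 / 2) >= dev_obs - 1e-9)
    method <- "exact"
    sdU <- stats::sd(us) * sqrt((ncol(combs) - 1) / ncol(combs))
    z <- if (sdU > 0) (U - n1 * n2 / 2) / sdU else 0
  } else {
    ties <- table(pooled)
    N <- n1 + n2
    varU <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    sdU <- sqrt(varU)
    cc <- if (continuity) 0.5 else 0
    num <- U - n1 * n2 / 2
    z <- if (sdU > 0) sign(num) * max(abs(num) - cc, 0) / sdU else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(U = U, z = z, p = p, method = method, n1 = n1, n2 = n2,
                 mean_a = mean(a), mean_b = mean(b),
                 range_a = range(a), range_b = range(b)),
            class = "rw_mw")
}

#' @export
print.rw_mw <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney: U = %.1f, z = %.2f, p = %.4g (%s; n1 = %d, n2 = %d)\n",
    x$U, x$z, x$p, x$method, x$n1, x$n2))
  invisible(x)
}

#' Holm sequential Bonferroni decisions
#'
#' Step-down procedure over a family of m p-values: order them
#' ascending and compare the i-th smallest to `alpha / (m - i + 1)`,
#' stopping at the first failure. Uniformly no less powerful than plain
#' Bonferroni and never rejects where unadjusted testing would not.
#'
#' @param p p-values.
#' @param alpha family-wise level.
#' @return Logical rejection vector in the original order.
#' @export
sequential_bonferroni <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (is.na(p[ord[i]])) break
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE
    else break
  }
  reject
}

#' Calf-segregation habitat comparison table
#'
#' Mann-Whitney comparison of each environmental variable between
#' sightings with and without a calf, pooled across years and
#' semimonths, reported with group means and ranges.
#'
#' @param records an [extract_sighting_env()] table.
#' @param variables columns to compare.
#' @param continuity passed to [mann_whitney()].
#' @return Data frame, one row per variable: group means/ranges, `U`,
#'   `z`, `p`, group sizes.
#' @export
calf_habitat_table <- function(records,
                               variables = c("depth_m", "dist_shore_km",
                                             "sst_c", "dist_iso_km"),
                               continuity = TRUE) {
  out <- lapply(variables, function(v) {
    a <- records[[v]][records$calf_present]
    b <- records[[v]][!records$calf_present]
    m <- mann_whitney(a, b, continuity = continuity)
    data.frame(variable = v,
               calf_mean = m$mean_a, calf_min = m$range_a[1],
               calf_max = m$range_a[2],
               nocalf_mean = m$mean_b, nocalf_min = m$range_b[1],
               nocalf_max = m$range_b[2],
               n_calf = m$n1, n_nocalf = m$n2,
               U = m$U, z = m$z, p = m$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-semimonth northing comparisons with sequential Bonferroni
#'
#' Because of migration timing, northings of calf and no-calf sightings
#' are compared separately within each of the eight semimonthly
#' periods; the family of p-values is adjusted with Holm's sequential
#' Bonferroni. Periods lacking one of the groups are skipped and
#' reported.
#'
#' @param records an [extract_sighting_env()] table.
#' @param alpha family-wise level.
#' @param continuity passed to [mann_whitney()].
#' @return Data frame with one row per testable semimonth: group sizes,
#'   mean northings, `U`, `z`, `p`, `reject` (Holm decision); skipped
#'   periods are listed in the `skipped` attribute.
#' @export
semimonth_northing_comparisons <- function(records, alpha = 0.05,
                                           continuity = TRUE) {
  rows <- list(); skipped <- integer(0)
  for (sm in sort(unique(records$semimonth))) {
    rr <- records[records$semimonth == sm, ]
    a <- rr$northing_km[rr$calf_present]
    b <- rr$northing_km[!rr$calf_present]
    if (!length(a) || !length(b)) { skipped <- c(skipped, sm); next }
    m <- mann_whitney(a, b, continuity = continuity)
    rows[[length(rows) + 1L]] <- data.frame(
      semimonth = sm, n_calf = m$n1, n_nocalf = m$n2,
      calf_mean_northing = m$mean_a, nocalf_mean_northing = m$mean_b,
      U = m$U, z = m$z, p = m$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$reject <- sequential_bonferroni(out$p, alpha)
  attr(out, "skipped") <- skipped
  out
}
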