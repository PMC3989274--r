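#' Global Moran's I with inverse-distance weights
#'
#' Spatial autocorrelation of residuals treating all grid cells as
#' neighbours, weighted by inverse distance so nearby cells exert
#' greater influence: `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i
#' z_i^2` with `w_ij = 1 / d_ij`, `w_ii = 0`, `S0 = sum w_ij` and `z`
#' the centred values. The expectation under independence is
#' `-1 / (n - 1)`; the z-score uses the normality-assumption variance.
#' The unstandardized statistic can exceed `[-1, 1]` slightly;
#' row-standardized weights are available as an option.
#'
#' @param values residual (or any) values, one per cell.
#' @param x,y cell-centre coordinates (km); coincident centres are
#'   rejected (infinite weight).
#' @param row_standardize divide each row of the weight matrix by its
#'   sum?
#' @return List of class `rw_moran`: `I`, `n`, `expected`, `sd`, `z`,
#'   `p` (two-sided normal), `weighting`, `degenerate` (TRUE with `I =
#'   NA` when n < 3 or the values have zero variance).
#' @export
morans_i <- function(values, x, y, row_standardize = FALSE) {
  keep <- is.finite(values) & is.finite(x) & is.finite(y)
  values <- values[keep]; x <- x[keep]; y <- y[keep]
  n <- length(values)
  weighting <- paste0("inverse_distance",
                      if (row_standardize) "_row_standardized")
  if (n < 3 || stats::var(values) == 0) {
    return(structure(list(I = NA_real_, n = n,
                          expected = if (n > 1) -1 / (n - 1) else NA_real_,
                          sd = NA_real_, z = NA_real_, p = NA_real_,
                          weighting = weighting, degenerate = TRUE),
                     class = "rw_moran"))
  }
  d <- as.matrix(stats::dist(cbind(x, y)))
  if (any(d[upper.tri(d)] == 0))
    stop("coincident cell centres give infinite inverse-distance weights")
  w <- 1 / d
  diag(w) <- 0
  if (row_standardize) w <- w / rowSums(w)
  z <- values - mean(values)
  s0 <- sum(w)
  I <- (n / s0) * sum(w * tcrossprod(z)) / sum(z^2)
  # normality-assumption moments
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  eI <- -1 / (n - 1)
  varI <- (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - eI^2
  sdI <- sqrt(max(varI, 0))
  zscore <- (I - eI) / sdI
  structure(list(I = I, n = n, expected = eI, sd = sdI, z = zscore,
                 p = 2 * stats::pnorm(-abs(zscore)),
                 weighting = weighting, degenerate = FALSE),
            class = "rw_moran")
}

#' @export
print.rw_moran <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Moran's I: degenerate (n = %d or zero variance)\n", x$n))
  } else {
    cat(sprintf(
      "Moran's I = %.4f (n = %d, E[I] = %.4f, z = %.2f, p = %.3g; %s)\n",
      x$I, x$n, x$expected, x$z, x$p, x$weighting))
  }
  invisible(x)
}

#' Moran's I of hurdle deviance residuals per semimonth
#'
#' Computes [residuals.rw_hurdle()] on the supplied units and the
#' global inverse-distance Moran's I of those residuals separately for
#' every season-semimonth, using only unmasked units with observations
#' in that period.
#'
#' @param hurdle an [fit_hurdle()] model.
#' @param units sampling units with observed counts and coordinates.
#' @param row_standardize passed to [morans_i()].
#' @return Data frame: `season`, `semimonth`, `n`, `I`, `expected`,
#'   `z`, `p`, `degenerate`.
#' @export
moran_by_semimonth <- function(hurdle, units, row_standardize = FALSE) {
  r <- stats::residuals(hurdle, units)
  key <- interaction(units$season, units$semimonth, drop = TRUE)
  out <- lapply(levels(key), function(kk) {
    i <- which(key == kk & !is.na(r))
    m <- if (length(i) >= 3)
      morans_i(r[i], units$easting_km[i], units$northing_km[i],
               row_standardize)
    else list(I = NA_real_, n = length(i), expected = NA_real_,
              z = NA_real_, p = NA_real_, degenerate = TRUE)
    data.frame(season = units$season[key == kk][1],
               semimonth = units$semimonth[key == kk][1],
               n = m$n, I = m$I, expected = m$expected, z = m$z,
               p = m$p, degenerate = isTRUE(m$degenerate),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$season, out$semimonth), ]
}
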