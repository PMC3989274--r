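#' Fit the semimonthly hurdle habitat model
#'
#' The central model of the package: whale counts per sampling unit are
#' zero-inflated (the sighting record is dominated by units with no
#' whales), so occurrence and positive abundance are modelled
#' separately and multiplied. The presence component is a
#' quasibinomial-logit GAM of the presence indicator over all included
#' units; the abundance component is a Gamma-log GAM of the whale count
#' over units with at least one whale. Both use shrinkage smooths at
#' basis dimension `k = 3` with GCV-selected smoothing parameters.
#' Predicted relative abundance (sighted whales per unit at a reference
#' survey effort) is the product of the occurrence probability and the
#' conditional expected count.
#'
#' @param units sampling-unit table with covariates
#'   ([add_unit_covariates()]); excluded units and units with missing
#'   model covariates are dropped (accounted in the result).
#' @param presence_terms,abundance_terms term labels for each component
#'   (see [term_formula()]); defaults are the full candidate sets with
#'   effort in the presence component only (effort raises the
#'   abundance-component GCV and is excluded there).
#' @param k basis dimension.
#' @param effort_ref reference survey effort (km^2) for prediction
#'   maps; 250 km^2 lies where the presence-effort smooth plateaus.
#' @param min_positive minimum number of positive units required.
#' @return Object of class `rw_hurdle` with components `presence` and
#'   `abundance` ([hab_gam()] fits), the training data, dropped-row
#'   accounting and `effort_ref`.
#' @seealso [predict.rw_hurdle()], [residuals.rw_hurdle()],
#'   [stepwise_select()]
#' @export
fit_hurdle <- function(units,
                       presence_terms = c("mig", "dist_shore", "year",
                                          "effort", "sst", "depth",
                                          "dist_iso"),
                       abundance_terms = c("mig", "year", "sst",
                                           "dist_iso", "dist_shore",
                                           "depth"),
                       k = 3, effort_ref = 250, min_positive = 30) {
  dat <- units[!units$excluded, , drop = FALSE]
  need <- unique(c(unlist(lapply(presence_terms, term_columns)),
                   unlist(lapply(abundance_terms, term_columns))))
  need <- setdiff(need, "year")
  cc <- stats::complete.cases(dat[, need, drop = FALSE])
  n_dropped <- sum(!cc) + sum(units$excluded)
  dat <- dat[cc, , drop = FALSE]
  if (!nrow(dat)) stop("no usable sampling units")
  dat$presence <- as.numeric(dat$whales > 0)
  if (all(dat$presence == 0) || all(dat$presence == 1))
    stop("degenerate presence response (all zero or all positive)")
  pos <- dat[dat$whales > 0, , drop = FALSE]
  if (nrow(pos) < min_positive)
    stop("fewer than ", min_positive, " positive sampling units")
  presence <- hab_gam(dat, "presence", presence_terms,
                      family = "quasibinomial", k = k)
  abundance <- hab_gam(pos, "whales", abundance_terms,
                       family = "Gamma", k = k)
  structure(list(presence = presence, abundance = abundance,
                 data = dat, n_positive = nrow(pos),
                 n_dropped = n_dropped, effort_ref = effort_ref,
                 k = k),
            class = "rw_hurdle")
}

#' Predict relative abundance from a hurdle model
#'
#' Component predictions with standard errors and their product, the
#' relative abundance surface. Survey effort is overridden to the
#' constant reference value everywhere so that variable effort does not
#' confound the predicted distribution. Rows with covariates outside
#' the training range, missing covariates, or years unseen in training
#' are masked with a reason (hindcasts only; no extrapolation). The
#' product's standard error uses the delta method under component
#' independence: `Var(RA) ~ p^2 Var(E) + E^2 Var(p)`.
#'
#' @param object an [fit_hurdle()] model.
#' @param newdata covariate rows (defaults to the training units).
#' @param effort_ref reference effort (km^2); must lie inside the
#'   presence component's training effort range.
#' @param exclude_out_of_range mask out-of-range covariates?
#' @param ... unused.
#' @return Data frame of class `rw_prediction`: any id columns
#'   (`cell_id`, `season`, `semimonth`, `northing_km`, `easting_km`)
#'   carried from `newdata`, then `p_presence`, `se_p`, `e_abundance`,
#'   `se_e`, `rel_abundance`, `se_ra`, `masked`, `mask_reason`.
#' @export
predict.rw_hurdle <- function(object, newdata = object$data,
                              effort_ref = object$effort_ref,
                              exclude_out_of_range = TRUE, ...) {
  nd <- as.data.frame(newdata)
  if ("effort_km2" %in% names(object$presence$ranges)) {
    r <- object$presence$ranges$effort_km2
    if (effort_ref < r[1] || effort_ref > r[2])
      stop(sprintf(
        "effort_ref %.1f outside the presence training range [%.1f, %.1f]",
        effort_ref, r[1], r[2]))
    nd$effort_km2 <- effort_ref
  }
  pp <- predict_units(object$presence, nd, exclude_out_of_range)
  pa <- predict_units(object$abundance, nd, exclude_out_of_range)
  masked <- pp$masked | pa$masked
  reason <- ifelse(pp$masked, pp$mask_reason, pa$mask_reason)
  p <- ifelse(masked, NA_real_, pp$response)
  e <- ifelse(masked, NA_real_, pa$response)
  sp <- ifelse(masked, NA_real_, pp$se_response)
  se <- ifelse(masked, NA_real_, pa$se_response)
  ids <- intersect(c("cell_id", "season", "season_start_year",
                     "semimonth", "northing_km", "easting_km"),
                   names(nd))
  out <- cbind(nd[, ids, drop = FALSE],
               data.frame(p_presence = p, se_p = sp,
                          e_abundance = e, se_e = se,
                          rel_abundance = p * e,
                          se_ra = sqrt(p^2 * se^2 + e^2 * sp^2),
                          masked = masked, mask_reason = reason,
                          stringsAsFactors = FALSE))
  class(out) <- c("rw_prediction", "data.frame")
  out
}

#' Constant-effort hindcast prediction map
#'
#' Thin wrapper over [predict.rw_hurdle()] that predicts every
#' cell-semimonth row of a covariate table at the reference effort,
#' keyed by cell and period.
#'
#' @inheritParams predict.rw_hurdle
#' @param cells covariate table with one row per cell x semimonth.
#' @return An `rw_prediction` data frame.
#' @export
predict_map <- function(object, cells, effort_ref = object$effort_ref) {
  stats::predict(object, newdata = cells, effort_ref = effort_ref)
}

#' Composite deviance residuals of a hurdle model
#'
#' Signed square-root deviance contributions of the observed whale
#' count against the predicted relative abundance. Positive counts use
#' the Gamma deviance form
#' `d = 2 (-log(y / mu) + (y - mu) / mu)` with `mu` the predicted
#' relative abundance; zero counts take their contribution from the
#' presence component, `d = -2 log(1 - p)`, with a negative sign
#' (observed below prediction). This composite definition is a
#' documented package choice. The result carries an over/under
#' prediction summary split by observed presence.
#'
#' @param object an [fit_hurdle()] model.
#' @param newdata units with observed `whales` (default training data).
#' @param ... unused.
#' @return Numeric vector of residuals (`NA` for masked units), with
#'   attributes `summary` (mean observed and predicted by presence
#'   stratum) and `n_skipped`.
#' @export
residuals.rw_hurdle <- function(object, newdata = object$data, ...) {
  pr <- stats::predict(object, newdata = newdata,
                       exclude_out_of_range = FALSE)
  y <- newdata$whales
  mu <- pr$rel_abundance
  p <- pr$p_presence
  r <- rep(NA_real_, length(y))
  pos <- !pr$masked & y > 0
  zer <- !pr$masked & y == 0
  r[pos] <- sign(y[pos] - mu[pos]) *
    sqrt(pmax(2 * (-log(y[pos] / mu[pos]) + (y[pos] - mu[pos]) / mu[pos]),
              0))
  r[zer] <- -sqrt(pmax(-2 * log1p(-pmin(p[zer], 1 - 1e-12)), 0))
  summ <- data.frame(
    stratum = c("whales_absent", "whales_present"),
    mean_observed = c(mean(y[zer]), mean(y[pos])),
    mean_predicted = c(mean(mu[zer]), mean(mu[pos])))
  attr(r, "summary") <- summ
  attr(r, "n_skipped") <- sum(pr$masked)
  r
}

#' @export
print.rw_hurdle <- function(x, ...) {
  cat("Hurdle habitat model (occurrence x positive abundance)\n")
  cat(sprintf("  units: %d (%d with whales); %d dropped/excluded\n",
              nrow(x$data), x$n_positive, x$n_dropped))
  cat("  presence:  "); print(x$presence)
  cat("  abundance: "); print(x$abundance)
  invisible(x)
}

#' @export
summary.rw_hurdle <- function(object, ...) {
  out <- list(
    n_units = nrow(object$data), n_positive = object$n_positive,
    n_dropped = object$n_dropped, effort_ref = object$effort_ref,
    presence = list(terms = object$presence$terms,
                    gcv = gcv_score(object$presence),
                    pct_deviance = percent_deviance(object$presence),
                    edf = edf_terms(object$presence),
                    scale = object$presence$gam$sig2),
    abundance = list(terms = object$abundance$terms,
                     gcv = gcv_score(object$abundance),
                     pct_deviance = percent_deviance(object$abundance),
                     edf = edf_terms(object$abundance),
                     scale = object$abundance$gam$sig2))
  class(out) <- "summary.rw_hurdle"
  out
}

#' @export
print.summary.rw_hurdle <- function(x, ...) {
  cat("Hurdle habitat model summary\n")
  cat(sprintf("  %d units, %d positive, %d dropped; effort reference %.0f km2\n",
              x$n_units, x$n_positive, x$n_dropped, x$effort_ref))
  for (comp in c("presence", "abundance")) {
    c_ <- x[[comp]]
    cat(sprintf("  %s: %s\n", comp, paste(c_$terms, collapse = " + ")))
    cat(sprintf("    GCV %.5g, deviance explained %.1f%%, scale %.3g\n",
                c_$gcv, c_$pct_deviance, c_$scale))
  }
  invisible(x)
}

#' Plot fitted partial effects
#'
#' One panel per smooth term of the chosen component, on the linear
#' predictor scale with a pointwise 2-standard-error band (dashed), in
#' the style habitat-model smooth-function figures are usually drawn.
#'
#' @param x an [fit_hurdle()] model.
#' @param component `"presence"` or `"abundance"`.
#' @param ... passed to `plot`.
#' @export
plot.rw_hurdle <- function(x, component = c("presence", "abundance"),
                           ...) {
  component <- match.arg(component)
  fit <- x[[component]]
  labs <- setdiff(fit$terms, c("year", "mig"))
  n <- length(labs)
  if (!n) return(invisible(x))
  op <- graphics::par(mfrow = c(ceiling(n / 2), min(n, 2)),
                      mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (lb in labs) {
    pe <- partial_effect(fit, lb)
    ylim <- range(pe$fit + 2 * pe$se, pe$fit - 2 * pe$se)
    plot(pe$x, pe$fit, type = "l", xlab = lb,
         ylab = sprintf("s(%s)", lb), ylim = ylim, ...)
    graphics::lines(pe$x, pe$fit + 2 * pe$se, lty = 2)
    graphics::lines(pe$x, pe$fit - 2 * pe$se, lty = 2)
    graphics::abline(h = 0, col = "grey")
  }
  invisible(x)
}

#' Variance-inflation-factor screening report
#'
#' Pre-selection collinearity report: VIF of each numeric candidate
#' covariate from a linear regression on the others. Covariates above
#' the threshold are reported, not automatically excluded (dropping
#' easting/slope is a configuration choice).
#'
#' @param units sampling-unit table.
#' @param covariates numeric covariate columns to screen.
#' @param threshold flag level (default 5).
#' @return Data frame `covariate`, `vif`, `flagged`.
#' @export
vif_screen <- function(units,
                       covariates = c("effort_km2", "sst_c",
                                      "dist_shore_km", "depth_m",
                                      "dist_iso_km", "northing_km"),
                       threshold = 5) {
  d <- units[, covariates, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  vif <- vapply(covariates, function(v) {
    fml <- stats::as.formula(paste(v, "~ ."))
    r2 <- summary(stats::lm(fml, data = d))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  data.frame(covariate = covariates, vif = unname(vif),
             flagged = unname(vif) > threshold)
}
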