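#' Habitat-model GAM terms
#'
#' The candidate term set of the semimonthly hurdle model. Labels map to
#' model formula components: univariate penalized cubic regression
#' splines with shrinkage (`bs = "cs"`) at basis dimension `k = 3`
#' (limiting each smooth to at most 2 effective degrees of freedom), a
#' tensor-product surface for the semimonth-by-northing migration
#' interaction, and an unpenalized factor for survey year.
#'
#' @param label one of `"effort"`, `"sst"`, `"dist_shore"`, `"depth"`,
#'   `"dist_iso"`, `"mig"` (semimonth x northing interaction), `"year"`.
#' @param k basis dimension.
#' @return A formula fragment as character.
#' @export
term_formula <- function(label, k = 3) {
  cols <- c(effort = "effort_km2", sst = "sst_c",
            dist_shore = "dist_shore_km", depth = "depth_m",
            dist_iso = "dist_iso_km")
  if (label %in% names(cols))
    return(sprintf("s(%s, k = %d, bs = \"cs\")", cols[[label]], k))
  if (label == "mig")
    return(sprintf("te(semimonth, northing_km, k = c(%d, %d), bs = \"cs\")",
                   k, k))
  if (label == "year") return("year")
  # any other label is taken as a raw column name to smooth
  sprintf("s(%s, k = %d, bs = \"cs\")", label, k)
}

term_columns <- function(label) {
  cols <- c(effort = "effort_km2", sst = "sst_c",
            dist_shore = "dist_shore_km", depth = "depth_m",
            dist_iso = "dist_iso_km")
  if (label %in% names(cols)) return(cols[[label]])
  if (label == "mig") return(c("semimonth", "northing_km"))
  if (label == "year") return("year")
  label
}

#' Fit one component GAM of the hurdle model
#'
#' Penalized-regression-spline GAM with shrinkage smooths at basis
#' dimension `k` and smoothing parameters chosen by minimizing the GCV
#' score `n D / (n - edf)^2` (mgcv's `GCV.Cp`). Families: quasibinomial
#' with logit link for presence-absence, Gamma with log link for
#' positive whale counts, gaussian for engine-level checks.
#'
#' @param data sampling-unit data.
#' @param response name of the response column.
#' @param terms character vector of term labels ([term_formula()]);
#'   empty for the null (intercept-only) model.
#' @param family `"quasibinomial"`, `"Gamma"` or `"gaussian"`.
#' @param k basis dimension (3 by default).
#' @param sp optional fixed smoothing-parameter vector (bypasses GCV
#'   selection; `0` gives the unpenalized fit).
#' @param gamma GCV inflation factor (1 = plain GCV).
#' @return Object of class `rw_gam`: the mgcv fit (`$gam`), term
#'   labels, the training covariate ranges and factor levels used for
#'   prediction masking, and cached scores.
#' @export
hab_gam <- function(data, response, terms = character(0),
                    family = c("quasibinomial", "Gamma", "gaussian"),
                    k = 3, sp = NULL, gamma = 1) {
  family <- match.arg(family)
  fam <- switch(family,
                quasibinomial = stats::quasibinomial(link = "logit"),
                Gamma = stats::Gamma(link = "log"),
                gaussian = stats::gaussian())
  if (family == "Gamma" && any(data[[response]] <= 0))
    stop("Gamma-log component requires strictly positive responses")
  if (family == "Gamma" && stats::var(data[[response]]) == 0)
    stop("degenerate positive-abundance response (all counts equal)")
  if ("year" %in% terms) {
    data$year <- factor(data$year)
    # a single-season data set has no interannual contrast to estimate
    if (nlevels(data$year) < 2) terms <- setdiff(terms, "year")
  }
  rhs <- if (length(terms)) paste(vapply(terms, term_formula, "", k = k),
                                  collapse = " + ") else "1"
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- mgcv::gam(form, family = fam, data = data, method = "GCV.Cp",
                   sp = sp, gamma = gamma,
                   control = mgcv::gam.control(epsilon = 1e-10,
                                               maxit = 200))
  if (!fit$converged)
    warning("GAM fit did not converge")
  num_cols <- unique(unlist(lapply(setdiff(terms, "year"), term_columns)))
  ranges <- lapply(num_cols, function(cc) range(data[[cc]], na.rm = TRUE))
  names(ranges) <- num_cols
  structure(list(
    gam = fit, terms = terms, family = family, response = response,
    k = k, ranges = ranges,
    year_levels = if ("year" %in% terms) levels(data$year) else NULL,
    n = length(fit$y)
  ), class = "rw_gam")
}

#' GCV score, deviance and percent deviance explained
#'
#' `gcv_score` returns mgcv's minimized GCV `n D / (n - edf)^2`;
#' `fit_deviance` the family deviance; `percent_deviance` the
#' percentage of null deviance explained.
#'
#' @param fit an [hab_gam()] object.
#' @return A scalar.
#' @export
gcv_score <- function(fit) unname(fit$gam$gcv.ubre)

#' @rdname gcv_score
#' @export
fit_deviance <- function(fit) stats::deviance(fit$gam)

#' @rdname gcv_score
#' @export
percent_deviance <- function(fit) {
  100 * (fit$gam$null.deviance - stats::deviance(fit$gam)) /
    fit$gam$null.deviance
}

#' Total and per-term effective degrees of freedom
#' @param fit an [hab_gam()] object.
#' @return `edf_total`: scalar; `edf_terms`: named vector over smooths.
#' @export
edf_total <- function(fit) sum(fit$gam$edf)

#' @rdname edf_total
#' @export
edf_terms <- function(fit) {
  sm <- fit$gam$smooth
  if (!length(sm)) return(numeric(0))
  out <- vapply(sm, function(s)
    sum(fit$gam$edf[s$first.para:s$last.para]), numeric(1))
  names(out) <- vapply(sm, function(s) s$label, character(1))
  out
}

#' Predict from a component GAM with range masking
#'
#' Linear-predictor and response-scale predictions with standard
#' errors. When `exclude_out_of_range` is set (the default, matching
#' the no-extrapolation rule), rows with any smooth covariate outside
#' its training range, unseen factor levels, or missing covariates are
#' masked with a reason rather than predicted.
#'
#' @param fit an [hab_gam()] object.
#' @param newdata data frame with the model's covariate columns.
#' @param exclude_out_of_range mask rows outside the training ranges?
#' @return Data frame: `eta`, `se_eta`, `response`, `se_response`,
#'   `masked`, `mask_reason`.
#' @export
predict_units <- function(fit, newdata, exclude_out_of_range = TRUE) {
  n <- nrow(newdata)
  masked <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  num_cols <- names(fit$ranges)
  miss <- setdiff(c(num_cols, if (!is.null(fit$year_levels)) "year"),
                  names(newdata))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  for (cc in num_cols) {
    v <- newdata[[cc]]
    bad_na <- is.na(v)
    if (any(bad_na)) {
      reason[bad_na & !masked] <- paste0("missing:", cc)
      masked <- masked | bad_na
    }
    if (exclude_out_of_range) {
      oor <- !is.na(v) & (v < fit$ranges[[cc]][1] | v > fit$ranges[[cc]][2])
      if (any(oor)) {
        reason[oor & !masked] <- paste0("out_of_range:", cc)
        masked <- masked | oor
      }
    }
  }
  if (!is.null(fit$year_levels)) {
    unseen <- !(as.character(newdata$year) %in% fit$year_levels)
    if (any(unseen)) {
      reason[unseen & !masked] <- "unseen_year"
      masked <- masked | unseen
    }
    newdata$year <- factor(as.character(newdata$year),
                           levels = fit$year_levels)
  }
  eta <- se <- rep(NA_real_, n)
  if (any(!masked)) {
    nd <- newdata[!masked, , drop = FALSE]
    pr <- mgcv::predict.gam(fit$gam, newdata = nd, type = "link",
                            se.fit = TRUE)
    eta[!masked] <- as.numeric(pr$fit)
    se[!masked] <- as.numeric(pr$se.fit)
  }
  inv <- fit$gam$family$linkinv
  mu_eta <- fit$gam$family$mu.eta
  data.frame(eta = eta, se_eta = se,
             response = inv(eta),
             se_response = abs(mu_eta(eta)) * se,
             masked = masked, mask_reason = reason,
             stringsAsFactors = FALSE)
}

#' Partial effect of a smooth term
#'
#' Evaluates one fitted smooth (centred partial effect on the linear
#' predictor scale) with pointwise standard errors over a grid of the
#' covariate, holding other covariates at training medians.
#'
#' @param fit an [hab_gam()] object.
#' @param label term label ([term_formula()]).
#' @param n grid size.
#' @param values optional explicit covariate values.
#' @return Data frame `x`, `fit`, `se` (for `"mig"`: `semimonth`,
#'   `northing_km`, `fit`, `se`).
#' @export
partial_effect <- function(fit, label, n = 100, values = NULL) {
  mf <- fit$gam$model
  cols <- term_columns(label)
  smooth_labels <- vapply(fit$gam$smooth, function(s) s$label, character(1))
  target <- if (label == "mig") {
    grep("^te\\(semimonth", smooth_labels, value = TRUE)
  } else {
    grep(paste0("^s\\(", cols[1]), smooth_labels, value = TRUE)
  }
  if (!length(target)) stop("term not in model: ", label)
  base <- mf[rep(1, 1), , drop = FALSE]
  if (label == "mig") {
    if (is.null(values)) {
      values <- expand.grid(
        semimonth = 1:8,
        northing_km = seq(min(mf$northing_km), max(mf$northing_km),
                          length.out = 25))
    }
    nd <- values
  } else {
    if (is.null(values))
      values <- seq(min(mf[[cols]]), max(mf[[cols]]), length.out = n)
    nd <- data.frame(values); names(nd) <- cols
  }
  # fill remaining covariates with medians / first level
  for (cc in names(mf)) {
    if (cc %in% names(nd)) next
    v <- mf[[cc]]
    nd[[cc]] <- if (is.factor(v)) factor(levels(v)[1], levels = levels(v))
      else stats::median(v)
  }
  pr <- mgcv::predict.gam(fit$gam, newdata = nd, type = "terms",
                          terms = target, se.fit = TRUE)
  out <- if (label == "mig") {
    data.frame(semimonth = nd$semimonth, northing_km = nd$northing_km,
               fit = as.numeric(pr$fit[, 1]),
               se = as.numeric(pr$se.fit[, 1]))
  } else {
    data.frame(x = nd[[cols]], fit = as.numeric(pr$fit[, 1]),
               se = as.numeric(pr$se.fit[, 1]))
  }
  out
}

#' Low-level shrinkage-spline basis
#'
#' Exposes the design columns and penalty of a single centred cubic
#' regression spline ([mgcv::smoothCon()]): with `k` knots at covariate
#' quantiles and the sum-to-zero identifiability constraint absorbed,
#' yielding `k - 1` columns. With `shrinkage = TRUE` the penalty's null
#' space is given a small positive eigenvalue so that as the smoothing
#' parameter grows the whole term shrinks to zero.
#'
#' @param x covariate values (at least `k` distinct).
#' @param k basis dimension.
#' @param shrinkage use the shrinkage variant?
#' @return List with design matrix `X` and penalty `S`.
#' @export
build_basis <- function(x, k = 3, shrinkage = TRUE) {
  if (length(unique(x)) < k)
    stop("degenerate covariate: fewer than k distinct values")
  bs <- if (shrinkage) "cs" else "cr"
  sc <- mgcv::smoothCon(mgcv::s(x, k = k, bs = bs),
                        data = data.frame(x = x), absorb.cons = TRUE)[[1]]
  list(X = sc$X, S = sc$S[[1]], smooth = sc)
}

#' Tensor-product interaction basis
#'
#' Marginal `k = 3` shrinkage spline bases for the semimonth ordinal and
#' northing combined into a tensor-product surface with one penalty per
#' margin.
#'
#' @param semimonth,northing covariate values.
#' @param k marginal basis dimension.
#' @return List with design matrix `X`, penalty list `S`, and the mgcv
#'   smooth object.
#' @export
build_interaction <- function(semimonth, northing, k = 3) {
  if (length(unique(semimonth)) < k || length(unique(northing)) < k)
    stop("degenerate covariate: fewer than k distinct values")
  sc <- mgcv::smoothCon(mgcv::te(semimonth, northing, k = c(k, k),
                                 bs = "cs"),
                        data = data.frame(semimonth = semimonth,
                                          northing = northing),
                        absorb.cons = TRUE)[[1]]
  list(X = sc$X, S = sc$S, smooth = sc)
}

#' @export
print.rw_gam <- function(x, ...) {
  cat(sprintf("%s GAM: %s ~ %s\n", x$family, x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ")
              else "1"))
  cat(sprintf("  n = %d, edf = %.2f, GCV = %.5g, deviance explained = %.1f%%\n",
              x$n, edf_total(x), gcv_score(x), percent_deviance(x)))
  invisible(x)
}
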