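#' Forward stepwise term selection
#'
#' Starting from the null model, every remaining candidate term is added
#' singly and the addition with the lowest GCV score advances to the
#' next step. The advancing term is accepted only if (i) its model's
#' GCV is lower than the previous step's, (ii) the analysis-of-deviance
#' F-test against the previous model improves it at level `alpha`
#' (`F = ((D_prev - D_new) / delta_edf) / phi_new` on
#' `(delta_edf, n - edf_new)` degrees of freedom), and (iii) for smooth
#' terms, the fitted partial effect's pointwise 2-standard-error band
#' excludes zero somewhere in the observed covariate range. Selection
#' stops at the first rejection. GCV ties are broken by fewer effective
#' degrees of freedom, then candidate order.
#'
#' @param data sampling-unit data (already restricted to included
#'   units).
#' @param response response column name.
#' @param candidates candidate term labels (see [term_formula()]).
#' @param family component family, `"quasibinomial"` or `"Gamma"`.
#' @param k basis dimension.
#' @param alpha analysis-of-deviance significance level.
#' @param aspe also compute the mean cross-validated average squared
#'   prediction error at each accepted step (slower)?
#' @param cv_repeats,cv_seed cross-validation settings when `aspe`.
#' @return List of class `rw_stepwise`: `steps` (one row per considered
#'   step: term, GCV, percent deviance, F, p, accepted, mean ASPE if
#'   requested), `selected` term labels, and the final `fit`.
#' @export
stepwise_select <- function(data, response, candidates,
                            family = c("quasibinomial", "Gamma"),
                            k = 3, alpha = 0.05, aspe = FALSE,
                            cv_repeats = 5, cv_seed = 1L) {
  family <- match.arg(family)
  if (length(candidates) < 2) stop("need at least 2 candidate terms")
  current <- character(0)
  fit_cur <- hab_gam(data, response, current, family, k = k)
  steps <- list()
  step_i <- 0L
  steps[[1]] <- data.frame(
    step = 0L, term = "null", gcv = gcv_score(fit_cur),
    pct_deviance = 0, edf = edf_total(fit_cur),
    F = NA_real_, p = NA_real_, accepted = TRUE,
    mean_aspe = if (aspe) cross_validate_aspe(
      data, response, current, family, repeats = cv_repeats,
      seed = cv_seed, k = k)$mean_aspe else NA_real_,
    stringsAsFactors = FALSE)
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    trials <- lapply(remaining, function(tm) {
      f <- try(hab_gam(data, response, c(current, tm), family, k = k),
               silent = TRUE)
      if (inherits(f, "try-error")) NULL else f
    })
    ok <- !vapply(trials, is.null, logical(1))
    if (!any(ok)) break
    gcvs <- vapply(trials[ok], gcv_score, numeric(1))
    edfs <- vapply(trials[ok], edf_total, numeric(1))
    ord <- order(gcvs, edfs, seq_along(gcvs))
    best_i <- which(ok)[ord[1]]
    fit_new <- trials[[best_i]]
    term <- remaining[best_i]
    step_i <- step_i + 1L

    gcv_ok <- gcv_score(fit_new) < gcv_score(fit_cur)
    d_prev <- fit_deviance(fit_cur); d_new <- fit_deviance(fit_new)
    d_edf <- max(edf_total(fit_new) - edf_total(fit_cur), 0.01)
    phi <- fit_new$gam$sig2
    Fstat <- ((d_prev - d_new) / d_edf) / phi
    pval <- stats::pf(Fstat, d_edf, fit_new$n - edf_total(fit_new),
                      lower.tail = FALSE)
    dev_ok <- is.finite(Fstat) && Fstat > 0 && pval < alpha
    band_ok <- TRUE
    if (term != "year") {
      pe <- partial_effect(fit_new, term)
      band_ok <- any(abs(pe$fit) > 2 * pe$se)
    }
    accepted <- gcv_ok && dev_ok && band_ok
    steps[[length(steps) + 1L]] <- data.frame(
      step = step_i, term = term, gcv = gcv_score(fit_new),
      pct_deviance = percent_deviance(fit_new),
      edf = edf_total(fit_new), F = Fstat, p = pval,
      accepted = accepted,
      mean_aspe = if (aspe && accepted) cross_validate_aspe(
        data, response, c(current, term), family,
        repeats = cv_repeats, seed = cv_seed, k = k)$mean_aspe
      else NA_real_,
      stringsAsFactors = FALSE)
    if (!accepted) break
    current <- c(current, term)
    fit_cur <- fit_new
    remaining <- setdiff(remaining, term)
  }
  structure(list(steps = do.call(rbind, steps), selected = current,
                 fit = fit_cur, family = family, response = response),
            class = "rw_stepwise")
}

#' @export
print.rw_stepwise <- function(x, ...) {
  cat(sprintf("Forward stepwise selection (%s): %s\n", x$family,
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "null model"))
  print(x$steps, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cross-validated average squared prediction error
#'
#' Five (by default) independent 80/20 splits: the model is refit on
#' the training 80% and predicts the held-out 20%; ASPE is the mean
#' squared difference between observation and prediction on the
#' component's response scale (probability against the 0/1 indicator
#' for the presence component, counts for the abundance component).
#' Validation rows with factor levels unseen in training are dropped
#' and counted.
#'
#' @inheritParams stepwise_select
#' @param terms term labels of the model under evaluation.
#' @param repeats number of random splits.
#' @param train_frac training fraction.
#' @param seed RNG seed making the splits reproducible.
#' @return List: `mean_aspe`, `aspe` per repeat, `dropped` rows count.
#' @export
cross_validate_aspe <- function(data, response, terms, family,
                                repeats = 5, train_frac = 0.8,
                                seed = 1L, k = 3) {
  set.seed(seed)
  n <- nrow(data)
  aspe <- numeric(repeats)
  dropped <- 0L
  for (r in seq_len(repeats)) {
    tr <- sample.int(n, floor(train_frac * n))
    fit <- hab_gam(data[tr, , drop = FALSE], response, terms, family,
                   k = k)
    val <- data[-tr, , drop = FALSE]
    pr <- predict_units(fit, val, exclude_out_of_range = FALSE)
    keep <- !pr$masked
    dropped <- dropped + sum(!keep)
    obs <- val[[response]][keep]
    aspe[r] <- mean((obs - pr$response[keep])^2)
  }
  list(mean_aspe = mean(aspe), aspe = aspe, dropped = dropped)
}
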