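test_that("the k = 3 centred basis has 2 columns and a PSD penalty", {
  set.seed(1)
  x <- runif(50)
  b <- build_basis(x, k = 3)
  expect_equal(ncol(b$X), 2L)
  ev <- eigen(b$S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_error(build_basis(rep(1, 20), k = 3), "degenerate")
})

test_that("the cubic-spline penalty vanishes on straight lines", {
  set.seed(2)
  x <- runif(80)
  b <- build_basis(x, k = 5, shrinkage = FALSE)
  # project a straight line onto the basis; its quadratic form is 0
  y <- 2 * x - 1
  beta <- qr.coef(qr(cbind(1, b$X)), y)[-1]
  expect_lt(drop(t(beta) %*% b$S %*% beta), 1e-10)
  # the shrinkage variant penalises even the linear component
  bs <- build_basis(x, k = 5, shrinkage = TRUE)
  beta_s <- qr.coef(qr(cbind(1, bs$X)), y)[-1]
  expect_gt(drop(t(beta_s) %*% bs$S %*% beta_s), 0)
})

test_that("unpenalized fits reproduce a textbook IRLS GLM", {
  set.seed(11)
  n <- 500
  x <- runif(n)
  y <- rbinom(n, 1, plogis(-1 + 2 * sin(2 * pi * x)))
  d <- data.frame(presence = y, sst_c = x)
  f <- hab_gam(d, "presence", "sst", family = "quasibinomial", sp = 0)
  beta <- irls_glm(model.matrix(f$gam), y, binomial())
  expect_lt(max(abs(coef(f$gam) - beta)), 1e-6)

  y2 <- rgamma(n, shape = 2, rate = 2 / exp(1 + 0.5 * x))
  d2 <- data.frame(whales = y2, sst_c = x)
  f2 <- hab_gam(d2, "whales", "sst", family = "Gamma", sp = 0)
  beta2 <- irls_glm(model.matrix(f2$gam), y2, Gamma(link = "log"))
  expect_lt(max(abs(coef(f2$gam) - beta2)), 1e-6)
})

test_that("huge smoothing parameters shrink terms to nothing", {
  set.seed(12)
  n <- 400
  d <- data.frame(whales = rgamma(n, 2, 0.5), sst_c = runif(n),
                  depth_m = runif(n, 5, 40))
  f <- hab_gam(d, "whales", c("sst", "depth"), family = "Gamma",
               sp = c(1e8, 1e8))
  expect_true(all(edf_terms(f) < 0.05))
  pe <- partial_effect(f, "sst")
  expect_lt(max(abs(pe$fit)), 1e-6)
})

test_that("deviance, percent deviance and GCV follow their formulas", {
  set.seed(13)
  n <- 120
  x <- runif(n)
  y <- rbinom(n, 1, plogis(1.5 * x))
  d <- data.frame(presence = y, sst_c = x)
  f <- hab_gam(d, "presence", "sst", family = "quasibinomial")
  mu <- fitted(f$gam)
  dev_oracle <- 2 * sum(ifelse(y == 1, log(1 / mu), log(1 / (1 - mu))))
  expect_equal(fit_deviance(f), dev_oracle, tolerance = 1e-8)

  y2 <- rgamma(n, 2, 1)
  d2 <- data.frame(whales = y2, sst_c = x)
  f2 <- hab_gam(d2, "whales", "sst", family = "Gamma")
  mu2 <- fitted(f2$gam)
  dev2 <- 2 * sum(-log(y2 / mu2) + (y2 - mu2) / mu2)
  expect_equal(fit_deviance(f2), dev2, tolerance = 1e-8)

  # null model: edf = 1, GCV = n * D / (n - 1)^2
  f0 <- hab_gam(d2, "whales", character(0), family = "Gamma")
  expect_equal(gcv_score(f0),
               n * fit_deviance(f0) / (n - 1)^2, tolerance = 1e-7)
  expect_equal(percent_deviance(f0), 0, tolerance = 1e-8)
  expect_true(percent_deviance(f2) >= 0 && percent_deviance(f2) <= 100)
})

test_that("the gaussian GCV profile matches a brute-force hat matrix", {
  set.seed(14)
  n <- 300
  x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.3)
  d <- data.frame(whales = y, sst_c = x)
  for (lam in 10^seq(-3, 3, by = 1.5)) {
    f <- hab_gam(d, "whales", "sst", family = "gaussian", sp = lam)
    X <- model.matrix(f$gam)
    sm <- f$gam$smooth[[1]]
    S <- matrix(0, ncol(X), ncol(X))
    idx <- sm$first.para:sm$last.para
    S[idx, idx] <- sm$S[[1]]
    A <- X %*% solve(crossprod(X) + lam * S, t(X))
    gcv <- n * sum((y - A %*% y)^2) / (n - sum(diag(A)))^2
    expect_equal(gcv_score(f), gcv, tolerance = 1e-6)
  }
})

test_that("GCV-selected smoothing beats random smoothing vectors", {
  set.seed(15)
  n <- 500
  x1 <- runif(n); x2 <- runif(n, 5, 40)
  y <- rbinom(n, 1, plogis(-1 + sin(2 * pi * x1) + 0.02 * x2))
  d <- data.frame(presence = y, sst_c = x1, depth_m = x2)
  f <- hab_gam(d, "presence", c("sst", "depth"),
               family = "quasibinomial")
  g0 <- gcv_score(f)
  for (i in 1:20) {
    sp <- 10^runif(2, -4, 4)
    fr <- hab_gam(d, "presence", c("sst", "depth"),
                  family = "quasibinomial", sp = sp)
    expect_lte(g0, gcv_score(fr) * (1 + 1e-6))
  }
})

test_that("per-term edf is non-increasing as lambda grows tenfold", {
  set.seed(16)
  n <- 400
  x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.4)
  d <- data.frame(whales = y, sst_c = x)
  edfs <- vapply(10^seq(-2, 6, by = 1), function(lam) {
    edf_terms(hab_gam(d, "whales", "sst", family = "gaussian",
                      sp = lam))
  }, numeric(1))
  expect_true(all(diff(edfs) < 1e-8))
})

test_that("tensor interactions evaluate correctly and recover surfaces", {
  set.seed(17)
  n <- 3000
  sm <- sample(1:8, n, replace = TRUE)
  no <- runif(n, 0, 240)
  b <- build_interaction(sm, no, k = 3)
  expect_equal(nrow(b$X), n)
  expect_equal(length(b$S), 2L)

  # separable truth f(s) * g(n), gaussian noise
  truth <- sin(pi * (sm - 1) / 7) * (no / 240 - 0.5)
  y <- truth + rnorm(n, 0, 0.3)
  d <- data.frame(whales = y, semimonth = sm, northing_km = no)
  f <- hab_gam(d, "whales", "mig", family = "gaussian")
  pe <- partial_effect(f, "mig",
                       values = data.frame(semimonth = sm, northing_km = no))
  expect_gt(cor(pe$fit, truth), 0.95)
  # zero coefficients give an identically zero surface
  f0 <- f
  f0$gam$coefficients[] <- 0
  pe0 <- partial_effect(f0, "mig")
  expect_true(all(abs(pe0$fit) < 1e-12))
  # evaluation at training points equals the design-matrix product
  smo <- f$gam$smooth[[1]]
  idx <- smo$first.para:smo$last.para
  direct <- drop(mgcv::PredictMat(smo, d) %*% coef(f$gam)[idx])
  expect_equal(pe$fit, direct, tolerance = 1e-9)
})

test_that("prediction masks out-of-range rows and returns positive SEs", {
  set.seed(18)
  n <- 300
  d <- data.frame(presence = rbinom(n, 1, 0.3),
                  depth_m = runif(n, 5, 70),
                  year = sample(c("2009/2010", "2010/2011"), n, TRUE))
  f <- hab_gam(d, "presence", c("depth", "year"),
               family = "quasibinomial")
  # training rows predict their own fitted values
  pr <- predict_units(f, d[1:5, ])
  expect_equal(pr$eta, as.numeric(predict(f$gam))[1:5], tolerance = 1e-9)
  expect_true(all(pr$se_eta > 0))

  nd <- data.frame(depth_m = c(71, 30, NA, 30),
                   year = c("2009/2010", "2009/2010", "2009/2010",
                            "2031/2032"))
  pr2 <- predict_units(f, nd)
  expect_equal(pr2$masked, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(pr2$mask_reason[1], "out_of_range:depth_m")
  expect_equal(pr2$mask_reason[3], "missing:depth_m")
  expect_equal(pr2$mask_reason[4], "unseen_year")
  expect_error(predict_units(f, nd[, "year", drop = FALSE]),
               "missing covariate")

  # SE grows toward the covariate-range edges for a single smooth
  f1 <- hab_gam(d, "presence", "depth", family = "quasibinomial")
  pe <- partial_effect(f1, "depth")
  mid <- pe$se[50]
  expect_gt(pe$se[1], mid)
  expect_gt(pe$se[100], mid)
})

test_that("family preconditions are enforced", {
  d <- data.frame(whales = c(0, 1, 2), sst_c = 1:3)
  expect_error(hab_gam(d, "whales", "sst", family = "Gamma"),
               "strictly positive")
  d2 <- data.frame(whales = rep(1, 40), sst_c = runif(40))
  expect_error(hab_gam(d2, "whales", "sst", family = "Gamma"),
               "degenerate")
})
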