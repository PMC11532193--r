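test_that("model-based covariance matches Poisson information closed forms", {
  y <- c(2, 3, 1, 4, 5, 3)
  fit <- irls_fit(y, matrix(1, 6, 1))
  v <- vcov_naive(fit)
  expect_equal(unname(v$cov[1, 1]), 1 / (6 * mean(y)), tolerance = 1e-10)

  # balanced two-group design: 1/(n0 mu0) and 1/(n0 mu0) + 1/(n1 mu1)
  x <- rep(0:1, each = 5)
  y2 <- c(1, 2, 3, 2, 2, 6, 5, 7, 6, 6)
  fit2 <- irls_fit(y2, cbind(1, x))
  v2 <- vcov_naive(fit2)
  mu0 <- mean(y2[x == 0]); mu1 <- mean(y2[x == 1])
  expect_equal(unname(diag(v2$cov)),
               c(1 / (5 * mu0), 1 / (5 * mu0) + 1 / (5 * mu1)),
               tolerance = 1e-8)
})

test_that("HC3 sandwich equals the dense-matrix oracle and external cross-check", {
  # hand-picked 5-point dataset
  X <- cbind(1, c(-1, 0, 1, 2, 4))
  y <- c(3, 1, 4, 9, 2)
  fit <- irls_fit(y, X)
  v <- vcov_hc3(fit)
  expect_equal(unname(v$cov),
               unname(oracle_hc3(X, fit$weights, fit$residuals, fit$leverages)),
               tolerance = 1e-10)

  # independent implementation: sandwich::vcovHC on the glm fit
  skip_if_not_installed("sandwich")
  d <- small_pois_data()
  g <- glm(d$y ~ d$x, family = poisson())
  fit2 <- irls_fit(d$y, d$X)
  expect_equal(unname(vcov_hc3(fit2)$cov),
               unname(sandwich::vcovHC(g, type = "HC3")),
               tolerance = 1e-8)
  expect_equal(unname(vcov_hc3(fit2, hc0 = TRUE)$cov),
               unname(sandwich::vcovHC(g, type = "HC0")),
               tolerance = 1e-8)
})

test_that("HC3 degenerate and ordering properties hold", {
  # perfect saturated fit: zero residuals, zero sandwich
  X <- cbind(1, c(0, 0, 1, 1))
  fit <- irls_fit(c(2, 2, 4, 4), X)
  expect_lt(max(abs(vcov_hc3(fit)$cov)), 1e-12)

  # HC3 >= HC0 on the diagonal since 0 < h_ii < 1
  d <- small_pois_data(seed = 21)
  fit2 <- irls_fit(d$y, d$X)
  expect_true(all(diag(vcov_hc3(fit2)$cov) >= diag(vcov_hc3(fit2, hc0 = TRUE)$cov)))

  # perfect-leverage point: h_ii = 1 must error with the index
  X1 <- cbind(1, c(0, 0, 0, 1))
  fit3 <- suppressWarnings(irls_fit(c(2, 3, 4, 5), X1))
  expect_error(vcov_hc3(fit3), "leverage")
})

test_that("bootstrap covariance is reproducible and near zero for a perfect fit", {
  d <- small_pois_data(seed = 31)
  v1 <- vcov_bootstrap(d$y, d$X, B = 100, seed = 7)
  v2 <- vcov_bootstrap(d$y, d$X, B = 100, seed = 7)
  expect_identical(v1$cov, v2$cov)
  v3 <- vcov_bootstrap(d$y, d$X, B = 100, seed = 8)
  expect_false(identical(v1$cov, v3$cov))
  expect_equal(v1$meta$B, 100L)

  # y an exact function of a saturated design: every resample refits exactly
  x <- rep(0:1, each = 10)
  y <- ifelse(x == 0, 3, 7)
  vb <- vcov_bootstrap(y, cbind(1, x), B = 50, seed = 1)
  expect_lt(max(abs(vb$cov)), 1e-12)
})

test_that("bootstrap and HC3 agree as estimates of the same asymptotic variance", {
  set.seed(77)
  x <- sim_covariate(200)
  y <- sim_response(x, 2, 0, "od_poisson")
  X <- cbind(1, x)
  fit <- irls_fit(y, X)
  se_hc3 <- vcov_hc3(fit)$se
  se_boot <- vcov_bootstrap(y, X, B = 4000, seed = 5)$se
  expect_true(all(abs(se_boot / se_hc3 - 1) < 0.10))
})

test_that("quasi-Poisson dispersion recovers the generating variance ratio", {
  set.seed(12)
  x <- sim_covariate(2000)
  X <- cbind(1, x)

  # equidispersed data: phi near 1, covariance near the model-based one
  y <- sim_response(x, 2, 0.5, "poisson")
  fit <- irls_fit(y, X)
  vq <- vcov_quasipoisson(fit)
  expect_equal(vq$meta$phi, 1, tolerance = 0.1)
  expect_equal(vq$cov, vq$meta$phi * vcov_naive(fit)$cov, tolerance = 1e-12)

  # Var = 2*mu generator: phi approaches 2, SEs approach sqrt(2) x naive
  y2 <- sim_response(x, 2, 0.5, "od_poisson")
  fit2 <- irls_fit(y2, X)
  vq2 <- vcov_quasipoisson(fit2)
  expect_equal(vq2$meta$phi, 2, tolerance = 0.15)
  expect_equal(unname(vq2$se / vcov_naive(fit2)$se),
               rep(sqrt(vq2$meta$phi), 2), tolerance = 1e-8)

  expect_error(vcov_quasipoisson(irls_fit(3, matrix(1, 1, 1))), "n > p")
})

test_that("negative binomial baseline matches an independent ML fitter", {
  skip_if_not_installed("MASS")
  set.seed(8)
  x <- sim_covariate(200)
  y <- sim_response(x, 2, 1, "negbin")
  nb <- negbin_fit(y, cbind("(Intercept)" = 1, x = x))
  m <- MASS::glm.nb(y ~ x)
  expect_equal(unname(nb$fit$coefficients), unname(coef(m)), tolerance = 1e-6)
  expect_equal(nb$r, m$theta, tolerance = 1e-4)
  expect_equal(unname(nb$vcov$se), unname(sqrt(diag(vcov(m)))), tolerance = 1e-4)
})

test_that("negative binomial likelihood is locally maximal at the fit", {
  set.seed(19)
  x <- rep(0:1, each = 15)
  y <- rnbinom(30, size = 0.8, mu = exp(1.5 + 0.5 * x))
  X <- cbind(1, x)
  nb <- negbin_fit(y, X)
  ll <- function(beta, r) {
    mu <- exp(drop(X %*% beta))
    sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
          r * log(r / (r + mu)) + y * log(mu / (r + mu)))
  }
  ll_hat <- ll(nb$fit$coefficients, nb$r)
  grid <- expand.grid(d0 = c(-0.05, 0, 0.05), d1 = c(-0.05, 0, 0.05),
                      dr = c(0.9, 1, 1.1))
  for (k in seq_len(nrow(grid))) {
    pert <- ll(nb$fit$coefficients + c(grid$d0[k], grid$d1[k]),
               nb$r * grid$dr[k])
    expect_lte(pert, ll_hat + 1e-8)
  }
})

test_that("negative binomial handles Poisson-like and continuous responses as documented", {
  set.seed(23)
  x <- sim_covariate(200)
  y <- sim_response(x, 2, 0.5, "poisson")
  nb <- suppressWarnings(negbin_fit(y, cbind(1, x)))
  fitp <- irls_fit(y, cbind(1, x))
  # NB nests Poisson: large size estimate, SEs close to model-based Poisson
  expect_gt(nb$r, 50)
  expect_equal(unname(nb$vcov$se), unname(vcov_naive(fitp)$se), tolerance = 0.05)

  yc <- sim_response(x, 2, 0.5, "gamma_misspec")
  expect_warning(negbin_fit(yc, cbind(1, x)), "non-integer")
})

test_that("point estimates are shared across covariance methods", {
  set.seed(44)
  x <- sim_covariate(100)
  y <- sim_response(x, 2, 0.7, "od_poisson")
  X <- cbind(1, x)
  fit <- irls_fit(y, X)
  beta <- coef(fit)
  # variance estimators reuse the same fit, never refit
  for (v in list(vcov_naive(fit), vcov_hc3(fit), vcov_quasipoisson(fit)))
    expect_equal(coef(fit), beta, tolerance = 0)
  # the NB MLE coincides with the Poisson quasi-MLE on a saturated
  # two-group design
  nb <- negbin_fit(y, X)
  expect_equal(unname(nb$fit$coefficients), unname(beta), tolerance = 1e-7)
})
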