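test_that("five-year age banding matches its closed form", {
  expect_equal(age_band(c(3L, 83L, 87L)), c(0L, 80L, 85L))
  a <- 0:104
  expect_equal(age_band(a), as.integer(pmin(85, 5 * floor(a / 5))))
  expect_error(age_band(-1L), ">= 0")
})

test_that("design rows activate exactly the record's indicators", {
  rec <- toy_records(c(0L, 1L, 0L, 0L), c(3L, 83L, 84L, 87L),
                     c(1L, 405L, 1L, 1L))
  d <- build_design(rec)
  expect_equal(colnames(d$X)[1:2], c("(Intercept)", "sex"))
  expect_equal(unname(d$X[1, ]), c(1, rep(0, ncol(d$X) - 1)))
  on2 <- colnames(d$X)[d$X[2, ] == 1]
  expect_setequal(on2, c("(Intercept)", "sex", "age_band_80", "amg_405"))
  # ages 84 vs 87 differ only in the 80 vs 85 band columns
  diffcols <- colnames(d$X)[d$X[3, ] != d$X[4, ]]
  expect_setequal(diffcols, c("age_band_80", "age_band_85"))
})

test_that("a frozen encoding rejects unseen levels by name", {
  enc <- build_design(toy_records(0L, 20L, 101L))$encoding
  expect_error(build_design(toy_records(0L, 40L, 101L), enc), "age_band_40")
  expect_error(build_design(toy_records(0L, 20L, 335L), enc), "amg_335")
})

test_that("gaussian/identity reduces to ordinary least squares", {
  X <- cbind("(Intercept)" = 1, x = c(0, 1, 2))
  m <- fit_glm(list(X = X, y = c(1, 3, 5)), family = "gaussian",
               link = "identity")
  expect_equal(unname(m$coefficients), c(1, 2), tolerance = 1e-10)
  set.seed(21)
  Xr <- cbind("(Intercept)" = 1, a = rnorm(200), b = runif(200))
  yr <- 2 + Xr[, 2] - 0.5 * Xr[, 3] + rnorm(200)
  m2 <- fit_glm(list(X = Xr, y = yr), family = "gaussian", link = "identity")
  ols <- qr.solve(Xr, yr)
  expect_equal(unname(m2$coefficients), unname(ols), tolerance = 1e-8)
})

test_that("gamma/log recovers an exact log-linear mean with zero deviance", {
  x <- seq(-1, 1, length.out = 20)
  X <- cbind("(Intercept)" = 1, x = x)
  m <- fit_glm(list(X = X, y = exp(0.5 + 1.2 * x)), family = "gamma",
               link = "log")
  expect_equal(unname(m$coefficients), c(0.5, 1.2), tolerance = 1e-7)
  expect_lt(m$deviance, 1e-8)
  expect_equal(pseudo_r2_deviance(m), 1, tolerance = 1e-6)
})

test_that("coefficient estimates fall within three standard errors", {
  pop <- make_reduced_population(20000, seed = 31)
  m <- fit_cost_glm(pop, "gamma", "log")
  truth <- reduced_coefs()[names(m$coefficients)]
  se <- sqrt(diag(m$vcov))
  expect_true(all(abs(m$coefficients - truth) < 3 * se))
})

test_that("rank-deficient designs are refused", {
  X <- cbind("(Intercept)" = 1, a = c(1, 2, 3), b = c(2, 4, 6))
  expect_error(fit_glm(list(X = X, y = c(1, 2, 3)), family = "gaussian",
                       link = "identity"), "rank-deficient")
})

test_that("gaussian AIC matches its closed form and orders by fit", {
  set.seed(32)
  X <- cbind("(Intercept)" = 1, x = rnorm(10))
  y <- 1 + X[, 2] + rnorm(10)
  m <- fit_glm(list(X = X, y = y), family = "gaussian", link = "identity")
  rss <- sum((y - m$fitted_mu)^2)
  n <- 10; k <- 3  # two coefficients + the variance
  expect_equal(m$aic, n * log(rss / n) + n * (log(2 * pi) + 1) + 2 * k,
               tolerance = 1e-10)
  ic <- information_criteria(m)
  expect_equal(ic$aic_per_obs, m$aic / n)
  expect_equal(ic$bic, -2 * m$loglik + k * log(n))
  # same k, more noise -> larger RSS -> larger AIC
  m2 <- fit_glm(list(X = X, y = y + rnorm(10, sd = 3)),
                family = "gaussian", link = "identity")
  expect_true((m$deviance < m2$deviance) == (m$aic < m2$aic))
})

test_that("adding a covariate never increases the deviance", {
  pop <- make_reduced_population(2000, seed = 33)
  d <- build_design(pop)
  for (fam in c("gaussian", "gamma")) {
    full <- fit_glm(d, family = fam, link = "log")
    reduced <- fit_glm(list(X = d$X[, colnames(d$X) != "amg_335"], y = d$y),
                       family = fam, link = "log")
    expect_lte(full$deviance, reduced$deviance + 1e-8)
    expect_lte(full$deviance, full$null_deviance)
  }
})

test_that("predictions invert each link", {
  X1 <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  m <- fit_glm(list(X = X1, y = rep(exp(5.731), 3)), family = "gamma",
               link = "log")
  expect_equal(predict(m, list(X = X1))$mu, rep(exp(5.731), 3),
               tolerance = 1e-9)
  x <- seq(1, 4, length.out = 12)
  Xp <- cbind("(Intercept)" = 1, x = x)
  mp <- fit_glm(list(X = Xp, y = (1 + 0.5 * x)^2), family = "gamma",
                link = "power_half")
  expect_equal(unname(mp$coefficients), c(1, 0.5), tolerance = 1e-6)
  pr <- predict(mp, list(X = cbind(1, 4)))
  expect_equal(pr$eta, 3, tolerance = 1e-6)
  expect_equal(pr$mu, 9, tolerance = 1e-5)
  mi <- fit_glm(list(X = Xp, y = 2 + x), family = "gaussian",
                link = "identity")
  pi_ <- predict(mi, list(X = Xp))
  expect_equal(pi_$mu, pi_$eta)
})

test_that("log-link predictions are invariant to the reference level", {
  pop <- make_reduced_population(3000, seed = 34)
  m1 <- fit_cost_glm(pop, "gamma", "log")
  # swap labels so the former amg 321 becomes the reference group
  pop2 <- pop
  pop2$amg_code[pop$amg_code == 1L] <- 321L
  pop2$amg_code[pop$amg_code == 321L] <- 1L
  m2 <- fit_cost_glm(pop2, "gamma", "log")
  expect_equal(predict(m1, pop)$mu, predict(m2, pop2)$mu, tolerance = 1e-7)
})

test_that("pseudo R-squared spans its range", {
  X <- matrix(1, 50, 1, dimnames = list(NULL, "(Intercept)"))
  set.seed(35)
  y <- rgamma(50, 2, 0.1)
  null <- fit_glm(list(X = X, y = y), family = "gamma", link = "log")
  expect_equal(pseudo_r2_deviance(null), 0)
  expect_error(information_criteria(
    structure(list(converged = FALSE), class = "cost_glm")), "converge")
})
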