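test_that("proportion scores divide raw by maximum and reject impossible raws", {
  expect_equal(proportion_scores(0, 103), 0)
  expect_equal(proportion_scores(103, 103), 1)
  expect_equal(proportion_scores(c(10, 56), c(103, 112)),
               c(10 / 103, 56 / 112))
  expect_error(proportion_scores(104, 103), "\\[0, max\\]")
  # a mean proportion of 0.26 corresponds to raw ~ 27 of 103
  expect_equal(round(0.26 * 103), 27)
  expect_equal(proportion_scores(26.78, 103), 0.26, tolerance = 0.001)
})

test_that("OLS fits match the normal-equation oracle exactly", {
  x1 <- c(1, 2, 3, 4, 5, 6)
  x2 <- c(2, 1, 4, 3, 6, 5)
  y <- c(1.2, 1.9, 3.3, 3.8, 5.5, 5.6)
  fit <- fit_linear(y, data.frame(x1 = x1, x2 = x2))
  X <- cbind(1, x1, x2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)
  # classical SEs from the oracle covariance
  res <- y - X %*% beta
  s2 <- sum(res^2) / (6 - 3)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(fit$coefficients$se, unname(se), tolerance = 1e-10)
  # perfect linear data: exact coefficients, R^2 = 1
  fit2 <- suppressWarnings(fit_linear(2 + 3 * x1, data.frame(x1 = x1)))
  expect_equal(fit2$coefficients$estimate, c(2, 3), tolerance = 1e-10)
  expect_equal(fit2$r_squared, 1)
  # centred predictors make the intercept the mean of y
  fit3 <- fit_linear(y, data.frame(x1 = x1 - mean(x1), x2 = x2 - mean(x2)))
  expect_equal(fit3$coefficients$estimate[1], mean(y))
  expect_error(fit_linear(y, data.frame(a = x1, b = x1)), "rank-deficient")
})

test_that("variance inflation factors follow the closed form", {
  set.seed(71)
  n <- 120
  z1 <- rnorm(n); z2 <- rnorm(n)
  # Gram-Schmidt so the sample correlation is exactly 0.6
  e1 <- (z1 - mean(z1)) / sd(z1)
  r2 <- resid(lm(z2 ~ z1))
  e2 <- (r2 - mean(r2)) / sd(r2)
  x2 <- 0.6 * e1 + sqrt(1 - 0.36) * e2
  v <- vif(data.frame(a = e1, b = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.36), 2), tolerance = 1e-10)
  # orthogonal predictors: VIF = 1
  expect_equal(unname(vif(data.frame(a = e1, b = e2))), c(1, 1),
               tolerance = 1e-10)
  # duplicated predictor: infinite VIF
  expect_true(all(is.infinite(suppressWarnings(
    vif(data.frame(a = e1, b = e1))))))
  # cross-check against car on a three-predictor design
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rnorm(n)
  fit <- lm(y ~ ., data = X)
  expect_equal(unname(vif(X)), unname(car::vif(fit)), tolerance = 1e-8)
})

test_that("the non-constant-variance score test is calibrated and has power", {
  set.seed(81)
  n <- 100
  null_p <- replicate(300, {
    x <- rnorm(n); y <- 1 + 2 * x + rnorm(n)
    ncv_test(lm(y ~ x))
  })
  expect_gte(mean(null_p < 0.05), 0.005)
  expect_lte(mean(null_p < 0.05), 0.11)
  power_p <- replicate(50, {
    x <- runif(200, 1, 3); y <- 1 + 2 * x + rnorm(200, sd = 0.5 * (1 + 2 * x))
    ncv_test(lm(y ~ x))
  })
  expect_gte(mean(power_p < 0.05), 0.8)
  # equal-magnitude residuals carry no heteroscedasticity signal
  x <- 1:20
  y <- x + rep(c(0.5, -0.5), 10)
  expect_gt(ncv_test(lm(y ~ x)), 0.2)
  # the implementation is the score test: chi^2 statistic cross-check
  x <- rnorm(50); y <- 1 + x + rnorm(50)
  fit <- lm(y ~ x)
  e2 <- resid(fit)^2; fv <- fitted(fit)
  u <- e2 / mean(e2)
  ss <- sum((fv - mean(fv)) * u)^2 / (2 * sum((fv - mean(fv))^2))
  expect_equal(ncv_test(fit), pchisq(ss, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("the vocabulary models recover generating coefficients and branch on ncv", {
  cfg <- sim_config(seed = 1)
  set.seed(91)
  n <- 200
  zs <- rnorm(n, 1.71, 0.97); zy <- rnorm(n, 1.47, 0.86)
  sc <- synth_vocab(cfg, zy, zs, seed = 3)
  models <- run_vocab_models(sc, zs, zy)
  co <- models$expressive$coefficients
  est <- co$estimate[co$term == "z_syllable"]
  se <- co$se[co$term == "z_syllable"]
  expect_lt(abs(est - 0.09), 4 * se)
  est_s <- co$estimate[co$term == "z_stress"]
  expect_lt(abs(est_s - 0.0), 4 * co$se[co$term == "z_stress"])
  # receptive model recovers its autoregressive coefficient
  cr <- models$receptive$coefficients
  expect_lt(abs(cr$estimate[cr$term == "receptive_10"] - 0.62),
            4 * cr$se[cr$term == "receptive_10"])
  expect_equal(models$n_complete, n)
  expect_true(all(models$expressive$vif >= 1))
  # a homoscedastic linear outcome keeps the identity scale
  sc2 <- sc
  sc2$expressive_18 <- 0.2 + 0.05 * zy + 0.5 * sc$expressive_10 +
    rnorm(n, 0, 0.02)
  m2 <- run_vocab_models(sc2, zs, zy)
  expect_equal(m2$expressive$transform, "none")
  # listwise deletion drops incomplete 18-month data
  sc3 <- sc
  sc3$receptive_18[1:7] <- NA
  m3 <- run_vocab_models(sc3, zs, zy)
  expect_equal(m3$n_complete, n - 7)
  expect_error(run_vocab_models(sc[1:9, ], zs[1:9], zy[1:9]), "fewer than 10")
})
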