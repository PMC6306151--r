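test_that("log_transform computes logs and guards zeros", {
  expect_equal(log_transform(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(log_transform(100), log(100))
  expect_error(log_transform(c(0, 5)), "positive shift")
  expect_equal(log_transform(c(0, 5), shift = 0.5), log(c(0.5, 5.5)))
})

test_that("sample_acf/pacf agree with the stats oracles", {
  set.seed(21)
  y <- as.numeric(arima.sim(list(ar = 0.4, ma = 0.3), n = 300))
  expect_equal(sample_acf(y, 10L)[1L], 1)
  oracle_acf <- as.numeric(stats::acf(y, lag.max = 10, plot = FALSE)$acf)
  expect_equal(sample_acf(y, 10L), oracle_acf, tolerance = 1e-10)
  oracle_pacf <- as.numeric(stats::pacf(y, lag.max = 10, plot = FALSE)$acf)
  expect_equal(sample_pacf(y, 10L), oracle_pacf, tolerance = 1e-8)

  const <- sample_acf(rep(3, 50), 5L)
  expect_true(all(is.nan(const)))
  expect_true(attr(const, "degenerate"))
  expect_error(sample_acf(1:5, 10L), "length")
})

test_that("ACF matches theory for AR(1) and white noise", {
  set.seed(22)
  y <- as.numeric(arima.sim(list(ar = 0.6), n = 5000))
  a <- sample_acf(y, 3L)[-1L]
  expect_true(all(abs(a - 0.6^(1:3)) < 0.05))

  wn <- rnorm(2000)
  a <- sample_acf(wn, 20L)[-1L]
  expect_gte(mean(abs(a) < 2 / sqrt(2000)), 0.9)
})

test_that("fit_arima closed forms: white noise and random walk", {
  set.seed(23)
  y <- rnorm(60, mean = 5)
  f <- fit_arima(y, c(0, 0, 0))
  expect_true(f$converged)
  expect_equal(f$constant, mean(y), tolerance = 1e-4)
  expect_equal(f$sigma2, mean((y - mean(y))^2), tolerance = 1e-4)

  rw <- cumsum(rnorm(60))
  f <- fit_arima(rw, c(0, 1, 0))
  expect_true(is.na(f$constant))  # no drift when d = 1
  expect_equal(f$residuals[-1L], diff(rw), tolerance = 1e-6)
  expect_error(fit_arima(rnorm(3), c(1, 0, 1)), "too short")
})

test_that("one_step_rmse equals the brute-force identity", {
  expect_equal(one_step_rmse(fake_fit(c(0, 0, 0))), 0)
  expect_equal(one_step_rmse(fake_fit(c(3, 4))), sqrt(25 / 2))
  # skips the first d start-up residuals
  expect_equal(one_step_rmse(fake_fit(c(99, 3, 4), d = 1L)), sqrt(25 / 2))
  set.seed(24)
  f <- fit_arima(cumsum(rnorm(50)), c(1, 1, 0))
  expect_equal(one_step_rmse(f), sqrt(mean(f$residuals[-1L]^2)))
})

test_that("forecast_path matches the closed forms and the AR(1) oracle", {
  set.seed(25)
  rw <- cumsum(rnorm(80))
  f <- fit_arima(rw, c(0, 1, 0))
  fp <- forecast_path(f, 5L)
  expect_equal(fp$log_means, rep(rw[80], 5), tolerance = 1e-6)
  expect_equal(fp$log_ses, sqrt(f$sigma2 * (1:5)), tolerance = 1e-6)
  expect_equal(fp$median_counts, exp(fp$log_means))

  y <- rnorm(80, mean = 3)
  f0 <- fit_arima(y, c(0, 0, 0))
  fp0 <- forecast_path(f0, 4L)
  expect_equal(fp0$log_means, rep(f0$constant, 4), tolerance = 1e-8)
  expect_equal(fp0$log_ses, rep(sqrt(f0$sigma2), 4), tolerance = 1e-8)

  # AR(1): h-step mean mu + phi^h * (y_n - mu), iterated one-step oracle
  ar1 <- as.numeric(arima.sim(list(ar = 0.5), n = 200)) + 2
  f1 <- fit_arima(ar1, c(1, 0, 0))
  fp1 <- forecast_path(f1, 6L)
  phi <- f1$ar_coefs; mu <- f1$constant
  oracle <- numeric(6)
  prev <- ar1[200]
  for (h in 1:6) {
    prev <- mu + phi * (prev - mu)
    oracle[h] <- prev
  }
  expect_equal(fp1$log_means, oracle, tolerance = 1e-8)

  expect_error(forecast_path(f1, 0L), "horizon")
})

test_that("forecast SEs are non-decreasing for d = 1 models", {
  set.seed(26)
  for (ord in list(c(0, 1, 0), c(1, 1, 0), c(0, 1, 2))) {
    f <- fit_arima(cumsum(rnorm(60)), ord)
    if (!f$converged) next
    fp <- forecast_path(f, 10L)
    expect_true(all(diff(fp$log_ses) >= -1e-10))
  }
})

test_that("fit_arima recovers a known AR coefficient", {
  set.seed(27)
  phis <- replicate(20, {
    y <- as.numeric(arima.sim(list(ar = 0.7), n = 500))
    fit_arima(y, c(1, 0, 0))$ar_coefs
  })
  expect_lt(abs(mean(phis) - 0.7), 0.05)
})

test_that("select_order returns a full candidate table and picks the minimum", {
  set.seed(28)
  y <- log(rpois(17, 75) + 0.5)
  sel <- select_order(y)
  expect_equal(nrow(sel$candidates), 17L)
  conv <- sel$candidates[sel$candidates$converged, ]
  best <- min(conv$rmse)
  chosen_rmse <- one_step_rmse(sel$fit)
  expect_lte(chosen_rmse, best + 1e-9)
  # parsimony among ties
  tied <- conv[conv$rmse <= best + 1e-9, ]
  expect_equal(sel$chosen$p + sel$chosen$q, min(tied$p + tied$q))

  one <- select_order(y, grid = list(arima_order(0, 1, 0)))
  expect_equal(format(one$chosen), "ARIMA(0,1,0)")
  expect_error(select_order(y, grid = list()), "empty")
})

test_that("selection table is reproducible and prefers d = 1 for I(1) data", {
  set.seed(29)
  y <- log(rpois(40, exp(cumsum(rnorm(40, sd = 0.08)) + log(60))))
  s1 <- select_order(y)
  s2 <- select_order(y)
  expect_identical(s1$candidates, s2$candidates)

  # In-sample one-step RMSE cannot separate d = 1 from a d = 0 fit whose AR
  # polynomial has a near-unit root (their one-step predictions coincide);
  # the recoverable property is that the selected model carries the
  # integrated structure in one of those two forms.
  set.seed(30)
  hits <- replicate(60, {
    x <- as.numeric(arima.sim(list(order = c(1, 1, 0), ar = 0.5), n = 199,
                              sd = 0.1))
    sel <- select_order(x)
    sel$chosen$d == 1L ||
      (length(sel$fit$ar_coefs) > 0 &&
         min(Mod(polyroot(c(1, -sel$fit$ar_coefs)))) < 1.1)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("chosen-model residuals are white on well-specified data", {
  set.seed(31)
  pvals <- replicate(100, {
    y <- as.numeric(arima.sim(list(ar = 0.5), n = 200))
    f <- fit_arima(y, c(1, 0, 0))
    stats::Box.test(f$residuals, lag = 8, type = "Ljung-Box", fitdf = 1)$p.value
  })
  expect_gte(mean(pvals > 0.05), 0.9)
})
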