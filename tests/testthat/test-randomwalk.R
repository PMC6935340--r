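test_that("differencing follows the definition and inverts by summation", {
  expect_equal(difference_series(c(1, 1, 1)), c(0, 0))
  expect_equal(difference_series(c(1.0, 1.3, 1.1)), c(0.3, -0.2))
  expect_error(difference_series(1.5), class = "nodewalk_data_error")

  withr::with_seed(2, {
    for (i in 1:20) {
      H <- cumsum(rnorm(sample(5:60, 1)))
      d <- difference_series(H)
      expect_equal(cumsum(c(H[1], d)), H)
    }
  })
})

test_that("drift estimation recovers a deterministic linear series", {
  H <- 1 + 0.02 * (0:50)
  fit <- estimate_drift(difference_series(H))
  expect_equal(fit$mu, 0.02)
  expect_equal(fit$sigma2, 0)
  expect_equal(fit$residuals, rep(0, 50))
  expect_error(estimate_drift(0.5), class = "nodewalk_data_error")
})

test_that("drift equals the telescoping formula and residuals centre at 0", {
  withr::with_seed(8, {
    for (i in 1:25) {
      H <- cumsum(c(rnorm(1), 0.05 + rnorm(sample(10:80, 1), sd = 0.1)))
      fit <- estimate_drift(difference_series(H))
      n <- length(H)
      expect_equal(fit$mu, (H[n] - H[1]) / (n - 1), tolerance = 1e-13)
      expect_lt(abs(mean(fit$residuals)), 1e-13)
      expect_equal(fit$n_diffs, n - 1)
    }
  })
})

test_that("reconstruction is the exact inverse of drift estimation", {
  expect_equal(reconstruct_series(0, 1.5, rep(0, 6)), rep(1.5, 7))
  expect_equal(reconstruct_series(0.02, 1, rep(0, 5)), 1 + 0.02 * (0:5))

  withr::with_seed(15, {
    for (i in 1:20) {
      H <- cumsum(c(runif(1, 0.5, 2), rnorm(sample(5:100, 1), 0.02, 0.08)))
      fit <- estimate_drift(difference_series(H))
      expect_equal(reconstruct_series(fit$mu, H[1], fit$residuals), H,
                   tolerance = 1e-12)
    }
  })
})

test_that("autocorrelations follow the centred-product formula", {
  a <- series_acf(sin(1:30), max_lag = 5)
  expect_equal(a$rho[1], 1)
  expect_true(all(abs(a$rho) <= 1 + 1e-12))
  expect_equal(attr(a, "n"), 30L)

  # alternating series: rho_1 = -7/8 by direct evaluation
  x <- rep(c(1, -1), 4)
  expect_equal(series_acf(x, max_lag = 1)$rho[2], -0.875)

  expect_error(series_acf(rep(3, 20), 2), class = "nodewalk_data_error")
  expect_error(series_acf(1:5, max_lag = 8), class = "nodewalk_data_error")
})

test_that("autocorrelations match a naive double-loop implementation", {
  naive_acf <- function(x, k) {
    n <- length(x)
    xb <- mean(x)
    num <- 0
    for (t in (k + 1):n) num <- num + (x[t] - xb) * (x[t - k] - xb)
    den <- 0
    for (t in 1:n) den <- den + (x[t] - xb)^2
    num / den
  }
  withr::with_seed(23, {
    for (i in 1:10) {
      x <- rnorm(sample(15:60, 1))
      got <- series_acf(x, max_lag = 6)$rho
      want <- c(1, vapply(1:6, function(k) naive_acf(x, k), numeric(1)))
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("portmanteau statistics match the reference implementation", {
  withr::with_seed(40, x <- rnorm(20))
  for (h in c(3, 5)) {
    lb <- portmanteau_test(x, lags = h, variant = "ljung-box")
    ref <- stats::Box.test(x, lag = h, type = "Ljung-Box")
    expect_equal(lb$Q, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(lb$p, unname(ref$p.value), tolerance = 1e-6)
    bp <- portmanteau_test(x, lags = h, variant = "box-pierce")
    ref_bp <- stats::Box.test(x, lag = h, type = "Box-Pierce")
    expect_equal(bp$Q, unname(ref_bp$statistic), tolerance = 1e-6)
  }

  # a series constructed with zero lag-1 autocorrelation: Q = 0, p = 1
  x0 <- rep(c(1, 0, -1, 0), 4)
  pm <- portmanteau_test(x0, lags = 1)
  expect_equal(pm$Q, 0)
  expect_equal(pm$p, 1)

  expect_error(portmanteau_test(rep(1, 30), lags = 5),
               class = "nodewalk_data_error")
  expect_error(portmanteau_test(rnorm(5), lags = 10),
               class = "nodewalk_data_error")
})

test_that("drift recovery is unbiased under the generative difference model", {
  # simulate differences directly: d_t = mu + a_t
  mu <- 0.05
  sigma <- 0.06
  reps <- 10000
  len <- 60
  withr::with_seed(55, {
    d <- matrix(mu + rnorm(reps * len, sd = sigma), nrow = len)
  })
  mu_hat <- colMeans(d)
  mc_se <- sd(mu_hat) / sqrt(reps)
  expect_lt(abs(mean(mu_hat) - mu), 3 * mc_se)
})

test_that("drift and variance estimates tighten with series length", {
  reps <- 2000
  bias <- sapply(c(20, 80, 320), function(len) {
    withr::with_seed(60 + len, {
      d <- matrix(0.02 + rnorm(reps * len, sd = sqrt(0.004)), nrow = len)
    })
    mu_hat <- colMeans(d)
    s2_hat <- apply(d, 2, var)
    c(mu = abs(mean(mu_hat) - 0.02), s2 = abs(mean(s2_hat) - 0.004),
      mu_sd = sd(mu_hat))
  })
  # spread of the estimator shrinks with n, and bias stays inside 3 MC SEs
  expect_true(all(diff(bias["mu_sd", ]) < 0))
  expect_true(all(bias["mu", ] < 3 * bias["mu_sd", ] / sqrt(reps)))
})

test_that("the bundled random-walk fit composes its parts", {
  withr::with_seed(71, {
    H <- reconstruct_series(0.02, 1, rnorm(80, sd = sqrt(0.004)))
  })
  fit <- fit_random_walk(H, lags = 10)
  expect_s3_class(fit, "rw_fit")
  expect_equal(fit$drift$mu, mean(diff(H)))
  expect_equal(fit$h0, H[1])
  expect_equal(fit$lags, 10L)
  expect_equal(fit$portmanteau$df, 10L)
  expect_equal(fit$acf$rho[1], 1)
  # round trip through the bundle
  expect_equal(reconstruct_series(fit$drift$mu, fit$h0, fit$drift$residuals),
               H, tolerance = 1e-12)
  gl <- glance(fit)
  expect_named(gl, c("mu", "sigma2", "n_points", "n_diffs", "lags", "variant",
                     "statistic", "p.value", "scale", "spacing"))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "mu"], fit$drift$mu)
})

test_that("a pure-drift series degenerates loudly, not silently", {
  H <- 1 + 0.02 * (0:40)
  fit <- fit_random_walk(H)
  expect_equal(fit$drift$mu, 0.02)
  expect_equal(fit$drift$sigma2, 0)
  expect_null(fit$portmanteau)
  expect_match(fit$notes, "degenerate", all = FALSE)
})

test_that("lag default, spacing and scale options behave as documented", {
  withr::with_seed(90, H <- cumsum(c(1, rnorm(30, 0.05, 0.1))))
  fit <- fit_random_walk(H)
  expect_equal(fit$lags, min(10L, floor(30 / 5)))

  # percent spacing divides each difference by the cutoff gap
  series <- tibble::tibble(cutoff_pct = c(2, 4, 6, 10, 12, 14, 16, 20, 22, 24),
                           hr = seq(1, 1.9, by = 0.1))
  f_idx <- fit_random_walk(series, lags = 1)
  f_pct <- fit_random_walk(series, lags = 1, spacing = "percent")
  expect_equal(f_idx$drift$mu, 0.1, tolerance = 1e-12)
  expect_equal(f_pct$drift$mu, mean(0.1 / diff(series$cutoff_pct)),
               tolerance = 1e-12)

  withr::with_seed(91, Hp <- exp(cumsum(c(0, rnorm(20, 0.02, 0.05)))))
  f_log <- fit_random_walk(Hp, lags = 2, scale = "log")
  expect_equal(f_log$drift$mu, mean(diff(log(Hp))), tolerance = 1e-12)

  expect_error(fit_random_walk(c(1, 1.1), lags = 1),
               class = "nodewalk_data_error")
})
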