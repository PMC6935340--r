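test_that("null-coefficient partial likelihood equals its closed form", {
  # with beta = 0 and no ties the partial log-likelihood is minus the sum of
  # log risk-set sizes over event times
  d <- make_small_surv(n = 30, seed = 4, ties = FALSE)
  X <- as.matrix(d[paste0("x", 1:3)])
  expected <- -sum(vapply(which(d$event == 1), function(i) {
    log(sum(d$time >= d$time[i]))
  }, numeric(1)))
  expect_equal(cox_partial_loglik(numeric(3), d$time, d$event, X), expected)

  # two subjects, one informative risk set
  expect_equal(
    cox_partial_loglik(0, c(1, 2), c(1, 1), cbind(c(1, 0))),
    log(1 / 2)
  )
})

test_that("partial likelihood matches a direct risk-set summation", {
  fs <- four_subject_data()
  for (beta in c(-1, 0.5, 2)) {
    expect_equal(
      cox_partial_loglik(beta, fs$time, fs$event, cbind(fs$x)),
      naive_partial_loglik_1cov(beta, fs$time, fs$event, fs$x)
    )
  }
  # and on a larger no-ties dataset
  d <- make_small_surv(n = 25, seed = 11, ties = FALSE)
  expect_equal(
    cox_partial_loglik(0.3, d$time, d$event, as.matrix(d["x1"])),
    naive_partial_loglik_1cov(0.3, d$time, d$event, d$x1)
  )
})

test_that("the Newton optimum matches a fine grid search", {
  fs <- four_subject_data()
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, naive_partial_loglik_1cov,
               numeric(1), fs$time, fs$event, fs$x)
  beta_grid <- grid[which.max(ll)]
  fit <- fit_cox(tibble::tibble(time = fs$time, event = fs$event, x = fs$x),
                 covariates = "x")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), beta_grid, tolerance = 1e-4)
  expect_lt(max(abs(fit$score)), fit$tol)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("degenerate designs and separation are surfaced, not hidden", {
  d <- make_small_surv(n = 20, seed = 5)
  d$flat <- 1
  expect_error(fit_cox(d, covariates = "flat"), class = "nodewalk_data_error")
  expect_error(
    fit_cox(tibble::tibble(time = 1, event = 0, x = 1), covariates = "x"),
    class = "nodewalk_data_error"
  )

  # two subjects whose covariate perfectly orders the deaths: monotone
  # likelihood, flagged and reported as non-converged
  sep <- fit_cox(tibble::tibble(time = c(1, 2), event = c(1, 1), x = c(1, 0)),
                 covariates = "x")
  expect_true(any(sep$flags))
  expect_false(sep$converged)
  expect_error(hazard_ratio_ci(sep, "x"), class = "nodewalk_numeric_error")
})

test_that("estimates agree with an established implementation", {
  skip_if_not_installed("survival")
  for (seed in 1:6) {
    d <- make_small_surv(n = 50, p = 3, seed = seed, ties = TRUE)
    for (ties in c("efron", "breslow")) {
      fit <- fit_cox(d, covariates = paste0("x", 1:3), ties = ties)
      ref <- survival::coxph(
        survival::Surv(time, event) ~ x1 + x2 + x3,
        data = d, ties = ties
      )
      expect_equal(unname(fit$coefficients), unname(coef(ref)),
                   tolerance = 1e-5)
      expect_equal(unname(sqrt(diag(fit$covariance))),
                   unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
      expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-6)
    }
  }
})

test_that("coefficients are invariant to monotone time transforms", {
  d <- make_small_surv(n = 45, seed = 14)
  f1 <- fit_cox(d, covariates = paste0("x", 1:3))
  d2 <- dplyr::mutate(d, time = time^3)
  f2 <- fit_cox(d2, covariates = paste0("x", 1:3))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$covariance, f2$covariance, tolerance = 1e-8)
})

test_that("Efron and Breslow coincide exactly without tied events", {
  d <- make_small_surv(n = 35, seed = 6, ties = FALSE)
  stopifnot(!anyDuplicated(d$time[d$event == 1]))
  fe <- fit_cox(d, covariates = paste0("x", 1:3), ties = "efron")
  fb <- fit_cox(d, covariates = paste0("x", 1:3), ties = "breslow")
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-10)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-10)
})

test_that("hazard-ratio intervals follow the Wald closed form", {
  fake <- structure(
    list(coefficients = c(x = 0), covariance = matrix(0.01, 1, 1,
                                                      dimnames = list("x", "x")),
         converged = TRUE),
    class = "cox_fit"
  )
  ci <- hazard_ratio_ci(fake, "x")
  expect_equal(ci$hr, 1)
  expect_equal(c(ci$lo, ci$hi), c(0.822, 1.217), tolerance = 1e-3)

  fake$coefficients <- c(x = log(2))
  ci2 <- hazard_ratio_ci(fake, "x")
  expect_equal(ci2$hr, 2)
  expect_equal(c(ci2$lo, ci2$hi),
               exp(log(2) + c(-1, 1) * 1.959964 * 0.1), tolerance = 1e-6)

  # interval widens monotonically with the confidence level
  withr::with_seed(31, {
    for (i in 1:10) {
      fake$coefficients <- c(x = rnorm(1))
      fake$covariance[] <- runif(1, 0.001, 0.2)
      lo_hi_95 <- hazard_ratio_ci(fake, "x", level = 0.95)
      lo_hi_99 <- hazard_ratio_ci(fake, "x", level = 0.99)
      expect_lt(lo_hi_99$lo, lo_hi_95$lo)
      expect_gt(lo_hi_99$hi, lo_hi_95$hi)
    }
  })
})

test_that("tidy and glance expose broom-style summaries", {
  d <- make_small_surv(n = 40, seed = 19)
  fit <- fit_cox(d, covariates = paste0("x", 1:3))
  td <- tidy(fit, conf.int = TRUE, exponentiate = TRUE)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(td$estimate, unname(exp(fit$coefficients)))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, nrow(d))
})
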