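# Small random survival datasets used across the Cox tests. Rounding times
# to one decimal guarantees tied event times at these sample sizes.
make_small_surv <- function(n = 40, p = 3, seed = 1, ties = TRUE) {
  withr::with_seed(seed, {
    X <- cbind(
      matrix(rnorm(n * (p - 1)), n, p - 1),
      rbinom(n, 1, 0.5)
    )
    colnames(X) <- paste0("x", seq_len(p))
    beta <- seq(-0.5, 0.5, length.out = p)
    time <- rexp(n, 0.2 * exp(drop(X %*% beta)))
    if (ties) time <- ceiling(time * 10) / 10
    cens <- runif(n, 0, quantile(time, 0.9))
    tibble::tibble(
      time = pmax(pmin(time, cens), 0.01),
      event = as.integer(time <= cens)
    ) |>
      dplyr::bind_cols(tibble::as_tibble(X))
  })
}

# The four-subject worked dataset: all events at distinct times, one binary
# covariate alternating between arms.
four_subject_data <- function() {
  list(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1), x = c(1, 0, 1, 0))
}

# Direct summation of the no-ties partial log-likelihood for a single
# covariate: sum over events of [beta * x_i - log(sum_{t_j >= t_i} exp(beta
# * x_j))]. Independent of the package's cumulative-sum implementation.
naive_partial_loglik_1cov <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# A small cohort configuration used where the full default size is not needed.
small_cohort <- function(n = 600, seed = 42, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}
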