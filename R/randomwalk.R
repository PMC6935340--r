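# Random-walk-with-drift analysis of an ordered hazard-ratio series:
# the model is H_t - H_{t-1} = mu + a_t with a_t white noise, so the level
# series integrates the drift and all past innovations,
# H_t = mu * t + H_0 + (a_1 + ... + a_t).

#' First differences of an ordered series
#'
#' @param H Numeric vector of at least 2 ordered values.
#' @return `H[i+1] - H[i]`, length `length(H) - 1`.
#' @export
#' @examples
#' difference_series(c(1.0, 1.3, 1.1))  # 0.3, -0.2
difference_series <- function(H) {
  H <- as.numeric(H)
  if (length(H) < 2L) {
    stop_data("Need at least 2 points to difference a series.")
  }
  if (any(!is.finite(H))) stop_data("Series values must be finite.")
  diff(H)
}

#' Estimate drift and innovation variance from differences
#'
#' The drift is the sample mean of the differences (equivalently, by
#' telescoping, `(H_last - H_first) / (n - 1)`); the innovations are the
#' mean-removed differences and their variance uses the n-1 denominator.
#'
#' @param differences Numeric vector of at least 2 first differences.
#' @return An object of class `drift_fit` with elements `mu`, `sigma2`,
#'   `residuals` and `n_diffs`.
#' @export
#' @examples
#' estimate_drift(difference_series(1 + 0.02 * (0:10)))  # mu = 0.02, sigma2 = 0
estimate_drift <- function(differences) {
  differences <- as.numeric(differences)
  if (length(differences) < 2L) {
    stop_data("Need at least 2 differences: the variance is undefined.")
  }
  if (any(!is.finite(differences))) {
    stop_data("Differences must be finite.")
  }
  mu <- mean(differences)
  residuals <- differences - mu
  structure(
    list(
      mu = mu,
      sigma2 = var(residuals),
      residuals = residuals,
      n_diffs = length(differences)
    ),
    class = "drift_fit"
  )
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf(
    "<drift_fit> mu = %.4g, sigma2 = %.4g (%d differences)\n",
    x$mu, x$sigma2, x$n_diffs
  ))
  invisible(x)
}

#' Sample autocorrelation function
#'
#' Computes `rho_k = sum_{t=k+1..n} (x_t - xbar)(x_{t-k} - xbar) /
#' sum_t (x_t - xbar)^2` for lags 0..`max_lag`.
#'
#' @param x Numeric series with nonzero variance, length >= `max_lag + 2`.
#' @param max_lag Largest lag.
#' @return An object of class `acf_result`: a tibble with columns `lag` and
#'   `rho` (with `rho[lag = 0] = 1`) and the series length in `attr(, "n")`.
#' @export
#' @examples
#' series_acf(sin(1:30), max_lag = 5)
series_acf <- function(x, max_lag = 10L) {
  x <- as.numeric(x)
  n <- length(x)
  if (!is_scalar_number(max_lag) || max_lag < 0 || max_lag != round(max_lag)) {
    stop_config("`max_lag` must be a non-negative integer.")
  }
  if (n < max_lag + 2L) {
    stop_data("Series too short for max_lag = %d (need length >= %d).",
              max_lag, max_lag + 2L)
  }
  if (any(!is.finite(x))) stop_data("Series values must be finite.")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) {
    stop_data("Zero-variance series: autocorrelation is undefined.")
  }
  rho <- vapply(0:max_lag, function(k) {
    sum(xc[(k + 1):n] * xc[1:(n - k)]) / denom
  }, numeric(1))
  structure(
    tibble::tibble(lag = 0:max_lag, rho = rho),
    n = n,
    class = c("acf_result", class(tibble::tibble()))
  )
}

#' Portmanteau (Ljung-Box) white-noise test
#'
#' Tests that the first `lags` autocorrelations of a residual series are
#' jointly zero. The Ljung-Box statistic is
#' `Q = n (n + 2) * sum_{k=1..h} rho_k^2 / (n - k)`; the Box-Pierce variant
#' is `Q = n * sum rho_k^2`. Q is referred to a chi-square with `lags`
#' degrees of freedom — no degrees-of-freedom correction is applied, because
#' the residuals here come from mean-only (drift) fitting, not an ARMA fit.
#'
#' @param residuals Numeric residual series with nonzero variance.
#' @param lags Number of lags h to pool; default `min(10, floor(n / 5))`.
#' @param variant `"ljung-box"` (default) or `"box-pierce"`.
#' @return An object of class `portmanteau_test` with elements `Q`, `df`,
#'   `p`, `variant`, `lags`, `n` and the `rho` vector used.
#' @export
#' @examples
#' set.seed(1)
#' portmanteau_test(rnorm(60), lags = 10)
portmanteau_test <- function(residuals, lags = NULL,
                             variant = c("ljung-box", "box-pierce")) {
  variant <- match.arg(variant)
  residuals <- as.numeric(residuals)
  n <- length(residuals)
  if (is.null(lags)) lags <- min(10L, floor(n / 5))
  if (!is_scalar_number(lags) || lags < 1 || lags != round(lags)) {
    stop_config("`lags` must be a positive integer.")
  }
  lags <- as.integer(lags)
  if (n <= lags + 1L) {
    stop_data("Residual series too short for %d lags.", lags)
  }
  acf_res <- series_acf(residuals, max_lag = lags)
  rho <- acf_res$rho[-1]
  Q <- if (variant == "ljung-box") {
    n * (n + 2) * sum(rho^2 / (n - seq_len(lags)))
  } else {
    n * sum(rho^2)
  }
  structure(
    list(
      Q = Q, df = lags, p = pchisq(Q, df = lags, lower.tail = FALSE),
      variant = variant, lags = lags, n = n, rho = rho
    ),
    class = "portmanteau_test"
  )
}

#' @export
print.portmanteau_test <- function(x, ...) {
  cat(sprintf(
    "Portmanteau (%s) test: Q = %.4g on %d df, p = %.4g (n = %d)\n",
    x$variant, x$Q, x$df, x$p, x$n
  ))
  invisible(x)
}

#' Reconstruct the level series from drift, anchor and innovations
#'
#' Inverts the differencing: `H_t = mu * t + h0 + (a_1 + ... + a_t)` for
#' t = 0..n, so `reconstruct_series()` applied to the output of
#' [estimate_drift()] with `h0 = H[1]` reproduces the original series.
#'
#' @param mu Drift per step.
#' @param h0 Anchor: the series value at t = 0.
#' @param residuals Innovation sequence `a_1..a_n`.
#' @return Numeric vector of length `length(residuals) + 1`.
#' @export
#' @examples
#' reconstruct_series(0.02, 1, rep(0, 5))  # 1.00 1.02 ... 1.10
reconstruct_series <- function(mu, h0, residuals) {
  if (!is_scalar_number(mu) || !is_scalar_number(h0)) {
    stop_config("`mu` and `h0` must be single finite numbers.")
  }
  residuals <- as.numeric(residuals)
  if (any(!is.finite(residuals))) stop_data("Residuals must be finite.")
  n <- length(residuals)
  mu * (0:n) + h0 + c(0, cumsum(residuals))
}

#' Fit the random-walk-with-drift model to a hazard-ratio series
#'
#' Differences the ordered H_t series, estimates the drift and innovation
#' variance, and runs autocorrelation plus portmanteau white-noise
#' diagnostics on the innovations. Retained sweep points are re-indexed
#' consecutively by default (unit steps), since skipped cutoffs would
#' otherwise create irregular spacing; `spacing = "percent"` instead divides
#' each difference by the actual cutoff gap, giving drift per percentage
#' point. `scale = "log"` models log(H_t).
#'
#' @param series An `hr_series` tibble from [sweep_cutoffs()] (or any data
#'   frame with `cutoff_pct` and `hr` columns, or a bare numeric H_t vector).
#' @param lags Portmanteau lag count h; default `min(10, floor(n_diffs / 5))`.
#' @param variant Portmanteau variant, `"ljung-box"` or `"box-pierce"`.
#' @param scale `"natural"` (differences of H_t, the default) or `"log"`.
#' @param spacing `"index"` (unit steps, default) or `"percent"`.
#' @return An object of class `rw_fit`: `drift` (a [estimate_drift()] result),
#'   `acf`, `portmanteau` (either may be `NULL` for a degenerate, e.g.
#'   pure-drift, series — see `notes`), `h0`, `n_points`, plus the
#'   configuration echo (`lags`, `variant`, `scale`, `spacing`). Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' H <- 1 + 0.02 * (0:40) + rnorm(41, sd = 0.06)
#' fit <- fit_random_walk(H)
#' glance(fit)
fit_random_walk <- function(series, lags = NULL,
                            variant = c("ljung-box", "box-pierce"),
                            scale = c("natural", "log"),
                            spacing = c("index", "percent")) {
  variant <- match.arg(variant)
  scale <- match.arg(scale)
  spacing <- match.arg(spacing)
  if (is.data.frame(series)) {
    if (!all(c("cutoff_pct", "hr") %in% names(series))) {
      stop_data("`series` must have `cutoff_pct` and `hr` columns.")
    }
    H <- series$hr
    t_pct <- series$cutoff_pct
  } else {
    H <- as.numeric(series)
    t_pct <- seq_along(H)
  }
  if (scale == "log") {
    if (any(H <= 0)) stop_data("Log scale requires positive hazard ratios.")
    H <- log(H)
  }
  if (length(H) < 3L) {
    stop_data("Need at least 3 retained points to fit the model.")
  }
  d <- difference_series(H)
  if (spacing == "percent") {
    gaps <- diff(t_pct)
    if (any(gaps <= 0)) stop_data("Cutoffs must be strictly increasing.")
    d <- d / gaps
  }
  if (is.null(lags)) lags <- max(1L, min(10L, floor(length(d) / 5)))
  if (length(d) < lags + 3L) {
    stop_data(
      "Series too short: %d differences for %d portmanteau lags (need >= %d).",
      length(d), lags, lags + 3L
    )
  }
  drift <- estimate_drift(d)
  notes <- character()
  acf_res <- NULL
  pm <- NULL
  # a pure-drift series leaves residuals at floating-point noise; treat
  # variance below 1e-10 of the difference scale as zero-variance too
  degenerate <- drift$sigma2 == 0 ||
    sqrt(drift$sigma2) < 1e-10 * max(abs(d))
  if (degenerate) {
    notes <- c(notes, paste(
      "white-noise diagnostics degenerate:",
      "zero-variance residuals (pure-drift series)."
    ))
  } else {
    diag_res <- tryCatch(
      list(
        acf = series_acf(drift$residuals, max_lag = lags),
        pm = portmanteau_test(drift$residuals, lags = lags, variant = variant)
      ),
      nodewalk_data_error = function(e) e
    )
    if (inherits(diag_res, "condition")) {
      notes <- c(notes, paste("white-noise diagnostics degenerate:",
                              conditionMessage(diag_res)))
    } else {
      acf_res <- diag_res$acf
      pm <- diag_res$pm
    }
  }
  structure(
    list(
      drift = drift,
      acf = acf_res,
      portmanteau = pm,
      h0 = H[1],
      n_points = length(H),
      t = t_pct,
      H = H,
      lags = as.integer(lags),
      variant = variant,
      scale = scale,
      spacing = spacing,
      notes = notes
    ),
    class = "rw_fit"
  )
}

#' @export
print.rw_fit <- function(x, ...) {
  cat(sprintf(
    "<rw_fit> random walk with drift on %d points (%s scale, %s spacing)\n",
    x$n_points, x$scale, x$spacing
  ))
  cat(sprintf("  mu = %.4g per step, sigma2 = %.4g\n",
              x$drift$mu, x$drift$sigma2))
  if (!is.null(x$portmanteau)) {
    cat("  ")
    print(x$portmanteau)
  }
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' @method tidy rw_fit
#' @export
tidy.rw_fit <- function(x, ...) {
  se_mu <- sqrt(x$drift$sigma2 / x$drift$n_diffs)
  tibble::tibble(
    term = c("mu", "sigma2"),
    estimate = c(x$drift$mu, x$drift$sigma2),
    std.error = c(se_mu, NA_real_)
  )
}

#' @method glance rw_fit
#' @export
glance.rw_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$drift$mu,
    sigma2 = x$drift$sigma2,
    n_points = x$n_points,
    n_diffs = x$drift$n_diffs,
    lags = x$lags,
    variant = x$variant,
    statistic = if (is.null(x$portmanteau)) NA_real_ else x$portmanteau$Q,
    p.value = if (is.null(x$portmanteau)) NA_real_ else x$portmanteau$p,
    scale = x$scale,
    spacing = x$spacing
  )
}

#' Plot the differenced series with the drift line
#'
#' Differences `H_t - H_{t-1}` against the cutoff, with a horizontal line at
#' the estimated drift — the differenced-series panel of the analysis.
#'
#' @param object An `rw_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rw_fit
#' @export
autoplot.rw_fit <- function(object, ...) {
  d <- object$drift$residuals + object$drift$mu
  df <- tibble::tibble(t = object$t[-1], diff = d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$drift$mu) +
    ggplot2::labs(
      x = "Percentage of involved nodes cutoff (t)",
      y = expression(H[t] - H[t - 1]),
      subtitle = sprintf("horizontal line: estimated drift mu = %.4g",
                         object$drift$mu)
    ) +
    ggplot2::theme_minimal()
}
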