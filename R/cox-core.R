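# Cox partial-likelihood machinery, written directly from the likelihood.
#
# All quantities are computed on data sorted by increasing time. For an event
# time t_g with d_g tied deaths, the Efron correction evaluates the l-th tied
# death (l = 0..d_g-1) against the denominator S0(t_g) - (l/d_g) * D0(t_g),
# where S0 is the risk-set sum of exp(eta) and D0 the same sum over the tied
# deaths; Breslow uses the uncorrected S0 for all d_g deaths. Risk-set sums
# are reverse cumulative sums, and the per-death denominators are assembled
# group-wise, so no explicit loop over risk sets is needed.

# Precompute ordering, tie groups and centred covariates for repeated
# likelihood evaluations. Centring columns leaves the partial likelihood
# invariant and keeps exp(eta) well scaled.
cox_prep <- function(time, event, X, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(time)
  if (length(event) != n || nrow(X) != n) {
    stop_data("`time`, `event` and `X` must have matching lengths.")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop_data("All times must be finite and positive.")
  }
  if (!all(event %in% c(0, 1))) stop_data("`event` must be coded 0/1.")
  if (sum(event) == 0) {
    stop_data("No events: the partial likelihood is undefined.")
  }
  ord <- order(time)
  time <- time[ord]
  event <- as.integer(event[ord])
  X <- X[ord, , drop = FALSE]
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  ev_idx <- which(event == 1L)
  ev_times <- time[ev_idx]
  ug <- unique(ev_times)
  gid <- match(ev_times, ug)
  d <- tabulate(gid)
  # first sorted index at risk at each unique event time (time >= t_g)
  risk_start <- match(ug, time)
  # within-group death index l = 0..d-1 (Efron); all zero for Breslow
  l_within <- sequence(d) - 1L
  # ev_idx is time-ordered, so deaths of a group are consecutive
  lfrac <- if (ties == "efron") l_within / d[gid] else rep(0, length(gid))
  p <- ncol(Xc)
  vech_i <- rep(seq_len(p), times = p:1)
  vech_j <- unlist(lapply(seq_len(p), function(i) i:p))
  list(
    time = time, event = event, X = Xc, n = n, p = p,
    ev_idx = ev_idx, gid = gid, d = d, risk_start = risk_start,
    lfrac = lfrac, ties = ties, vech_i = vech_i, vech_j = vech_j,
    center = center, n_events = length(ev_idx)
  )
}

# Partial log-likelihood and, optionally, its score vector and observed
# information at `beta`, all from one pass of reverse cumulative sums.
cox_terms <- function(prep, beta, derivatives = TRUE) {
  X <- prep$X
  eta <- drop(X %*% beta)
  eta <- pmin(pmax(eta, -500), 500)
  w <- exp(eta)
  ev <- prep$ev_idx
  g <- prep$gid
  rs <- prep$risk_start
  cum0 <- rev(cumsum(rev(w)))
  D0 <- drop(rowsum(w[ev], g, reorder = TRUE))
  En0 <- cum0[rs][g] - prep$lfrac * D0[g]
  loglik <- sum(eta[ev]) - sum(log(En0))
  if (!derivatives) {
    return(list(loglik = loglik))
  }
  WX <- w * X
  cum1 <- rev_cumsum_matrix(WX)
  D1 <- rowsum(WX[ev, , drop = FALSE], g, reorder = TRUE)
  En1 <- cum1[rs, , drop = FALSE][g, , drop = FALSE] - prep$lfrac * D1[g, , drop = FALSE]
  R <- En1 / En0
  score <- colSums(X[ev, , drop = FALSE]) - colSums(R)
  Z <- WX[, prep$vech_i, drop = FALSE] * X[, prep$vech_j, drop = FALSE]
  cum2 <- rev_cumsum_matrix(Z)
  D2 <- rowsum(Z[ev, , drop = FALSE], g, reorder = TRUE)
  En2 <- cum2[rs, , drop = FALSE][g, , drop = FALSE] - prep$lfrac * D2[g, , drop = FALSE]
  s2 <- colSums(En2 / En0)
  p <- prep$p
  info <- matrix(0, p, p)
  info[cbind(prep$vech_i, prep$vech_j)] <- s2
  info[cbind(prep$vech_j, prep$vech_i)] <- s2
  info <- info - crossprod(R)
  list(loglik = loglik, score = score, info = info)
}

#' Cox partial log-likelihood
#'
#' Evaluates the Cox proportional-hazards partial log-likelihood at a given
#' coefficient vector, with Efron (default) or Breslow handling of tied event
#' times. The two corrections coincide exactly when no event times are tied.
#'
#' @param beta Coefficient vector, one entry per column of `X`.
#' @param time Positive follow-up times.
#' @param event Event indicators, 0/1 (at least one event required).
#' @param X Covariate matrix, rows matching `time`.
#' @param ties `"efron"` or `"breslow"`.
#' @return The partial log-likelihood, a single number.
#' @export
#' @examples
#' # two subjects, one informative risk set: at beta = 0 the only term is
#' # log(1/2)
#' cox_partial_loglik(0, time = c(1, 2), event = c(1, 1), X = cbind(c(1, 0)))
cox_partial_loglik <- function(beta, time, event, X,
                               ties = c("efron", "breslow")) {
  prep <- cox_prep(time, event, as.matrix(X), match.arg(ties))
  if (length(beta) != prep$p) {
    stop_data("`beta` must have one entry per column of `X`.")
  }
  cox_terms(prep, as.numeric(beta), derivatives = FALSE)$loglik
}

# Newton-Raphson maximisation of the partial likelihood with step halving.
# Returns an (unclassed) fit list; fit_cox() adds names and class.
cox_newton <- function(time, event, X, ties = "efron", tol = 1e-8,
                       max_iter = 50L, flag_bound = 15, init = NULL) {
  p <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(is.na(sds) | sds == 0)) {
    stop_data("Degenerate design: covariate column(s) %s are constant.",
              paste(which(sds == 0), collapse = ", "))
  }
  prep <- cox_prep(time, event, X, ties)
  beta <- if (is.null(init)) numeric(p) else as.numeric(init)
  cur <- cox_terms(prep, beta)
  loglik0 <- if (all(beta == 0)) cur$loglik else
    cox_terms(prep, numeric(p), derivatives = FALSE)$loglik
  converged <- FALSE
  flagged <- rep(FALSE, p)
  singular <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      singular <- TRUE
      break
    }
    halves <- 0L
    repeat {
      cand <- beta + step
      new <- cox_terms(prep, cand)
      if (is.finite(new$loglik) && new$loglik >= cur$loglik - 1e-12) break
      step <- step / 2
      halves <- halves + 1L
      if (halves > 25L) break
    }
    if (halves > 25L) break
    beta <- cand
    cur <- new
    if (any(abs(beta) > flag_bound)) {
      flagged <- abs(beta) > flag_bound
      break
    }
    if (max(abs(cur$score)) < tol) {
      converged <- TRUE
      break
    }
  }
  covariance <- tryCatch(solve(cur$info), error = function(e) {
    singular <<- TRUE
    matrix(NA_real_, p, p)
  })
  covariance <- (covariance + t(covariance)) / 2
  list(
    coefficients = beta,
    covariance = covariance,
    loglik = cur$loglik,
    loglik_null = loglik0,
    score = cur$score,
    n = prep$n,
    n_events = prep$n_events,
    converged = converged && !any(flagged) && !singular,
    iterations = iter,
    flags = flagged,
    singular = singular,
    ties = prep$ties,
    tol = tol
  )
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Cox partial likelihood by Newton-Raphson with step halving.
#' Convergence is declared when the score sup-norm falls below `tol`; the
#' coefficient covariance is the inverse observed information at the optimum.
#' A coefficient whose magnitude crosses `flag_bound` is flagged as a
#' monotone-likelihood (separation) case and the fit is reported as not
#' converged rather than erroring, so sweeps can skip such cutoffs.
#'
#' @param data A data frame holding the modelling columns.
#' @param covariates Character vector of covariate column names.
#' @param time,event Names of the follow-up time and 0/1 event columns.
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @param tol Convergence tolerance on the score sup-norm.
#' @param max_iter Maximum Newton iterations.
#' @param flag_bound Monotone-likelihood bound on `|beta_j|`.
#' @param init Optional starting coefficient vector (defaults to zero).
#' @return An object of class `cox_fit`: named `coefficients` (log hazard
#'   ratios), `covariance`, `loglik`, `loglik_null`, `n`, `n_events`,
#'   `converged`, `iterations` and per-coefficient monotone-likelihood
#'   `flags`. Supports [tidy()], [glance()] and [hazard_ratio_ci()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 300, seed = 2))
#' fit <- fit_cox(cohort, covariates = c("black", "grade_high", "age_years"))
#' tidy(fit, exponentiate = TRUE)
fit_cox <- function(data, covariates, time = "time", event = "event",
                    ties = c("efron", "breslow"), tol = 1e-8, max_iter = 50L,
                    flag_bound = 15, init = NULL) {
  ties <- match.arg(ties)
  missing <- setdiff(c(time, event, covariates), names(data))
  if (length(missing)) {
    stop_data("`data` is missing columns: %s.", paste(missing, collapse = ", "))
  }
  X <- as.matrix(data[covariates])
  if (!is.numeric(X)) stop_data("Covariate columns must be numeric.")
  fit <- cox_newton(data[[time]], data[[event]], X, ties = ties, tol = tol,
                    max_iter = max_iter, flag_bound = flag_bound, init = init)
  names(fit$coefficients) <- covariates
  dimnames(fit$covariance) <- list(covariates, covariates)
  names(fit$flags) <- covariates
  class(fit) <- "cox_fit"
  fit
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, %s ties, %s (%d iterations)\n",
              x$n, x$n_events, x$ties,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(tidy(x), ...)
  invisible(x)
}

#' Wald confidence interval for a hazard ratio
#'
#' Extracts `exp(beta_j)` with a Wald interval on the log scale:
#' `exp(beta_j +/- z * se_j)` at the requested coverage.
#'
#' @param fit A converged [fit_cox()] object.
#' @param term Coefficient name or index.
#' @param level Coverage probability (default 0.95).
#' @return A one-row tibble: `term`, `hr`, `lo`, `hi`, `level`.
#' @export
hazard_ratio_ci <- function(fit, term, level = 0.95) {
  if (!inherits(fit, "cox_fit")) stop_data("`fit` must be a cox_fit object.")
  if (!isTRUE(fit$converged)) {
    stop_numeric("Hazard-ratio interval requested from a non-converged fit.")
  }
  if (!is_scalar_number(level) || level <= 0 || level >= 1) {
    stop_config("`level` must be in (0, 1).")
  }
  nm <- names(fit$coefficients)
  j <- if (is.character(term)) match(term, nm) else as.integer(term)
  if (is.na(j) || j < 1L || j > length(nm)) {
    stop_data("Unknown coefficient `term`.")
  }
  b <- fit$coefficients[[j]]
  se <- sqrt(fit$covariance[j, j])
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = nm[j], hr = exp(b), lo = exp(b - z * se), hi = exp(b + z * se),
    level = level
  )
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, exponentiate = FALSE, conf.int = FALSE,
                         conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$covariance))
  stat <- est / se
  out <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat)))
  )
  if (conf.int) {
    z <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    if (conf.int) {
      out$conf.low <- exp(out$conf.low)
      out$conf.high <- exp(out$conf.high)
    }
  }
  out
}

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, loglik = x$loglik,
    loglik_null = x$loglik_null, iterations = x$iterations,
    converged = x$converged, ties = x$ties
  )
}
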