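# Stratum bounds for nodes examined: 1-4, 5-9, 10-14, 15-max_examined.
examined_strata <- function(max_examined) {
  list(lo = c(1L, 5L, 10L, 15L), hi = c(4L, 9L, 14L, as.integer(max_examined)))
}

#' Sample nodes examined and nodes positive
#'
#' Draws the nodes-examined stratum from the configured weights, the examined
#' count uniformly within the stratum, a per-patient involvement propensity
#' from the configured beta mixture (or the fixed value), and the positive
#' count as a binomial truncated to at least one involved node. Truncation is
#' by rejection, which targets the mixture distribution conditioned on one or
#' more positive nodes.
#'
#' @param n Number of patients to draw.
#' @param config A [cohort_config()].
#' @param seed Optional integer seed (local to this call).
#' @return A tibble with integer columns `nodes_examined`, `nodes_positive`;
#'   every row satisfies `1 <= nodes_positive <= nodes_examined`.
#' @export
#' @examples
#' sample_nodal_counts(5, cohort_config(), seed = 1)
sample_nodal_counts <- function(n, config = cohort_config(), seed = NULL) {
  if (!inherits(config, "cohort_config")) {
    stop_config("`config` must be a cohort_config object.")
  }
  if (!is_scalar_number(n) || n < 1 || n != round(n)) {
    stop_config("`n` must be a positive integer.")
  }
  n <- as.integer(n)
  with_seed(seed, {
    strata <- examined_strata(config$max_examined)
    s <- sample.int(4L, n, replace = TRUE, prob = config$examined_weights)
    width <- strata$hi[s] - strata$lo[s] + 1L
    examined <- strata$lo[s] + as.integer(floor(runif(n) * width))
    positive <- draw_positive(examined, config$involvement)
    tibble::tibble(nodes_examined = examined, nodes_positive = positive)
  })
}

draw_positive <- function(examined, inv) {
  n <- length(examined)
  positive <- integer(n)
  todo <- seq_len(n)
  guard <- 0L
  while (length(todo)) {
    m <- length(todo)
    if (!is.null(inv$fixed)) {
      p <- rep(inv$fixed, m)
    } else {
      comp <- sample.int(length(inv$weights), m, replace = TRUE,
                         prob = inv$weights)
      p <- rbeta(m, inv$alpha[comp], inv$beta[comp])
    }
    k <- rbinom(m, examined[todo], p)
    ok <- k >= 1L
    positive[todo[ok]] <- k[ok]
    todo <- todo[!ok]
    guard <- guard + 1L
    if (guard > 10000L) {
      stop_numeric("Truncated involvement sampling failed to terminate.")
    }
  }
  positive
}

#' Sample adjustment covariates
#'
#' Draws the demographic and tumour covariates from their marginal
#' distributions: Bernoulli indicators at the configured prevalences, age
#' uniform on (50, 65) years, tumour size uniform on (1, 50) mm, year of
#' diagnosis uniform over 1988-1997, and a three-level geography expanded into
#' `area_central` / `area_west` indicators (east is the reference).
#'
#' @inheritParams sample_nodal_counts
#' @return A tibble with one row per patient and the covariate columns
#'   `age_years`, `black`, `married`, `ductal`, `grade_high`, `er_negative`,
#'   `pr_negative`, `medial`, `tumor_size_mm`, `year_dx`, `area_central`,
#'   `area_west`.
#' @export
sample_covariates <- function(n, config = cohort_config(), seed = NULL) {
  if (!is_scalar_number(n) || n < 1 || n != round(n)) {
    stop_config("`n` must be a positive integer.")
  }
  n <- as.integer(n)
  prev <- config$covariate_prevalence
  with_seed(seed, {
    area <- sample(names(prev$area), n, replace = TRUE, prob = prev$area)
    tibble::tibble(
      age_years = runif(n, 50, 65),
      black = rbinom(n, 1L, prev$black),
      married = rbinom(n, 1L, prev$married),
      ductal = rbinom(n, 1L, prev$ductal),
      grade_high = rbinom(n, 1L, prev$grade_high),
      er_negative = rbinom(n, 1L, prev$er_negative),
      pr_negative = rbinom(n, 1L, prev$pr_negative),
      medial = rbinom(n, 1L, prev$medial),
      tumor_size_mm = runif(n, 1, 50),
      year_dx = sample(1988:1997, n, replace = TRUE),
      area_central = as.integer(area == "central"),
      area_west = as.integer(area == "west")
    )
  })
}

# Linear predictor of the generative proportional-hazards model. Continuous
# covariates are centred at their natural origin so the baseline rate refers
# to an age-50 patient diagnosed in 1988.
cohort_linear_predictor <- function(records, config) {
  pct <- node_percentage(records$nodes_positive, records$nodes_examined)
  eff <- config$covariate_effects
  centred <- cbind(
    area_central = records$area_central,
    area_west = records$area_west,
    year_dx = records$year_dx - 1988,
    black = records$black,
    married = records$married,
    age_years = records$age_years - 50,
    ductal = records$ductal,
    grade_high = records$grade_high,
    er_negative = records$er_negative,
    pr_negative = records$pr_negative,
    medial = records$medial,
    tumor_size_mm = records$tumor_size_mm
  )
  drop(config$beta_pct * pct + centred %*% eff[colnames(centred)])
}

#' Simulate survival outcomes for a set of patient records
#'
#' Given node counts and covariates, draws an exponential event time with
#' log-rate `log(baseline) + beta_pct * pct + sum(effects * covariates)` where
#' `pct = 100 * nodes_positive / nodes_examined`, an independent uniform
#' administrative censoring time from the configured window, and records the
#' earlier of the two with the corresponding event indicator.
#'
#' @param records A data frame with `nodes_examined`, `nodes_positive` and the
#'   covariate columns of [sample_covariates()].
#' @param config A [cohort_config()].
#' @param seed Optional integer seed (local to this call).
#' @param censor If `FALSE`, disable censoring (all events observed).
#' @return A tibble: `records` with `time` (months, > 0) and `event` (0/1)
#'   columns appended.
#' @export
simulate_survival <- function(records, config = cohort_config(), seed = NULL,
                              censor = TRUE) {
  needed <- c("nodes_examined", "nodes_positive",
              names(default_covariate_effects()))
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop_data("`records` is missing columns: %s.",
              paste(missing, collapse = ", "))
  }
  lp <- cohort_linear_predictor(records, config)
  rate <- config$baseline_hazard_rate * exp(lp)
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stop_config("Non-finite or non-positive hazard rate; check effects.")
  }
  n <- nrow(records)
  with_seed(seed, {
    t_event <- rexp(n, rate)
    if (censor) {
      t_cens <- runif(n, config$censoring[1], config$censoring[2])
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    if (config$round_times) time <- ceiling(time)
    out <- tibble::as_tibble(records)
    out$time <- time
    out$event <- event
    out
  })
}

#' Generate a complete synthetic cohort
#'
#' Composes [sample_nodal_counts()], [sample_covariates()] and
#' [simulate_survival()] into one seeded draw of a registry-like node-positive
#' cohort. Identical configuration and seed give an identical table.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to the seed stored in `config`.
#' @return A tibble with one row per patient: `id`, `time` (months), `event`
#'   (0/1), `nodes_examined`, `nodes_positive`, and the covariate columns.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 200, seed = 7))
#' dplyr::count(cohort, event)
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  if (!inherits(config, "cohort_config")) {
    stop_config("`config` must be a cohort_config object.")
  }
  n <- config$n_patients
  with_seed(seed, {
    counts <- sample_nodal_counts(n, config)
    covs <- sample_covariates(n, config)
    records <- dplyr::bind_cols(counts, covs)
    out <- simulate_survival(records, config)
    out <- dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
    dplyr::select(
      out, "id", "time", "event", "nodes_examined", "nodes_positive",
      "age_years", "black", "married", "ductal", "grade_high", "er_negative",
      "pr_negative", "medial", "tumor_size_mm", "year_dx", "area_central",
      "area_west"
    )
  })
}

cohort_columns <- function() {
  c("id", "time", "event", "nodes_examined", "nodes_positive", "age_years",
    "black", "married", "ductal", "grade_high", "er_negative", "pr_negative",
    "medial", "tumor_size_mm", "year_dx", "area_central", "area_west")
}

#' Read / write a cohort CSV
#'
#' The on-disk schema is one header row with the columns `id, time, event,
#' nodes_examined, nodes_positive, age_years, black, married, ductal,
#' grade_high, er_negative, pr_negative, medial, tumor_size_mm, year_dx,
#' area_central, area_west`; times in months, binary columns coded 0/1.
#' Reading validates the patient-record invariants (positive times, binary
#' events, `1 <= nodes_positive <= nodes_examined`).
#'
#' @param cohort A cohort tibble as produced by [generate_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns a validated tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing <- setdiff(cohort_columns(), names(cohort))
  if (length(missing)) {
    stop_data("Cohort is missing columns: %s.", paste(missing, collapse = ", "))
  }
  readr::write_csv(cohort[cohort_columns()], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_data("Cohort file not found: %s", path)
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(cohort)
}

# Shared invariant checks for any cohort table entering the analysis.
validate_cohort <- function(cohort) {
  missing <- setdiff(setdiff(cohort_columns(), "id"), names(cohort))
  if (length(missing)) {
    stop_data("Cohort is missing columns: %s.", paste(missing, collapse = ", "))
  }
  if (nrow(cohort) == 0L) stop_data("Cohort has no rows.")
  if (any(!is.finite(cohort$time)) || any(cohort$time <= 0)) {
    stop_data("All survival times must be finite and positive.")
  }
  if (!all(cohort$event %in% c(0, 1))) {
    stop_data("`event` must be coded 0/1.")
  }
  if (any(cohort$nodes_examined < 1) ||
      any(cohort$nodes_positive < 1) ||
      any(cohort$nodes_positive > cohort$nodes_examined)) {
    stop_data(
      "Node counts violate 1 <= nodes_positive <= nodes_examined (e.g. more involved nodes than examined)."
    )
  }
  tibble::as_tibble(cohort)
}
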