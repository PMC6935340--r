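#' Percentage of involved nodes
#'
#' Computes `100 * nodes_positive / nodes_examined`, the lymph node ratio
#' expressed as a percentage. For node-positive records the value lies in
#' (0, 100]. A record with more involved than examined nodes is a
#' data-integrity error, mirroring the registry cleaning rule.
#'
#' @param nodes_positive,nodes_examined Integer vectors (recycled like base
#'   arithmetic operands of equal length).
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' node_percentage(5, 20)  # 25
#' node_percentage(7, 7)   # 100
node_percentage <- function(nodes_positive, nodes_examined) {
  if (any(nodes_examined < 1)) {
    stop_data("`nodes_examined` must be at least 1.")
  }
  if (any(nodes_positive < 0)) {
    stop_data("`nodes_positive` must be non-negative.")
  }
  if (any(nodes_positive > nodes_examined)) {
    stop_data("More involved nodes than examined.")
  }
  100 * nodes_positive / nodes_examined
}

#' Default adjustment covariates for the cutoff sweep
#'
#' The demographic and tumour covariates used to adjust every cutoff model:
#' geography, year of diagnosis, race, marital status, age, histology, grade,
#' hormone receptors, tumour location and size. Node-count variables are
#' deliberately excluded — the cutoff indicator is the nodal term.
#'
#' @return Character vector of covariate column names.
#' @export
sweep_adjustment <- function() {
  c("area_central", "area_west", "year_dx", "black", "married", "age_years",
    "ductal", "grade_high", "er_negative", "pr_negative", "medial",
    "tumor_size_mm")
}

# Integer cutoffs in 1..100 that induce distinct dichotomies of `pct`,
# keeping the smallest cutoff of each run of identical splits.
observed_cutoff_grid <- function(pct) {
  cand <- 1:100
  n_high <- length(pct) - findInterval(cand - 1e-9, sort(pct))
  keep <- c(TRUE, diff(n_high) != 0)
  cand[keep]
}

#' Sweep dichotomisation cutoffs over the percentage of involved nodes
#'
#' For each cutoff t, fits an adjusted Cox model with the indicator
#' `pct >= t` (strictly-below as reference) plus the adjustment covariates,
#' and records the indicator's hazard ratio H_t with a Wald 95% interval.
#' Cutoffs with fewer than `min_events` events in either arm, degenerate
#' designs, monotone-likelihood flags or non-converged fits are set aside
#' with a reason rather than reported.
#'
#' @param cohort A cohort table (see [generate_cohort()] / [read_cohort()]).
#' @param adjustment Covariate names to adjust for; default
#'   [sweep_adjustment()].
#' @param cutoffs Integer cutoff grid in percent; the default uses the
#'   integer percentages 1-100 restricted to dichotomies observable in the
#'   cohort, each distinct split once.
#' @param min_events Minimum events required in each arm (default 10).
#' @param ties,conf_level Passed to the per-cutoff Cox fits.
#' @return A tibble of class `hr_series`, ordered by cutoff, with columns
#'   `cutoff_pct`, `hr`, `lo`, `hi`, `n_high`, `events_high`, `events_low`.
#'   Skipped cutoffs are in `attr(, "skipped")` (columns `cutoff_pct`,
#'   `reason`); the confidence level and adjustment set are also attached as
#'   attributes.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 800, seed = 3))
#' series <- sweep_cutoffs(cohort)
#' head(series)
#' attr(series, "skipped")
sweep_cutoffs <- function(cohort, adjustment = sweep_adjustment(),
                          cutoffs = NULL, min_events = 10,
                          ties = c("efron", "breslow"), conf_level = 0.95) {
  ties <- match.arg(ties)
  cohort <- validate_cohort(cohort)
  missing <- setdiff(adjustment, names(cohort))
  if (length(missing)) {
    stop_data("Adjustment covariates not in cohort: %s.",
              paste(missing, collapse = ", "))
  }
  if (!is_scalar_number(min_events) || min_events < 0) {
    stop_config("`min_events` must be a non-negative number.")
  }
  pct <- node_percentage(cohort$nodes_positive, cohort$nodes_examined)
  if (is.null(cutoffs)) {
    cutoffs <- observed_cutoff_grid(pct)
  } else {
    if (any(!is.finite(cutoffs))) stop_config("`cutoffs` must be finite.")
    cutoffs <- sort(unique(cutoffs))
  }
  time <- cohort$time
  event <- cohort$event
  X_adj <- as.matrix(cohort[adjustment])
  z <- qnorm(1 - (1 - conf_level) / 2)
  init <- NULL
  rows <- vector("list", length(cutoffs))
  skipped <- vector("list", length(cutoffs))
  for (i in seq_along(cutoffs)) {
    t_cut <- cutoffs[i]
    high <- pct >= t_cut
    ev_high <- sum(event[high])
    ev_low <- sum(event[!high])
    if (ev_high < min_events || ev_low < min_events) {
      skipped[[i]] <- tibble::tibble(
        cutoff_pct = t_cut,
        reason = sprintf("min_events: %d high / %d low", ev_high, ev_low)
      )
      next
    }
    X <- cbind(high_pct = as.numeric(high), X_adj)
    fit <- tryCatch(
      cox_newton(time, event, X, ties = ties,
                 init = if (is.null(init)) NULL else init),
      nodewalk_data_error = function(e) e
    )
    if (inherits(fit, "condition")) {
      skipped[[i]] <- tibble::tibble(cutoff_pct = t_cut,
                                     reason = "degenerate design")
      next
    }
    if (any(fit$flags)) {
      skipped[[i]] <- tibble::tibble(cutoff_pct = t_cut,
                                     reason = "monotone likelihood")
      init <- NULL
      next
    }
    if (!fit$converged) {
      skipped[[i]] <- tibble::tibble(cutoff_pct = t_cut,
                                     reason = "not converged")
      init <- NULL
      next
    }
    b <- unname(fit$coefficients[1])
    se <- sqrt(fit$covariance[1, 1])
    rows[[i]] <- tibble::tibble(
      cutoff_pct = t_cut,
      hr = exp(b),
      lo = exp(b - z * se),
      hi = exp(b + z * se),
      n_high = sum(high),
      events_high = ev_high,
      events_low = ev_low
    )
    init <- fit$coefficients
  }
  series <- dplyr::bind_rows(rows)
  skipped <- dplyr::bind_rows(skipped)
  if (nrow(series) == 0L) {
    stop_data("Every cutoff was skipped; no hazard-ratio series to model.")
  }
  new_hr_series(series, skipped = skipped, conf_level = conf_level,
                adjustment = adjustment, min_events = min_events)
}

new_hr_series <- function(series, skipped, conf_level, adjustment,
                          min_events) {
  structure(
    series,
    skipped = skipped,
    conf_level = conf_level,
    adjustment = adjustment,
    min_events = min_events,
    class = c("hr_series", class(tibble::tibble()))
  )
}

#' Read / write a hazard-ratio series CSV
#'
#' `write_hr_series()` writes the retained points to `path` (columns
#' `cutoff_pct, hr, lo95, hi95, n_high, events_high, events_low`) and the
#' skipped cutoffs with their reasons to a `*_skipped.csv` sidecar.
#' `read_hr_series()` reads the pair back into an `hr_series` tibble.
#'
#' @param series An `hr_series` object.
#' @param path CSV path for the retained points.
#' @return `write_hr_series()` returns `path` invisibly; `read_hr_series()`
#'   an `hr_series` tibble.
#' @export
write_hr_series <- function(series, path) {
  out <- tibble::as_tibble(series)
  names(out)[names(out) == "lo"] <- "lo95"
  names(out)[names(out) == "hi"] <- "hi95"
  readr::write_csv(out, path)
  skipped <- attr(series, "skipped") %||% tibble::tibble(
    cutoff_pct = numeric(), reason = character()
  )
  readr::write_csv(skipped, skipped_path(path))
  invisible(path)
}

skipped_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", "_skipped.csv", path)
}

#' @rdname write_hr_series
#' @export
read_hr_series <- function(path) {
  if (!file.exists(path)) stop_data("Series file not found: %s", path)
  series <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("cutoff_pct", "hr", "lo95", "hi95")
  missing <- setdiff(needed, names(series))
  if (length(missing)) {
    stop_data("Series file is missing columns: %s.",
              paste(missing, collapse = ", "))
  }
  names(series)[names(series) == "lo95"] <- "lo"
  names(series)[names(series) == "hi95"] <- "hi"
  skp <- skipped_path(path)
  skipped <- if (file.exists(skp)) {
    readr::read_csv(skp, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::tibble(cutoff_pct = numeric(), reason = character())
  }
  if (is.unsorted(series$cutoff_pct, strictly = TRUE)) {
    stop_data("Series cutoffs must be strictly increasing.")
  }
  new_hr_series(tibble::as_tibble(series), skipped = skipped,
                conf_level = 0.95, adjustment = character(),
                min_events = NA_real_)
}

#' Plot a hazard-ratio series
#'
#' Adjusted hazard ratio H_t against the percentage cutoff t, with the
#' pointwise confidence band and a reference line at HR = 1.
#'
#' @param object An `hr_series` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hr_series
#' @export
autoplot.hr_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$cutoff_pct, y = .data$hr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "Percentage of involved nodes cutoff (t)",
      y = expression("Adjusted mortality hazard ratio " * H[t])
    ) +
    ggplot2::theme_minimal()
}
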