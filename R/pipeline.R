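#' Analysis configuration for the end-to-end pipeline
#'
#' Bundles the cohort generator settings (or a path to an existing cohort
#' CSV), the cutoff-sweep settings and the random-walk settings, with full
#' defaulting. Every value, defaulted or not, is echoed into the run
#' manifest so no silent parameter exists.
#'
#' @param cohort A [cohort_config()], or a path to a cohort CSV.
#' @param sweep List: `adjustment`, `cutoffs`, `min_events`, `ties`,
#'   `conf_level` (missing entries are defaulted).
#' @param rw List: `lags`, `variant`, `scale`, `spacing`.
#' @param seed Integer master seed for the run.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cohort = cohort_config(), sweep = list(),
                            rw = list(), seed = 1L) {
  if (!inherits(cohort, "cohort_config") &&
      !(is.character(cohort) && length(cohort) == 1L)) {
    stop_config("`cohort` must be a cohort_config or a CSV path.")
  }
  sweep <- modifyList(
    list(adjustment = sweep_adjustment(), cutoffs = NULL, min_events = 10,
         ties = "efron", conf_level = 0.95),
    sweep
  )
  rw <- modifyList(
    list(lags = NULL, variant = "ljung-box", scale = "natural",
         spacing = "index"),
    rw
  )
  if (!is_scalar_number(seed)) stop_config("`seed` must be a single integer.")
  structure(
    list(cohort = cohort, sweep = sweep, rw = rw, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Top-level keys `cohort`, `sweep`, `rw`, `seed`; each sub-key overrides the
#' corresponding [analysis_config()] / [cohort_config()] default. Under
#' `cohort`, `path` points at an existing cohort CSV instead of generating
#' one, and `involvement` takes the [involvement_model()] arguments.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_config("Config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cohort <- if (!is.null(raw$cohort$path)) {
    raw$cohort$path
  } else {
    args <- raw$cohort %||% list()
    if (!is.null(args$involvement)) {
      args$involvement <- do.call(involvement_model, args$involvement)
    }
    if (!is.null(args$examined_weights)) {
      args$examined_weights <- as.numeric(args$examined_weights)
    }
    if (!is.null(args$covariate_effects)) {
      args$covariate_effects <- unlist(args$covariate_effects)
    }
    if (!is.null(args$censoring)) args$censoring <- as.numeric(args$censoring)
    do.call(cohort_config, args)
  }
  analysis_config(
    cohort = cohort,
    sweep = raw$sweep %||% list(),
    rw = raw$rw %||% list(),
    seed = raw$seed %||% 1L
  )
}

# Serialisable echo of the full configuration (defaults included).
config_echo <- function(config) {
  cohort <- config$cohort
  cohort_echo <- if (inherits(cohort, "cohort_config")) {
    l <- unclass(cohort)
    l$involvement <- unclass(l$involvement)
    l
  } else {
    list(path = cohort)
  }
  list(cohort = cohort_echo, sweep = config$sweep, rw = config$rw,
       seed = config$seed)
}

stage_log <- function(stage, t0, ...) {
  msg <- paste(sprintf("[%s]", stage), sprintf(...),
               sprintf("(%.2fs)", as.numeric(Sys.time()) - t0))
  message(msg)
}

#' Run the full simulate - sweep - random-walk pipeline
#'
#' Generates (or loads) the cohort, sweeps the percentage-of-involved-nodes
#' cutoffs to build the adjusted hazard-ratio series, fits the
#' random-walk-with-drift model with white-noise diagnostics, renders the
#' two figures, and writes every artifact plus a manifest (seed, full
#' configuration echo, artifact checksums) to `outdir`. Reruns with the same
#' configuration and seed produce byte-identical data artifacts.
#'
#' @param config An [analysis_config()].
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list with `cohort`, `series`, `fit` and the artifact
#'   `paths`.
#' @export
#' @examples
#' \donttest{
#' cfg <- analysis_config(cohort = cohort_config(n_patients = 600, seed = 5))
#' res <- run_pipeline(cfg, outdir = tempfile("nodewalk-run-"))
#' glance(res$fit)
#' }
run_pipeline <- function(config = analysis_config(), outdir, seed = NULL) {
  if (!inherits(config, "analysis_config")) {
    stop_config("`config` must be an analysis_config object.")
  }
  if (missing(outdir) || !is.character(outdir) || length(outdir) != 1L) {
    stop_config("`outdir` must be a single directory path.")
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cohort = file.path(outdir, "cohort.csv"),
    series = file.path(outdir, "hr_series.csv"),
    skipped = file.path(outdir, "hr_series_skipped.csv"),
    rwfit = file.path(outdir, "rwfit.json"),
    manifest = file.path(outdir, "manifest.json")
  )

  t0 <- as.numeric(Sys.time())
  cohort <- if (inherits(config$cohort, "cohort_config")) {
    generate_cohort(config$cohort, seed = config$seed)
  } else {
    read_cohort(config$cohort)
  }
  write_cohort(cohort, paths$cohort)
  stage_log("simulate", t0, "%d patients, %d events",
            nrow(cohort), sum(cohort$event))

  t0 <- as.numeric(Sys.time())
  sw <- config$sweep
  series <- sweep_cutoffs(
    cohort, adjustment = sw$adjustment, cutoffs = sw$cutoffs,
    min_events = sw$min_events, ties = sw$ties, conf_level = sw$conf_level
  )
  write_hr_series(series, paths$series)
  stage_log("sweep", t0, "%d cutoffs retained, %d skipped",
            nrow(series), nrow(attr(series, "skipped")))

  t0 <- as.numeric(Sys.time())
  fit <- fit_random_walk(series, lags = config$rw$lags,
                         variant = config$rw$variant,
                         scale = config$rw$scale,
                         spacing = config$rw$spacing)
  write_rw_fit(fit, paths$rwfit, config = config)
  stage_log("rwfit", t0, "mu = %.4g, sigma2 = %.4g", fit$drift$mu,
            fit$drift$sigma2)

  t0 <- as.numeric(Sys.time())
  figs <- render_figures(series, fit, outdir)
  paths$figures <- figs
  stage_log("plot", t0, "%d figure files", length(figs))

  artifacts <- c(paths$cohort, paths$series, paths$skipped, paths$rwfit, figs)
  manifest <- list(
    package = "nodewalk",
    version = as.character(packageVersion("nodewalk")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = config_echo(config),
    config_hash = rlang::hash(config_echo(config)),
    artifacts = as.list(tools::md5sum(artifacts))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(cohort = cohort, series = series, fit = fit, paths = paths))
}

# rwfit.json: estimates, diagnostics and the full configuration echo.
write_rw_fit <- function(fit, path, config = NULL) {
  out <- list(
    mu = fit$drift$mu,
    sigma2 = fit$drift$sigma2,
    h0 = fit$h0,
    n = fit$n_points,
    n_diffs = fit$drift$n_diffs,
    lags = fit$lags,
    variant = fit$variant,
    scale = fit$scale,
    spacing = fit$spacing,
    Q = if (is.null(fit$portmanteau)) NULL else fit$portmanteau$Q,
    df = if (is.null(fit$portmanteau)) NULL else fit$portmanteau$df,
    p = if (is.null(fit$portmanteau)) NULL else fit$portmanteau$p,
    acf = if (is.null(fit$acf)) NULL else fit$acf$rho,
    residuals = fit$drift$residuals,
    notes = fit$notes,
    config = if (is.null(config)) NULL else config_echo(config)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Render the two pipeline figures
#'
#' Panel (a): the hazard-ratio series H_t against the cutoff with its
#' pointwise confidence band. Panel (b): the successive differences with a
#' horizontal line at the estimated drift. Each panel is written as PNG and,
#' when a vector device is available, SVG (falling back to PDF).
#'
#' @param series An `hr_series` object.
#' @param fit An `rw_fit` object.
#' @param outdir Output directory.
#' @return Character vector of the files written.
#' @export
render_figures <- function(series, fit, outdir) {
  if (!is.data.frame(series) || nrow(series) == 0L) {
    stop_data("Cannot render figures from an empty series.")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  vector_ext <- if (isTRUE(capabilities("cairo"))) "svg" else "pdf"
  plots <- list(hr_series = autoplot(series), hr_differences = autoplot(fit))
  files <- character()
  for (nm in names(plots)) {
    for (ext in c("png", vector_ext)) {
      f <- file.path(outdir, paste0(nm, ".", ext))
      dev <- switch(ext, png = grDevices::png, svg = grDevices::svg,
                    pdf = grDevices::pdf)
      ggplot2::ggsave(f, plots[[nm]], device = dev, width = 7, height = 5,
                      dpi = 150)
      files <- c(files, f)
    }
  }
  files
}
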