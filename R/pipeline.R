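#' Validated pipeline configuration
#'
#' Collects everything a pipeline run needs — input table location, column
#' schema, measures, factor lists, window width, resampling settings, plateau
#' criteria, output directory and seed — validates it up front, and is
#' serialized (with its md5 digest) into every output file for provenance.
#' A configuration can also be read from a YAML file whose keys match the
#' arguments.
#'
#' @param input Path to the input CSV (see [read_behavior_table()]).
#' @param out_dir Output directory (created if missing).
#' @param measures Measures to analyze; `NULL` means all measures present.
#' @param random_factors Grouping factors for the multi-factor analysis.
#' @param window_factor Single grouping factor for the window scan.
#' @param fixed_factors Fixed covariates for the multi-factor analysis.
#' @param schema Optional column mapping, as in [read_behavior_table()].
#' @param window_width Sliding-window width in days.
#' @param n_boot,n_permut,seed Resampling settings.
#' @param rho_min,delta,require_ci_excludes_zero Plateau criteria for
#'   [recommend_start_day()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, out_dir, measures = NULL,
                       random_factors = c("animal_id", "strain", "experiment"),
                       window_factor = "animal_id",
                       fixed_factors = character(), schema = NULL,
                       window_width = 3L, n_boot = 500L, n_permut = 100L,
                       seed = 1L, rho_min = 0.4, delta = 0.15,
                       require_ci_excludes_zero = TRUE) {
  if (!is.character(input) || length(input) != 1L) {
    stop_habrep("usage_error", "input must be a single path")
  }
  if (!is_count(window_width, 2L)) {
    stop_habrep("usage_error", "window_width must be an integer >= 2")
  }
  settings <- resampling_settings(n_boot, n_permut, seed) # validates
  cfg <- list(input = input, out_dir = out_dir, measures = measures,
              random_factors = random_factors, window_factor = window_factor,
              fixed_factors = fixed_factors, schema = schema,
              window_width = as.integer(window_width),
              n_boot = settings$n_boot, n_permut = settings$n_permut,
              seed = settings$seed, rho_min = rho_min, delta = delta,
              require_ci_excludes_zero = isTRUE(require_ci_excludes_zero))
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @param ... Overrides taking precedence over the file's values.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop_habrep("usage_error", sprintf("config not found: %s", path))
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0L) {
    stop_habrep("usage_error",
      sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

config_stamp <- function(config) {
  list(config = unclass(config), config_digest = digest_object(unclass(config)),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("habrep")))
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

#' Simulate a dataset to files
#'
#' Writes a synthetic [behavior_table()] CSV plus its ground-truth JSON
#' sidecar, and prints summary counts. With `studylike = TRUE` (default) the
#' two-measure study-like scenario of [generate_studylike()] is drawn;
#' otherwise a [synthetic_config()] must be supplied.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param studylike Draw the calibrated study-like scenario.
#' @param config A [synthetic_config()] used when `studylike = FALSE`.
#' @param quiet Suppress the summary printout.
#' @return Invisibly, `list(csv, truth_json)` of the written paths.
#' @export
cmd_simulate <- function(out_dir, seed = 1L, studylike = TRUE, config = NULL,
                         quiet = FALSE) {
  ensure_dir(out_dir)
  if (studylike) {
    sim <- generate_studylike(seed)
    truth <- sim$truth
  } else {
    if (!inherits(config, "synthetic_config")) {
      stop_habrep("usage_error", "config must be a synthetic_config when studylike = FALSE")
    }
    one <- generate_habituation(config, seed = seed)
    sim <- list(table = one$table)
    truth <- one$truth
  }
  csv <- file.path(out_dir, "behavior_table.csv")
  write_behavior_table(sim$table, csv)
  tj <- file.path(out_dir, "ground_truth.json")
  payload <- if (inherits(truth, "ground_truth")) as_payload(truth) else
    lapply(truth, as_payload)
  jsonlite::write_json(list(schema_version = "1", seed = seed, truth = payload),
                       tj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet) {
    cat(sprintf("wrote %d records (%d animals x %d days, %d measure(s)) to %s\n",
                nrow(sim$table), length(unique(sim$table$animal_id)),
                length(unique(sim$table$day)),
                length(attr(sim$table, "measures")), csv))
  }
  invisible(list(csv = csv, truth_json = tj))
}

#' Multi-factor repeatability analysis to files
#'
#' Runs [rpt()] for every configured measure, writes one JSON result per
#' measure and factor plus a plain-text summary table (factor, R, CI, LRT p).
#'
#' @param config A [run_config()].
#' @param quiet Suppress console output.
#' @return Invisibly, the list of `rpt_results` per measure.
#' @export
cmd_rpt <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  tab <- read_behavior_table(config$input, config$schema)
  measures <- config$measures %||% attr(tab, "measures")
  ensure_dir(config$out_dir)
  stamp <- config_stamp(config)
  digest <- digest_file(config$input)
  settings <- resampling_settings(config$n_boot, config$n_permut, config$seed)
  txt <- file.path(config$out_dir, "repeatability_table.txt")
  con <- file(txt, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# repeatability analysis  (config %s, seed %d)",
                     stamp$config_digest, config$seed), con)
  writeLines(sprintf("%-14s %-12s %8s %18s %12s", "measure", "factor", "R",
                     "CI[2.5,97.5]%", "p(LRT)"), con)
  all_res <- list()
  for (m in measures) {
    res <- rpt(tab, m, config$random_factors, config$fixed_factors, settings)
    all_res[[m]] <- res
    for (r in res) {
      path <- file.path(config$out_dir,
                        sprintf("rpt_%s_%s.json", gsub("[^A-Za-z0-9]", "_", m),
                                gsub("[^A-Za-z0-9]", "_", r$factor)))
      write_results(r, path, input_digest = digest)
      writeLines(sprintf("%-14s %-12s %8.4f  [%6.4f, %6.4f] %12.3g",
                         m, r$factor, r$R, r$ci_low, r$ci_high, r$p_lrt), con)
    }
    if (!quiet) print(res)
  }
  invisible(all_res)
}

#' Window scan to files
#'
#' Runs [window_repeatability()] for every configured measure and writes the
#' per-window series as CSV and JSON.
#'
#' @inheritParams cmd_rpt
#' @return Invisibly, the list of `window_series` per measure.
#' @export
cmd_windows <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  tab <- read_behavior_table(config$input, config$schema)
  measures <- config$measures %||% attr(tab, "measures")
  ensure_dir(config$out_dir)
  digest <- digest_file(config$input)
  settings <- resampling_settings(config$n_boot, config$n_permut, config$seed)
  series <- lapply(measures, function(m) {
    ws <- window_repeatability(tab, m, config$window_factor,
                               width = config$window_width, settings = settings)
    stem <- file.path(config$out_dir,
                      sprintf("windows_%s", gsub("[^A-Za-z0-9]", "_", m)))
    write_window_series(ws, paste0(stem, ".csv"))
    write_results(ws, paste0(stem, ".json"), input_digest = digest)
    if (!quiet) print(ws)
    ws
  })
  names(series) <- measures
  invisible(series)
}

#' Full habituation pipeline to files
#'
#' Runs the window scan for every measure, applies the plateau criteria of
#' [recommend_start_day()], and writes the window series (CSV + JSON), the
#' habituation report (JSON) and a human-readable summary.
#'
#' @inheritParams cmd_rpt
#' @return Invisibly, the `habituation_report`.
#' @export
cmd_habituation <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  series <- cmd_windows(config, quiet = TRUE)
  report <- recommend_start_day(series, rho_min = config$rho_min,
                                delta = config$delta,
                                require_ci_excludes_zero = config$require_ci_excludes_zero)
  stamp <- config_stamp(config)
  rj <- file.path(config$out_dir, "habituation_report.json")
  doc <- c(as_payload(report), stamp)
  jsonlite::write_json(doc, rj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  summary_txt <- file.path(config$out_dir, "habituation_summary.txt")
  sink(summary_txt)
  print(report)
  sink()
  if (!quiet) print(report)
  invisible(report)
}
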