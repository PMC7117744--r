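#' Serialize analysis results to JSON
#'
#' Writes any of the package's result objects (repeatability results, window
#' series, habituation reports, ground truth, plain lists) to a JSON document
#' carrying a schema version, the package version, optional seed and input
#' digest, and all numeric content at full double precision. Model-fit
#' references inside results are reduced to their numeric summaries (variance
#' components, log-likelihood); the fitted data themselves are not embedded.
#'
#' @param x Result object to serialize.
#' @param path Output path.
#' @param input_digest Optional digest (e.g. [tools::md5sum()] of the input
#'   file) recorded for provenance.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(x, path, input_digest = NULL) {
  doc <- list(
    schema_version = "1",
    package = "habrep",
    package_version = as.character(utils::packageVersion("habrep")),
    type = class(x)[1L],
    input_digest = input_digest,
    payload = as_payload(x)
  )
  ok <- tryCatch({
    # I(17) significant digits: doubles survive the round-trip bit-exactly
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", pretty = TRUE, force = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_habrep("io_error", sprintf("cannot write results to %s: %s",
                                    path, conditionMessage(ok)))
  }
  invisible(path)
}

#' Read back a JSON results document
#'
#' Inverse of [write_results()]: returns the payload with its recorded class
#' restored, so that `read_results(write_results(x, p))` reproduces the
#' serializable content of `x` exactly (doubles survive round-trip at full
#' precision).
#'
#' @param path Path written by [write_results()].
#' @return The deserialized payload.
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  payload <- doc$payload
  if (!is.null(doc$type) && is.list(payload)) {
    class(payload) <- c(doc$type, "list")
  }
  payload
}

# payload converters: plain, JSON-safe representations of result objects
as_payload <- function(x) UseMethod("as_payload")

#' @export
as_payload.default <- function(x) x

#' @export
as_payload.repeatability_result <- function(x) {
  list(
    factor = x$factor, R = x$R, ci_low = x$ci_low, ci_high = x$ci_high,
    p_lrt = x$p_lrt, p_permut = x$p_permut, lrt_statistic = x$lrt_statistic,
    n_boot = x$n_boot, n_permut = x$n_permut, n_boot_failed = x$n_boot_failed,
    seed = x$seed,
    variance_components = as.list(x$fit$sigma2),
    residual_variance = x$fit$sigma2_resid,
    loglik = x$fit$loglik
  )
}

#' @export
as_payload.window_series <- function(x) {
  list(
    measure = x$measure, factor = x$factor, width = x$width, seed = x$seed,
    windows = lapply(seq_len(nrow(x$table)), function(i) as.list(x$table[i, ]))
  )
}

#' @export
as_payload.habituation_report <- function(x) {
  unclass(x)
}

#' @export
as_payload.ground_truth <- function(x) {
  list(
    R_star = x$R_star, R_single = x$R_single,
    animal_effects = as.list(x$animal_effects),
    strain_effects = as.list(x$strain_effects),
    batch_effects = as.list(x$batch_effects),
    config = x$config[setdiff(names(x$config), "n_per_strain")] |>
      c(list(n_per_strain = as.list(x$config$n_per_strain)))
  )
}

#' Export a window series as CSV
#'
#' One row per window with columns `measure`, `factor`, `start_day`, `end_day`,
#' `R`, `ci_low`, `ci_high`, `p_lrt`, `p_permut`, suitable for external
#' plotting.
#'
#' @param x A `window_series` from [window_repeatability()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_window_series <- function(x, path) {
  stopifnot(inherits(x, "window_series"))
  df <- data.frame(measure = x$measure, factor = x$factor, x$table,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
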