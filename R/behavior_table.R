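#' Long-format behavioral measurement tables
#'
#' A `behavior_table` holds repeated-measures behavioral data in long format:
#' one row per animal, trial day and measure. It is the common input container
#' for all model fitting in the package. Construction validates the structural
#' invariants the downstream mixed models rely on:
#'
#' * `day` is a positive integer (1-based trial day) and `value` is finite;
#' * `(animal_id, day, measure)` is unique;
#' * every `animal_id` maps to exactly one `strain` and one `experiment`.
#'
#' Unbalanced designs (animals missing days) are allowed; use
#' [completeness_map()] to see which animal/day cells are present.
#'
#' @param data A data.frame with columns `animal_id`, `strain`, `experiment`,
#'   `day`, `measure`, `value` (additional columns are dropped).
#' @return An object of class `behavior_table` (a validated data.frame).
#' @seealso [read_behavior_table()], [completeness_map()]
#' @examples
#' tab <- behavior_table(data.frame(
#'   animal_id = rep(c("m1", "m2"), each = 3),
#'   strain = "C57BL/6J", experiment = "exp1",
#'   day = rep(1:3, 2), measure = "distance_cm",
#'   value = c(900, 420, 380, 950, 460, 400)
#' ))
#' summary(tab)
#' @export
behavior_table <- function(data) {
  required <- c("animal_id", "strain", "experiment", "day", "measure", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop_habrep("schema_error",
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- data.frame(
    animal_id = as.character(data$animal_id),
    strain = as.character(data$strain),
    experiment = as.character(data$experiment),
    day = data$day,
    measure = as.character(data$measure),
    value = data$value,
    stringsAsFactors = FALSE
  )

  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(df$value)))))
    stop_habrep("parse_error",
      sprintf("non-numeric value(s) in row(s): %s", paste(utils::head(bad, 10L), collapse = ", ")),
      data = list(rows = bad))
  }
  bad_value <- which(!is.finite(df$value))
  if (length(bad_value) > 0L) {
    stop_habrep("parse_error",
      sprintf("non-finite value(s) in row(s): %s", paste(utils::head(bad_value, 10L), collapse = ", ")),
      data = list(rows = bad_value))
  }
  if (!is.numeric(df$day) || any(!is.finite(df$day)) || any(df$day < 1) ||
      any(df$day != round(df$day))) {
    bad <- which(!is.finite(df$day) | df$day < 1 | df$day != round(df$day))
    stop_habrep("parse_error",
      sprintf("day must be a positive integer; bad row(s): %s",
              paste(utils::head(bad, 10L), collapse = ", ")),
      data = list(rows = bad))
  }
  df$day <- as.integer(df$day)

  key <- paste(df$animal_id, df$day, df$measure, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop_habrep("integrity_error",
      sprintf("duplicate (animal_id, day, measure) in row(s): %s",
              paste(utils::head(dup, 10L), collapse = ", ")),
      data = list(rows = dup))
  }

  for (col in c("strain", "experiment")) {
    m <- unique(df[, c("animal_id", col)])
    multi <- unique(m$animal_id[duplicated(m$animal_id)])
    if (length(multi) > 0L) {
      stop_habrep("integrity_error",
        sprintf("animal(s) mapped to more than one %s: %s",
                col, paste(utils::head(multi, 10L), collapse = ", ")),
        data = list(animals = multi, column = col))
    }
  }

  structure(df,
    class = c("behavior_table", "data.frame"),
    measures = sort(unique(df$measure)))
}

#' Read a behavioral table from CSV
#'
#' Reads a UTF-8 CSV file with a header row and validates it into a
#' [behavior_table()]. Column names can be remapped through `schema` so that
#' files using other headers (e.g. an exported supplementary table) can be
#' ingested without editing.
#'
#' @param path Path to a CSV file.
#' @param schema Named list mapping the canonical names `animal_id`, `strain`,
#'   `experiment`, `day`, `measure`, `value` to the column names found in the
#'   file. Defaults to the identity mapping.
#' @return A validated [behavior_table()].
#' @export
read_behavior_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop_habrep("schema_error", sprintf("file not found: %s", path))
  }
  canonical <- c("animal_id", "strain", "experiment", "day", "measure", "value")
  map <- stats::setNames(as.list(canonical), canonical)
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), canonical)
    if (length(unknown) > 0L) {
      stop_habrep("schema_error",
        sprintf("unknown schema key(s): %s", paste(unknown, collapse = ", ")))
    }
    map[names(schema)] <- schema
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         encoding = "UTF-8")
  src <- unlist(map)
  missing_cols <- setdiff(src, names(raw))
  if (length(missing_cols) > 0L) {
    stop_habrep("schema_error",
      sprintf("column(s) not found in %s: %s", path, paste(missing_cols, collapse = ", ")))
  }
  df <- raw[, src]
  names(df) <- canonical
  if (is.character(df$value)) {
    num <- suppressWarnings(as.numeric(df$value))
    bad <- which(is.na(num) & !is.na(df$value) & nzchar(df$value))
    if (length(bad) > 0L) {
      stop_habrep("parse_error",
        sprintf("non-numeric value(s) in data row(s): %s (file %s)",
                paste(utils::head(bad, 10L), collapse = ", "), path),
        data = list(rows = bad))
    }
    df$value <- num
  }
  behavior_table(df)
}

#' Write a behavioral table to CSV
#'
#' @param x A [behavior_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_behavior_table <- function(x, path) {
  stopifnot(inherits(x, "behavior_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-animal completeness of the day grid
#'
#' Reports, per animal and measure, which trial days are present. The design is
#' flagged unbalanced when animals differ in their observed day sets for a
#' measure. Missing cells are allowed throughout the package (no imputation);
#' this map makes them visible.
#'
#' @param x A [behavior_table()].
#' @return A data.frame with columns `animal_id`, `measure`, `n_days`, `days`
#'   (comma-separated) and attribute `balanced` (logical).
#' @export
completeness_map <- function(x) {
  stopifnot(inherits(x, "behavior_table"))
  sp <- split(x$day, list(animal_id = x$animal_id, measure = x$measure), drop = TRUE)
  keys <- strsplit(names(sp), ".", fixed = TRUE)
  out <- data.frame(
    animal_id = vapply(keys, `[`, "", 1L),
    measure = vapply(keys, `[`, "", 2L),
    n_days = vapply(sp, length, 0L),
    days = vapply(sp, function(d) paste(sort(d), collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  balanced <- all(vapply(split(out$days, out$measure),
                         function(d) length(unique(d)) == 1L, TRUE))
  attr(out, "balanced") <- balanced
  out
}

#' @export
summary.behavior_table <- function(object, ...) {
  cm <- completeness_map(object)
  cat("behavior_table:", length(unique(object$animal_id)), "animals,",
      nrow(object), "records\n")
  cat("  measures:", paste(attr(object, "measures"), collapse = ", "), "\n")
  cat("  strains:", paste(sort(unique(object$strain)), collapse = ", "), "\n")
  cat("  experiments:", paste(sort(unique(object$experiment)), collapse = ", "), "\n")
  cat("  days:", paste(sort(unique(object$day)), collapse = ", "), "\n")
  cat("  design:", if (attr(cm, "balanced")) "balanced" else "unbalanced", "\n")
  invisible(object)
}

# subset a table to one measure (and optionally a day window), returning the
# plain analysis frame used by the fitting code
measure_frame <- function(table, response, days = NULL) {
  stopifnot(inherits(table, "behavior_table"))
  if (!response %in% attr(table, "measures")) {
    stop_habrep("schema_error",
      sprintf("measure '%s' not present (have: %s)", response,
              paste(attr(table, "measures"), collapse = ", ")))
  }
  df <- as.data.frame(table[table$measure == response, , drop = FALSE])
  if (!is.null(days)) df <- df[df$day %in% days, , drop = FALSE]
  rownames(df) <- NULL
  df
}
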