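#' Sliding windows of adjacent trial days
#'
#' Enumerates all maximal-overlap windows of `width` consecutive observed
#' days. With 7 daily trials and the default width of 3 this yields the five
#' windows 1-3, 2-4, 3-5, 4-6, 5-7. Windows that would span a gap in the
#' observed day grid are excluded and reported via the `excluded` attribute.
#'
#' @param days Integer vector of observed trial days (need not be sorted).
#' @param width Window width in days (>= 2).
#' @return A data.frame with columns `start_day`, `end_day`, `width`, one row
#'   per window, ordered by `start_day`; attribute `excluded` counts windows
#'   dropped because of day gaps.
#' @examples
#' sliding_windows(1:7, 3)
#' @export
sliding_windows <- function(days, width = 3L) {
  if (!is_count(width, min = 2L)) {
    stop_habrep("config_error", "width must be an integer >= 2")
  }
  width <- as.integer(width)
  days <- sort(unique(as.integer(days)))
  if (width > length(days)) {
    stop_habrep("config_error",
      sprintf("width %d exceeds the %d available days", width, length(days)))
  }
  starts <- days[seq_len(length(days) - width + 1L)]
  keep <- vapply(starts, function(s) all((s:(s + width - 1L)) %in% days), TRUE)
  out <- data.frame(start_day = starts[keep],
                    end_day = starts[keep] + width - 1L,
                    width = width)
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Repeatability across sliding day windows
#'
#' Computes the single-factor repeatability (with bootstrap CI, permutation
#' p-value and likelihood-ratio test) on every sliding window of adjacent
#' days. Each window uses the same resampling settings; the per-window seed is
#' the base seed plus the window index, so windows resample independently but
#' reproducibly. Windows whose fit fails are recorded with `NA` estimates and
#' the series is still returned.
#'
#' @param table A [behavior_table()].
#' @param response Measure name.
#' @param factor The single random grouping factor for the window fits
#'   (windows deliberately use one factor, not the full multi-factor model).
#' @param width Window width in days.
#' @param settings A [resampling_settings()].
#' @param fixed_factors Optional fixed covariates (used for adjusted window
#'   series, e.g. animal repeatability adjusted for strain).
#' @return An object of class `window_series`: list with `measure`, `factor`,
#'   `width`, `seed`, a per-window summary `table` (columns `start_day`,
#'   `end_day`, `R`, `ci_low`, `ci_high`, `p_lrt`, `p_permut`, `failed`) and
#'   the full per-window `results`.
#' @export
window_repeatability <- function(table, response, factor, width = 3L,
                                 settings = resampling_settings(),
                                 fixed_factors = character()) {
  stopifnot(inherits(table, "behavior_table"))
  days <- sort(unique(table$day[table$measure == response]))
  win <- sliding_windows(days, width)
  results <- vector("list", nrow(win))
  rows <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    wdays <- win$start_day[i]:win$end_day[i]
    s_i <- settings
    s_i$seed <- settings$seed + i
    res <- tryCatch({
      spec <- model_spec(response, factor, fixed_factors)
      fit <- fit_vc_lmm(table, spec, days = wdays)
      sub <- subset_days(table, wdays)
      repeatability_result(sub, fit, factor, s_i)
    }, habrep_error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(start_day = win$start_day[i],
                              end_day = win$end_day[i],
                              R = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                              p_lrt = NA_real_, p_permut = NA_real_, failed = TRUE)
      results[[i]] <- res
    } else {
      rows[[i]] <- data.frame(start_day = win$start_day[i],
                              end_day = win$end_day[i],
                              R = res$R, ci_low = res$ci_low, ci_high = res$ci_high,
                              p_lrt = res$p_lrt, p_permut = res$p_permut,
                              failed = FALSE)
      results[[i]] <- res
    }
  }
  structure(list(measure = response, factor = factor, width = as.integer(width),
                 seed = settings$seed, table = do.call(rbind, rows),
                 results = results),
            class = "window_series")
}

#' @export
print.window_series <- function(x, ...) {
  cat(sprintf("Window repeatability: measure '%s', random factor '%s', width %d\n",
              x$measure, x$factor, x$width))
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

# day subset as a fresh validated behavior_table
subset_days <- function(table, days) {
  behavior_table(as.data.frame(table)[table$day %in% days, , drop = FALSE])
}

#' Recommend a habituation length from window series
#'
#' Converts one window-repeatability series per measure into a habituation
#' recommendation. A window `w` is STABLE when (i) `R_w >= rho_min`, (ii) its
#' bootstrap CI excludes zero (if `require_ci_excludes_zero`), and (iii) the
#' series stays within `delta` of `R_w` over all later windows
#' (`|R_w - R_v| <= delta`). For the earliest stable window:
#' `first_repeatable_day` is its start day, `minimum_habituation_days` is
#' `start - 1` (days before individual differences are measurable), and
#' `recommended_habituation_days` is `start + width - 2` (test on the
#' window's last day, habituate on all days before it). If no window
#' qualifies the measure gets `NA`s and the report's `extend_habituation`
#' flag is set. The overall recommendation is the maximum across measures.
#'
#' @param series A `window_series` or a list of them (one per measure).
#' @param rho_min Minimum repeatability for a window to count as stable.
#' @param delta Maximum allowed drift of R across all later windows.
#' @param require_ci_excludes_zero Require `ci_low > 0` for the stable window.
#' @return An object of class `habituation_report`.
#' @examples
#' tab <- generate_habituation(studylike_scenario(), seed = 1)$table
#' ws <- window_repeatability(tab, "distance_cm", "animal_id",
#'   settings = resampling_settings(n_boot = 50, n_permut = 10, seed = 1))
#' recommend_start_day(ws)
#' @export
recommend_start_day <- function(series, rho_min = 0.4, delta = 0.15,
                                require_ci_excludes_zero = TRUE) {
  if (inherits(series, "window_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, TRUE, "window_series")))
  per_measure <- lapply(series, function(ws) {
    if (nrow(ws$table) < 2L) {
      stop_habrep("config_error", "need at least 2 windows per series")
    }
    tab <- ws$table
    stable <- NA_integer_
    for (i in seq_len(nrow(tab))) {
      if (tab$failed[i] || is.na(tab$R[i])) next
      if (tab$R[i] < rho_min) next
      if (require_ci_excludes_zero && !(tab$ci_low[i] > 0)) next
      later <- tab$R[seq_len(nrow(tab)) > i]
      if (any(is.na(later)) || any(abs(tab$R[i] - later) > delta)) next
      stable <- i
      break
    }
    if (is.na(stable)) {
      list(measure = ws$measure, first_repeatable_day = NA_integer_,
           minimum_habituation_days = NA_integer_,
           recommended_habituation_days = NA_integer_)
    } else {
      start <- tab$start_day[stable]
      list(measure = ws$measure,
           first_repeatable_day = as.integer(start),
           minimum_habituation_days = as.integer(start - 1L),
           recommended_habituation_days = as.integer(start + ws$width - 2L))
    }
  })
  names(per_measure) <- vapply(series, `[[`, "", "measure")
  rec <- vapply(per_measure, function(m) as.integer(m$recommended_habituation_days), 1L)
  extend <- any(is.na(rec))
  structure(list(
    per_measure = per_measure,
    criteria = list(rho_min = rho_min, delta = delta,
                    require_ci_excludes_zero = require_ci_excludes_zero),
    recommended_habituation_days = if (extend) NA_integer_ else max(rec),
    extend_habituation = extend
  ), class = "habituation_report")
}

#' @export
print.habituation_report <- function(x, ...) {
  cat("Habituation recommendation\n")
  cat(sprintf("  criteria: R >= %.2f, drift <= %.2f, CI excludes 0: %s\n",
              x$criteria$rho_min, x$criteria$delta,
              x$criteria$require_ci_excludes_zero))
  for (m in x$per_measure) {
    if (is.na(m$recommended_habituation_days)) {
      cat(sprintf("  %s: no stable window found -- extend habituation\n", m$measure))
    } else {
      cat(sprintf("  %s: first repeatable day %d, minimum %d day(s), recommended %d day(s)\n",
                  m$measure, m$first_repeatable_day, m$minimum_habituation_days,
                  m$recommended_habituation_days))
    }
  }
  if (x$extend_habituation) {
    cat("  overall: extend the habituation period and re-analyze\n")
  } else {
    cat(sprintf("  overall: habituate for %d day(s) before testing\n",
                x$recommended_habituation_days))
  }
  invisible(x)
}
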