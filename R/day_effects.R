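#' Friedman test with Dunn's comparisons against a control day
#'
#' Nonparametric day-effect screen on the complete-case animal x day grid:
#' values are mid-ranked within each animal, the tie-corrected Friedman
#' statistic is referred to chi-square on `k - 1` df, and each non-control day
#' is compared to the control day with Dunn's many-to-one z statistic
#' `z_d = |Rbar_ctrl - Rbar_d| / sqrt(k (k + 1) / (6 n))`, the two-sided
#' normal p-value Bonferroni-multiplied by `k - 1` (capped at 1). Animals
#' missing any day are dropped and counted (`n_dropped` attribute).
#'
#' For small complete designs `exact = TRUE` enumerates every within-animal
#' ordering ((k!)^n arrangements, guarded at 500000) and returns the exact
#' permutation p-value of the Friedman statistic instead of the chi-square
#' approximation.
#'
#' @param table A [behavior_table()].
#' @param response Measure name.
#' @param control_day Day the others are compared against (default 1).
#' @param exact Use exhaustive within-animal permutation for the global p.
#' @return An object of class `friedman_result`: `statistic`, `df`, `p`,
#'   `method`, and a `comparisons` data.frame (`day`, `z`, `p_unadjusted`,
#'   `p_adjusted`).
#' @export
friedman_dunn <- function(table, response, control_day = 1L, exact = FALSE) {
  df <- measure_frame(table, response)
  wide <- stats::xtabs(value ~ animal_id + day, data = df,
                       subset = NULL, sparse = FALSE)
  present <- stats::xtabs(~ animal_id + day, data = df) > 0
  complete <- rowSums(present) == ncol(present)
  n_dropped <- sum(!complete)
  Y <- as.matrix(wide)[complete, , drop = FALSE]
  k <- ncol(Y)
  n <- nrow(Y)
  days <- as.integer(colnames(wide))
  if (k < 3L) stop_habrep("config_error", "Friedman test needs at least 3 days")
  if (n < 2L) stop_habrep("degenerate_data_error",
                          "need at least 2 animals with complete day series")
  if (!control_day %in% days) {
    stop_habrep("config_error", sprintf("control day %d not observed", control_day))
  }

  ranks <- t(apply(Y, 1L, rank)) # mid-ranks within animal
  stat_fun <- function(r) {
    colsum <- colSums(r)
    num <- (k - 1) * sum((colsum - n * (k + 1) / 2)^2)
    den <- sum(r^2) - n * k * (k + 1)^2 / 4
    if (den <= 0) 0 else num / den # den = 0 iff all ranks tie everywhere
  }
  Q <- stat_fun(ranks)

  if (exact) {
    n_arr <- factorial(k)^n
    if (n_arr > 5e5) {
      stop_habrep("settings_error",
        sprintf("exact enumeration infeasible: (k!)^n = %g arrangements", n_arr))
    }
    perms <- all_permutations(k)
    idx <- rep(1L, n)
    count <- 0L
    total <- 0L
    repeat {
      r <- ranks
      for (i in seq_len(n)) r[i, ] <- ranks[i, perms[[idx[i]]]]
      total <- total + 1L
      if (stat_fun(r) >= Q - 1e-12) count <- count + 1L
      j <- 1L
      while (j <= n) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= length(perms)) break
        idx[j] <- 1L
        j <- j + 1L
      }
      if (j > n) break
    }
    p <- count / total
    method <- "exact permutation"
  } else {
    p <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
    method <- "chi-square approximation"
  }

  rbar <- colMeans(ranks)
  ctrl <- match(control_day, days)
  se <- sqrt(k * (k + 1) / (6 * n))
  comp_days <- days[-ctrl]
  z <- abs(rbar[ctrl] - rbar[-ctrl]) / se
  p_un <- 2 * stats::pnorm(-z)
  p_adj <- pmin(1, (k - 1) * p_un)
  comparisons <- data.frame(day = comp_days, z = unname(z),
                            p_unadjusted = unname(p_un),
                            p_adjusted = unname(p_adj))
  structure(list(statistic = Q, df = k - 1L, p = max(p, .Machine$double.xmin),
                 method = method, n = n, control_day = as.integer(control_day),
                 comparisons = comparisons),
            class = "friedman_result", n_dropped = n_dropped)
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman test (%s): Q = %.4f, df = %d, p = %.4g (n = %d animals)\n",
              x$method, x$statistic, x$df, x$p, x$n))
  cat(sprintf("Dunn's comparisons vs day %d (Bonferroni-adjusted):\n", x$control_day))
  print(x$comparisons, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Per-day mean with normal-theory confidence interval
#'
#' Descriptive summary of a measure's central trend across habituation days:
#' per day, the sample mean and a two-sided 95% (2.5%/97.5%) t-based interval
#' `mean +/- t(0.975, n - 1) * sd / sqrt(n)`. With constant values the
#' interval collapses to a point.
#'
#' @param table A [behavior_table()].
#' @param response Measure name.
#' @param level Two-sided confidence level (default 0.95).
#' @return A data.frame with columns `day`, `n`, `mean`, `ci_low`, `ci_high`.
#' @export
day_summary <- function(table, response, level = 0.95) {
  df <- measure_frame(table, response)
  sp <- split(df$value, df$day)
  if (any(vapply(sp, length, 0L) < 2L)) {
    stop_habrep("degenerate_data_error", "need >= 2 observations per day")
  }
  out <- do.call(rbind, lapply(names(sp), function(d) {
    v <- sp[[d]]
    n <- length(v)
    m <- mean(v)
    half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(v) / sqrt(n)
    data.frame(day = as.integer(d), n = n, mean = m,
               ci_low = m - half, ci_high = m + half)
  }))
  out[order(out$day), , drop = FALSE]
}

#' Normal quantile-quantile diagnostic
#'
#' Pairs the ordered sample with standard-normal quantiles at plotting
#' positions `(i - 0.5) / n` and reports the quantile-pair correlation as a
#' single normality diagnostic (1 means the empirical quantiles are an exact
#' affine image of the normal ones).
#'
#' @param values Numeric vector (length >= 3).
#' @return List with `theoretical`, `sample` (both ordered) and `correlation`.
#' @export
normality_qq <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop_habrep("degenerate_data_error", "need at least 3 values")
  theo <- stats::qnorm((seq_len(n) - 0.5) / n)
  samp <- sort(values)
  list(theoretical = theo, sample = samp,
       correlation = stats::cor(theo, samp))
}
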