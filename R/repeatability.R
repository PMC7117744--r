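#' Resampling settings for repeatability inference
#'
#' Bundles the bootstrap/permutation sizes, the random seed, and the CI
#' quantile pair used throughout repeatability inference. Defaults are 500
#' parametric-bootstrap runs, 100 permutations, and a central 95% interval
#' (2.5% and 97.5% empirical percentiles).
#'
#' @param n_boot Number of parametric bootstrap replicates (>= 1).
#' @param n_permut Number of permutations, the observed arrangement counted as
#'   one of them (>= 1; the permutation test itself requires >= 2).
#' @param seed Integer seed; all resampling is reproducible given the seed.
#' @param ci_quantiles Strictly increasing pair of probabilities in (0, 1).
#' @return An object of class `resampling_settings`.
#' @export
resampling_settings <- function(n_boot = 500L, n_permut = 100L, seed = 1L,
                                ci_quantiles = c(0.025, 0.975)) {
  if (!is_count(n_boot)) stop_habrep("settings_error", "n_boot must be a positive integer")
  if (!is_count(n_permut)) stop_habrep("settings_error", "n_permut must be a positive integer")
  if (!is_count(abs(seed), min = 0L)) stop_habrep("settings_error", "seed must be an integer")
  if (length(ci_quantiles) != 2L || any(ci_quantiles <= 0) ||
      any(ci_quantiles >= 1) || diff(ci_quantiles) <= 0) {
    stop_habrep("settings_error", "ci_quantiles must be an increasing pair in (0, 1)")
  }
  structure(list(n_boot = as.integer(n_boot), n_permut = as.integer(n_permut),
                 seed = as.integer(seed), ci_quantiles = as.numeric(ci_quantiles)),
            class = "resampling_settings")
}

#' Agreement repeatability of one grouping factor
#'
#' The repeatability (intraclass correlation) of grouping factor `g` is the
#' share of variance it explains among the random components:
#' `R_g = sigma2_g / (sum_h sigma2_h + sigma2_eps)`. Fixed-effect variance is
#' excluded from the denominator (agreement repeatability), so adding
#' covariates to the fixed part adjusts R rather than diluting it.
#'
#' @param fit An `lmm_fit` from [fit_vc_lmm()].
#' @param factor Name of one of the fit's random factors.
#' @return The point estimate, a number in `[0, 1]`.
#' @export
point_repeatability <- function(fit, factor) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!factor %in% names(fit$sigma2)) {
    stop_habrep("spec_error",
      sprintf("'%s' is not a random factor of this fit (have: %s)",
              factor, paste(names(fit$sigma2), collapse = ", ")))
  }
  unname(fit$sigma2[[factor]] / (sum(fit$sigma2) + fit$sigma2_resid))
}

#' Parametric-bootstrap confidence interval for repeatability
#'
#' Simulates `n_boot` response vectors from the fitted model
#' ([simulate_from_fit()]), refits each (warm-started at the original
#' optimum), recomputes `R`, and returns the empirical percentile interval at
#' the settings' quantiles (linear interpolation between order statistics).
#' Replicates whose refit fails are dropped and counted; a warning condition
#' is attached when more than 10% fail.
#'
#' @param table A [behavior_table()].
#' @param spec A [model_spec()].
#' @param factor Random factor whose repeatability is resampled.
#' @param settings A [resampling_settings()].
#' @return Numeric `c(low, high)` with attributes `n_failed` and `R_boot`
#'   (the bootstrap replicates).
#' @export
bootstrap_ci <- function(table, spec, factor, settings = resampling_settings()) {
  fit <- fit_vc_lmm(table, spec)
  bootstrap_ci_fit(fit, factor, settings)
}

# bootstrap from an existing fit (lets callers avoid a duplicate base fit)
bootstrap_ci_fit <- function(fit, factor, settings) {
  sims <- simulate_from_fit(fit, nsim = settings$n_boot, seed = settings$seed)
  if (settings$n_boot == 1L) sims <- matrix(sims, ncol = 1L)
  Rb <- rep(NA_real_, settings$n_boot)
  for (b in seq_len(settings$n_boot)) {
    Rb[b] <- tryCatch(
      point_repeatability(refit_response(fit, sims[, b]), factor),
      habrep_error = function(e) NA_real_)
  }
  failed <- sum(is.na(Rb))
  if (failed > 0.1 * settings$n_boot) {
    warn_habrep("inference_warning",
      sprintf("%d of %d bootstrap replicates failed to converge",
              failed, settings$n_boot))
  }
  ci <- stats::quantile(Rb, probs = settings$ci_quantiles, na.rm = TRUE,
                        names = FALSE)
  structure(ci, n_failed = failed, R_boot = Rb)
}

#' Permutation test for a random factor's repeatability
#'
#' Builds the null distribution by removing the focal factor from the model,
#' fitting the reduced model (any other random factors are retained and their
#' predicted values, including BLUPs, stay in the fitted part), permuting the
#' reduced-model residuals uniformly at random, adding them back to the fitted
#' values, refitting the full model and recomputing `R`. The observed
#' arrangement is counted as one permutation, so
#' `p = (1 + #\{R* >= R_hat\}) / n_permut` and the smallest attainable p is
#' `1 / n_permut`.
#'
#' With `exact = TRUE` all `n!` residual permutations are enumerated instead
#' (feasible for `n <= 8`) and `p = #\{R* >= R_hat\} / n!`, the identity
#' permutation supplying the observed value.
#'
#' @inheritParams bootstrap_ci
#' @param exact Enumerate all permutations instead of sampling.
#' @return The p-value, with attributes `R_perm` and `n_permut`.
#' @export
permutation_test <- function(table, spec, factor,
                             settings = resampling_settings(), exact = FALSE) {
  if (!exact && settings$n_permut < 2L) {
    stop_habrep("settings_error", "permutation test needs n_permut >= 2")
  }
  fit <- fit_vc_lmm(table, spec)
  permutation_test_fit(table, fit, factor, settings, exact)
}

permutation_test_fit <- function(table, fit, factor, settings, exact = FALSE) {
  spec <- fit$spec
  if (!factor %in% spec$random_factors) {
    stop_habrep("spec_error", sprintf("'%s' is not a random factor", factor))
  }
  R_hat <- point_repeatability(fit, factor)
  n <- fit$n
  other <- setdiff(spec$random_factors, factor)
  if (length(other) > 0L) {
    red_spec <- model_spec(spec$response, other, spec$fixed_factors, spec$estimation)
    red_fit <- fit_vc_lmm(table, red_spec, days = fit$days)
    fitted0 <- conditional_fitted(red_fit)
  } else {
    d <- fit$design
    beta_ols <- solve(d$XtX, d$Xty)
    fitted0 <- drop(d$X %*% beta_ols)
  }
  resid0 <- fit$design$y - fitted0
  # refits of the reconstructed response carry optimizer noise of ~1e-9;
  # ties with the observed value must still count as exceedances
  tol <- 1e-8
  perm_R <- function(idx) {
    tryCatch(
      point_repeatability(refit_response(fit, fitted0 + resid0[idx]), factor),
      habrep_error = function(e) NA_real_)
  }
  if (exact) {
    if (n > 8L) {
      stop_habrep("settings_error",
        "exact enumeration is limited to n <= 8 observations")
    }
    perms <- all_permutations(n)
    Rp <- vapply(perms, perm_R, numeric(1))
    # observed value through the identical numerical path (identity perm)
    R_obs <- perm_R(seq_len(n))
    p <- sum(Rp >= R_obs - tol, na.rm = TRUE) / length(perms)
    return(structure(p, R_perm = Rp, n_permut = length(perms), exact = TRUE))
  }
  Rp <- withr::with_seed(settings$seed, {
    vapply(seq_len(settings$n_permut - 1L),
           function(i) perm_R(sample.int(n)), numeric(1))
  })
  p <- (1 + sum(Rp >= R_hat - tol, na.rm = TRUE)) / settings$n_permut
  structure(p, R_perm = Rp, n_permut = settings$n_permut, exact = FALSE)
}

#' Boundary-corrected likelihood-ratio test for a variance component
#'
#' Tests `sigma2_factor = 0` by comparing the restricted log-likelihoods of
#' the full model and the model with the focal factor removed (identical fixed
#' effects). Because the null value lies on the boundary of the parameter
#' space, the statistic's null distribution is the equal mixture of a point
#' mass at zero and chi-square with 1 df, so the p-value is half the
#' chi-square tail probability (and 0.5 exactly when the statistic is 0).
#' P-values are floored at the smallest positive double rather than reported
#' as zero.
#'
#' @inheritParams bootstrap_ci
#' @return `list(statistic, p)`.
#' @export
lrt <- function(table, spec, factor) {
  fit <- fit_vc_lmm(table, spec)
  lrt_fit(table, fit, factor)
}

lrt_fit <- function(table, fit, factor) {
  spec <- fit$spec
  if (!factor %in% spec$random_factors) {
    stop_habrep("spec_error", sprintf("'%s' is not a random factor", factor))
  }
  other <- setdiff(spec$random_factors, factor)
  ll_red <- if (length(other) > 0L) {
    red_spec <- model_spec(spec$response, other, spec$fixed_factors, spec$estimation)
    fit_vc_lmm(table, red_spec, days = fit$days)$loglik
  } else {
    fixed_only_loglik(fit)
  }
  statistic <- max(0, 2 * (fit$loglik - ll_red))
  p <- 0.5 * stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  p <- max(p, .Machine$double.xmin)
  list(statistic = statistic, p = p)
}

# assemble a full inference result for one factor from a base fit
repeatability_result <- function(table, fit, factor, settings) {
  R <- point_repeatability(fit, factor)
  ci <- bootstrap_ci_fit(fit, factor, settings)
  perm_settings <- settings
  perm_settings$seed <- settings$seed + 1L
  p_perm <- permutation_test_fit(table, fit, factor, perm_settings)
  lr <- lrt_fit(table, fit, factor)
  structure(list(
    factor = factor, R = R,
    ci_low = unname(ci[1L]), ci_high = unname(ci[2L]),
    p_lrt = lr$p, p_permut = as.numeric(p_perm),
    lrt_statistic = lr$statistic,
    n_boot = settings$n_boot, n_permut = settings$n_permut,
    n_boot_failed = attr(ci, "n_failed"),
    seed = settings$seed,
    fit = fit, settings = settings
  ), class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Repeatability of '%s' (response '%s')\n",
              x$factor, x$fit$spec$response))
  cat(sprintf("  R = %.4f  CI[%.1f%%, %.1f%%] = [%.4f, %.4f]\n",
              x$R, 100 * x$settings$ci_quantiles[1L],
              100 * x$settings$ci_quantiles[2L], x$ci_low, x$ci_high))
  cat(sprintf("  LRT: statistic = %.4g, p = %.4g;  permutation p = %.4g (n = %d)\n",
              x$lrt_statistic, x$p_lrt, x$p_permut, x$n_permut))
  if (x$n_boot_failed > 0L) {
    cat(sprintf("  note: %d/%d bootstrap replicates dropped\n",
                x$n_boot_failed, x$n_boot))
  }
  invisible(x)
}

#' Multi-factor repeatability analysis
#'
#' Fits one mixed model with all requested random factors and reports, per
#' factor, the agreement repeatability with its parametric-bootstrap CI,
#' permutation p-value and boundary-corrected likelihood-ratio p-value.
#' Per-factor resampling seeds are derived deterministically from the base
#' seed so results do not depend on factor order.
#'
#' @param table A [behavior_table()].
#' @param response Measure name.
#' @param random_factors Character vector of grouping factors (e.g.
#'   `c("animal_id", "strain", "experiment")`).
#' @param fixed_factors Optional categorical covariates for the fixed part.
#' @param settings A [resampling_settings()].
#' @return A named list of `repeatability_result`s (class `rpt_results`), one
#'   per random factor, sharing the same underlying multi-factor fit.
#' @examples
#' tab <- generate_habituation(studylike_scenario(), seed = 1)$table
#' res <- rpt(tab, "distance_cm", c("animal_id", "strain", "experiment"),
#'            settings = resampling_settings(n_boot = 50, n_permut = 20, seed = 1))
#' res
#' @export
rpt <- function(table, response, random_factors, fixed_factors = character(),
                settings = resampling_settings()) {
  spec <- model_spec(response, random_factors, fixed_factors)
  fit <- fit_vc_lmm(table, spec)
  out <- vector("list", length(random_factors))
  names(out) <- random_factors
  for (g in random_factors) {
    s_g <- settings
    # stable per-factor seed: keyed to the factor's order in the sorted list,
    # so permuting the input order cannot change any factor's result
    s_g$seed <- settings$seed + 1000L * (match(g, sort(random_factors)) - 1L)
    out[[g]] <- repeatability_result(table, fit, g, s_g)
  }
  structure(out, class = c("rpt_results", "list"), response = response)
}

#' @export
print.rpt_results <- function(x, ...) {
  cat(sprintf("Repeatability, response '%s' (%d random factors)\n",
              attr(x, "response"), length(x)))
  df <- do.call(rbind, lapply(x, function(r) {
    data.frame(factor = r$factor, R = r$R, ci_low = r$ci_low,
               ci_high = r$ci_high, p_lrt = r$p_lrt, p_permut = r$p_permut)
  }))
  rownames(df) <- NULL
  print(df, digits = 4)
  invisible(x)
}

#' Repeatability adjusted for fixed covariates
#'
#' Fits `value ~ covariates + (1 | factor)` and returns
#' `R = sigma2_factor / (sigma2_factor + sigma2_eps)`: the covariates'
#' variance is absorbed by the fixed part and leaves both numerator and
#' denominator. Used to adjust the animal-level repeatability for strain.
#' When every group lies entirely within one covariate level and the covariate
#' has as many levels as there are groups, factor and covariate are confounded
#' and an identifiability warning is raised (the fit is still returned).
#'
#' @param table A [behavior_table()].
#' @param response Measure name.
#' @param factor The random grouping factor.
#' @param covariates Character vector of fixed covariates (disjoint from
#'   `factor`).
#' @param settings A [resampling_settings()].
#' @return A `repeatability_result`.
#' @export
adjusted_repeatability <- function(table, response, factor, covariates,
                                   settings = resampling_settings()) {
  if (factor %in% covariates) {
    stop_habrep("spec_error", "covariates must be disjoint from the random factor")
  }
  spec <- model_spec(response, factor, covariates)
  df <- measure_frame(table, response)
  for (cv in covariates) {
    nested <- all(vapply(split(df[[cv]], df[[factor]]),
                         function(v) length(unique(v)) == 1L, TRUE))
    if (nested && length(unique(df[[cv]])) >= length(unique(df[[factor]]))) {
      warn_habrep("identifiability_warning",
        sprintf("covariate '%s' saturates the levels of '%s'", cv, factor))
    }
  }
  fit <- fit_vc_lmm(table, spec)
  repeatability_result(table, fit, factor, settings)
}
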