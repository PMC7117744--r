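#' Specify a Gaussian mixed model for a behavioral measure
#'
#' The model is `value ~ fixed factors + (1 | g)` for each random grouping
#' factor `g`: a Gaussian linear mixed model with independent random intercepts
#' per factor (crossed factors such as animal, strain and batch each enter as a
#' separate intercept term). An intercept is always included; categorical fixed
#' factors use treatment coding with the lexicographically smallest level as
#' reference.
#'
#' @param response Measure name to model (must exist in the table).
#' @param random_factors Character vector of grouping-factor column names
#'   (at least one), e.g. `c("animal_id", "strain", "experiment")`.
#' @param fixed_factors Character vector of categorical fixed-effect column
#'   names (possibly empty).
#' @param estimation `"REML"` (default) or `"ML"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, random_factors, fixed_factors = character(),
                       estimation = c("REML", "ML")) {
  estimation <- match.arg(estimation)
  if (length(random_factors) < 1L) {
    stop_habrep("spec_error", "at least one random factor is required")
  }
  overlap <- intersect(random_factors, fixed_factors)
  if (length(overlap) > 0L) {
    stop_habrep("spec_error",
      sprintf("factor(s) in both random and fixed lists: %s",
              paste(overlap, collapse = ", ")))
  }
  if (anyDuplicated(random_factors)) {
    stop_habrep("spec_error", "duplicated random factor names")
  }
  structure(list(response = response,
                 random_factors = as.character(random_factors),
                 fixed_factors = as.character(fixed_factors),
                 estimation = estimation),
            class = "model_spec")
}

# ---- sufficient statistics -------------------------------------------------
#
# The marginal covariance is V = sigma2_eps * H with H = I + sum_g lambda_g
# Z_g Z_g', lambda_g = sigma2_g / sigma2_eps.  Everything the profiled
# (restricted) likelihood needs reduces to crossproducts of (X, y, Z), so a
# fit touches the n rows once and each objective evaluation costs O(q^3) in
# q = total random-effect levels (O(q) when there is a single factor, because
# Z'Z is then diagonal).  This is what makes the bootstrap affordable.

lmm_suffstats <- function(y, X, faclist) {
  n <- length(y)
  p <- ncol(X)
  k <- length(faclist)
  fac <- lapply(faclist, function(f) {
    f <- droplevels(factor(f))
    list(code = as.integer(f), levels = levels(f), nlev = nlevels(f))
  })
  nlev <- vapply(fac, `[[`, 0L, "nlev")
  q <- sum(nlev)
  off <- cumsum(c(0L, nlev))[seq_len(max(k, 1L))]
  Zty <- numeric(q)
  ZtX <- matrix(0, q, p)
  counts <- numeric(q)
  for (g in seq_len(k)) {
    r <- off[g] + seq_len(nlev[g])
    cg <- fac[[g]]$code
    Zty[r] <- rowsum(y, cg)[, 1L]
    ZtX[r, ] <- rowsum(X, cg)
    counts[r] <- tabulate(cg, nlev[g])
  }
  ZtZ <- NULL
  if (k >= 2L) {
    ZtZ <- matrix(0, q, q)
    for (g in seq_len(k)) {
      rg <- off[g] + seq_len(nlev[g])
      ZtZ[rg, rg] <- diag(counts[rg], nrow = nlev[g])
      if (g < k) for (h in seq((g + 1L), k)) {
        rh <- off[h] + seq_len(nlev[h])
        tab <- table(factor(fac[[g]]$code, levels = seq_len(nlev[g])),
                     factor(fac[[h]]$code, levels = seq_len(nlev[h])))
        ZtZ[rg, rh] <- as.matrix(tab)
        ZtZ[rh, rg] <- t(ZtZ[rg, rh])
      }
    }
  }
  list(y = y, X = X, n = n, p = p, k = k, q = q,
       fac = fac, nlev = nlev, off = off,
       yty = sum(y * y), Xty = crossprod(X, y), XtX = crossprod(X),
       Zty = Zty, ZtX = ZtX, counts = counts, ZtZ = ZtZ,
       fac_names = names(faclist))
}

# replace the response on an existing design (bootstrap / permutation refits)
suffstats_set_response <- function(d, y) {
  d$y <- y
  d$yty <- sum(y * y)
  d$Xty <- crossprod(d$X, y)
  for (g in seq_len(d$k)) {
    r <- d$off[g] + seq_len(d$nlev[g])
    d$Zty[r] <- rowsum(y, d$fac[[g]]$code)[, 1L]
  }
  d
}

# profiled (restricted) likelihood evaluation at theta = log(lambda)
reml_eval <- function(theta, d, reml = TRUE) {
  lam <- exp(theta)
  lam_rep <- rep(lam, d$nlev)
  if (d$k == 0L) {
    logdetM <- 0
    XtHiX <- d$XtX
    XtHiy <- d$Xty
    ytHiy <- d$yty
  } else if (d$k == 1L) {
    m <- 1 + lam_rep * d$counts
    w <- lam_rep / m
    logdetM <- sum(log(m))
    sw <- sqrt(w)
    XtHiX <- d$XtX - crossprod(d$ZtX * sw)
    XtHiy <- d$Xty - crossprod(d$ZtX, w * d$Zty)
    ytHiy <- d$yty - sum(w * d$Zty^2)
  } else {
    s <- sqrt(lam_rep)
    M <- d$ZtZ * (s %o% s)
    diag(M) <- diag(M) + 1
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(list(nll = 1e10, ok = FALSE))
    logdetM <- 2 * sum(log(diag(R)))
    B <- backsolve(R, s * d$ZtX, transpose = TRUE)
    b <- backsolve(R, s * d$Zty, transpose = TRUE)
    XtHiX <- d$XtX - crossprod(B)
    XtHiy <- d$Xty - crossprod(B, b)
    ytHiy <- d$yty - sum(b^2)
  }
  RX <- tryCatch(chol(XtHiX), error = function(e) NULL)
  if (is.null(RX)) {
    stop_habrep("rank_error", "fixed-effects design is singular")
  }
  beta <- backsolve(RX, backsolve(RX, XtHiy, transpose = TRUE))
  rHir <- max(ytHiy - sum(XtHiy * beta), 0)
  logdetRX <- 2 * sum(log(diag(RX)))
  df <- if (reml) d$n - d$p else d$n
  if (rHir <= 0 || !is.finite(rHir)) return(list(nll = 1e10, ok = FALSE))
  s2 <- rHir / df
  ll <- if (reml) {
    -0.5 * (logdetM + logdetRX + df * (1 + log(2 * pi * s2)))
  } else {
    -0.5 * (logdetM + df * (1 + log(2 * pi * s2)))
  }
  list(nll = -ll, ll = ll, beta = drop(beta), s2 = s2, rHir = rHir,
       logdetM = logdetM, logdetRX = logdetRX, ok = TRUE)
}

# maximize the profiled likelihood over theta; deterministic starts only
reml_optimize <- function(d, reml = TRUE, start_theta = NULL) {
  k <- d$k
  nll <- function(th) reml_eval(th, d, reml)$nll
  if (k == 0L) {
    return(list(theta = numeric(0), value = nll(numeric(0)),
                iterations = 0L, convergence = 0L, message = "closed form"))
  }
  if (k == 1L) {
    opt <- stats::optimize(nll, interval = c(-30, 20), tol = 1e-9)
    theta <- opt$minimum
    value <- opt$objective
    # golden section cannot land exactly on a boundary optimum; check it
    v_lo <- nll(-30)
    if (v_lo < value) {
      theta <- -30
      value <- v_lo
    }
    return(list(theta = theta, value = value, iterations = NA_integer_,
                convergence = 0L, message = "optimize"))
  }
  starts <- if (!is.null(start_theta)) {
    list(pmin(pmax(start_theta, -30), 20))
  } else {
    # equal shares, residual-dominant, group-dominant
    list(rep(0, k), rep(log(0.05), k), rep(log(5), k))
  }
  best <- NULL
  for (s0 in starts) {
    o <- tryCatch(
      stats::optim(s0, nll, method = "L-BFGS-B", lower = -30, upper = 20,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-10) best <- o
  }
  if (is.null(best)) {
    stop_habrep("convergence_error", "all optimizer starts failed")
  }
  if (best$convergence != 0L) {
    stop_habrep("convergence_error",
      sprintf("optimizer did not converge (code %d): %s",
              best$convergence, best$message %||% ""),
      data = list(counts = best$counts, value = best$value))
  }
  list(theta = best$par, value = best$value,
       iterations = unname(best$counts[1L]), convergence = best$convergence,
       message = best$message %||% "")
}

# core fit on a prepared design; shared by the public fitter and fast refits
reml_fit_core <- function(d, estimation = "REML", start_theta = NULL) {
  reml <- identical(estimation, "REML")
  opt <- reml_optimize(d, reml, start_theta)
  ev <- reml_eval(opt$theta, d, reml)
  lam <- exp(opt$theta)
  s2 <- ev$s2
  sigma2 <- lam * s2
  total <- sum(sigma2) + s2
  boundary <- sigma2 / total < 1e-8
  sigma2[boundary] <- 0
  names(sigma2) <- d$fac_names
  names(boundary) <- d$fac_names
  beta <- ev$beta
  names(beta) <- colnames(d$X)
  list(theta = opt$theta, sigma2 = sigma2, sigma2_resid = s2, beta = beta,
       boundary = boundary, loglik = ev$ll, optimizer = opt)
}

#' Fit a variance-components mixed model by REML
#'
#' Fits the Gaussian linear mixed model described by `spec` to one measure of a
#' [behavior_table()]: `y = X beta + sum_g Z_g u_g + e`, with
#' `u_g ~ N(0, sigma2_g I)` and `e ~ N(0, sigma2_eps I)`. Variance components
#' are estimated by restricted maximum likelihood (default) with non-negativity
#' enforced through an unconstrained search over log variance ratios
#' `theta_g = log(sigma2_g / sigma2_eps)`; the residual variance and the fixed
#' effects are profiled out, so each fit is a low-dimensional deterministic
#' optimization (quasi-Newton with three fixed starts for multi-factor models).
#' Components whose share of the total variance falls below `1e-8` at the
#' optimum are clamped to exactly zero and flagged as boundary estimates.
#'
#' @param table A [behavior_table()].
#' @param spec A [model_spec()].
#' @param days Optional integer vector restricting the fit to a subset of trial
#'   days (used by the sliding-window scan).
#' @param start Optional `lmm_fit` (or numeric theta vector) used as a warm
#'   start; used internally to speed up bootstrap refits.
#' @return An object of class `lmm_fit` with elements `sigma2` (named
#'   per-factor variances), `sigma2_resid`, `beta`, `boundary` flags, `loglik`
#'   (maximized restricted or full log-likelihood, in the same convention as
#'   `lme4`), `group_counts`, and optimizer diagnostics.
#' @examples
#' tab <- generate_habituation(synthetic_config(seed = 1))$table
#' fit <- fit_vc_lmm(tab, model_spec("distance_cm", "animal_id"))
#' fit$sigma2 / (sum(fit$sigma2) + fit$sigma2_resid)
#' @export
fit_vc_lmm <- function(table, spec, days = NULL, start = NULL) {
  prep <- build_design(table, spec, days)
  start_theta <- if (inherits(start, "lmm_fit")) start$theta else start
  core <- reml_fit_core(prep$d, spec$estimation, start_theta)
  structure(c(core, list(
    spec = spec, n = prep$d$n, p = prep$d$p,
    group_counts = stats::setNames(prep$d$nlev, spec$random_factors),
    days = prep$days,
    design = prep$d
  )), class = "lmm_fit")
}

# validate preconditions and assemble the design/sufficient statistics
build_design <- function(table, spec, days = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  df <- measure_frame(table, spec$response, days)
  all_factors <- c(spec$random_factors, spec$fixed_factors)
  missing_f <- setdiff(all_factors, names(df))
  if (length(missing_f) > 0L) {
    stop_habrep("spec_error",
      sprintf("factor column(s) not in table: %s", paste(missing_f, collapse = ", ")))
  }
  y <- df$value
  n <- length(y)
  if (n < 2L) stop_habrep("degenerate_data_error", "need at least 2 observations")
  if (stats::var(y) <= 0) {
    stop_habrep("degenerate_data_error", "response is constant")
  }
  for (g in spec$random_factors) {
    if (length(unique(df[[g]])) < 2L) {
      stop_habrep("identifiability_error",
        sprintf("random factor '%s' has fewer than 2 levels", g))
    }
  }
  # single-level covariates are constants: equivalent to the intercept, so
  # they are dropped rather than breaking the contrast coding
  fixed_use <- spec$fixed_factors[vapply(spec$fixed_factors,
    function(f) length(unique(df[[f]])) >= 2L, TRUE)]
  X <- if (length(fixed_use) == 0L) {
    matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    fdat <- df[fixed_use]
    fdat[] <- lapply(fdat, function(x) factor(x, levels = sort(unique(x))))
    stats::model.matrix(stats::reformulate(fixed_use), data = fdat)
  }
  faclist <- stats::setNames(lapply(spec$random_factors, function(g) df[[g]]),
                             spec$random_factors)
  list(d = lmm_suffstats(y, X, faclist), days = sort(unique(df$day)), df = df)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian LMM (%s), response '%s', n = %d\n",
              x$spec$estimation, x$spec$response, x$n))
  comp <- c(x$sigma2, residual = x$sigma2_resid)
  share <- comp / sum(comp)
  out <- data.frame(variance = comp, share = share,
                    boundary = c(x$boundary, FALSE))
  print(out, digits = 4)
  cat(sprintf("logLik (%s): %.4f\n", x$spec$estimation, x$loglik))
  invisible(x)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the (restricted, or full when `spec$estimation == "ML"`)
#' log-likelihood of the model in `spec` at user-supplied variance components,
#' with the fixed effects replaced by their generalized-least-squares profile
#' values. At the REML optimum this equals `fit_vc_lmm(...)$loglik`.
#'
#' @param table A [behavior_table()].
#' @param spec A [model_spec()].
#' @param variances Named numeric vector with one entry per random factor plus
#'   `"residual"` (all `>= 0`, residual `> 0`).
#' @param days Optional day subset, as in [fit_vc_lmm()].
#' @return The log-likelihood value (scalar).
#' @export
restricted_loglik <- function(table, spec, variances, days = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c(spec$random_factors, "residual")
  if (!all(need %in% names(variances))) {
    stop_habrep("spec_error",
      sprintf("variances must name: %s", paste(need, collapse = ", ")))
  }
  sig_e <- as.numeric(variances[["residual"]])
  sig_g <- as.numeric(variances[spec$random_factors])
  if (sig_e <= 0 || any(sig_g < 0)) {
    stop_habrep("spec_error", "variances must be >= 0 with residual > 0")
  }
  d <- build_design(table, spec, days)$d
  lam <- sig_g / sig_e
  # evaluate non-profiled likelihood at (lam, sig_e)
  theta <- log(pmax(lam, 1e-300))
  ev <- reml_eval(theta, d, reml = identical(spec$estimation, "REML"))
  reml <- identical(spec$estimation, "REML")
  df <- if (reml) d$n - d$p else d$n
  ll <- -0.5 * (df * log(2 * pi * sig_e) +
                  ev$logdetM +
                  (if (reml) ev$logdetRX else 0) +
                  ev$rHir / sig_e)
  ll
}

#' Simulate responses from a fitted mixed model
#'
#' Parametric simulation used by the bootstrap: draws fresh random intercepts
#' per group level and fresh residuals from the fitted variances and adds the
#' fixed-effect predictions. Rows align with the rows the model was fitted to.
#'
#' @param fit An `lmm_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Integer seed; the same seed yields identical output and the
#'   caller's RNG state is left untouched.
#' @return A numeric vector (`nsim = 1`) or an `n x nsim` matrix.
#' @export
simulate_from_fit <- function(fit, nsim = 1L, seed = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (fit$sigma2_resid <= 0) {
    stop_habrep("degenerate_data_error", "fitted residual variance must be > 0")
  }
  d <- fit$design
  mu <- drop(d$X %*% fit$beta)
  sim_one <- function() {
    y <- mu + stats::rnorm(d$n, 0, sqrt(fit$sigma2_resid))
    for (g in seq_len(d$k)) {
      sg <- sqrt(fit$sigma2[[g]])
      if (sg > 0) {
        u <- stats::rnorm(d$nlev[g], 0, sg)
        y <- y + u[d$fac[[g]]$code]
      }
    }
    y
  }
  run <- function() {
    if (nsim == 1L) sim_one() else vapply(seq_len(nsim), function(i) sim_one(),
                                          numeric(d$n))
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# conditional fitted values (X beta + Z u_hat) and residuals; the BLUPs are
# u_hat_g = lambda_g Z_g' H^{-1} (y - X beta)
conditional_fitted <- function(fit) {
  d <- fit$design
  beta <- fit$beta
  mu <- drop(d$X %*% beta)
  if (d$k == 0L) return(mu)
  lam <- fit$sigma2 / fit$sigma2_resid
  lam_rep <- rep(lam, d$nlev)
  Ztr <- drop(d$Zty - d$ZtX %*% beta)
  if (d$k == 1L) {
    ZtHir <- Ztr / (1 + lam_rep * d$counts)
  } else {
    s <- sqrt(lam_rep)
    M <- d$ZtZ * (s %o% s)
    diag(M) <- diag(M) + 1
    ZtHir <- Ztr - drop(d$ZtZ %*% (s * solve(M, s * Ztr)))
  }
  u <- lam_rep * ZtHir
  for (g in seq_len(d$k)) {
    r <- d$off[g] + seq_len(d$nlev[g])
    mu <- mu + u[r][d$fac[[g]]$code]
  }
  mu
}

# fast refit of the same design on a new response (bootstrap / permutation)
refit_response <- function(fit, y, start = NULL) {
  d <- suffstats_set_response(fit$design, y)
  if (stats::var(y) <= 0) {
    stop_habrep("degenerate_data_error", "response is constant")
  }
  core <- reml_fit_core(d, fit$spec$estimation,
                        start %||% fit$theta)
  structure(c(core, list(
    spec = fit$spec, n = fit$n, p = fit$p,
    group_counts = fit$group_counts, days = fit$days, design = d
  )), class = "lmm_fit")
}

# restricted log-likelihood of the fixed-effects-only model on a fit's design
# (the lambda -> 0 limit); used by the likelihood-ratio test when the reduced
# model has no random factors left
fixed_only_loglik <- function(fit) {
  d <- fit$design
  d$k <- 0L
  reml <- identical(fit$spec$estimation, "REML")
  reml_eval(numeric(0), d, reml)$ll
}
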