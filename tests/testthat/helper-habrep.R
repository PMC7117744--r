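# fixtures are built in code: small tables, closed-form oracles, simulators

# balanced one-way toy: g groups x r replicates, values supplied column-wise
toy_oneway <- function(values, g, r, measure = "m") {
  stopifnot(length(values) == g * r)
  behavior_table(data.frame(
    animal_id = rep(sprintf("g%02d", seq_len(g)), each = r),
    strain = "s0", experiment = "e0",
    day = rep(seq_len(r), g), measure = measure, value = values,
    stringsAsFactors = FALSE
  ))
}

# method-of-moments variance components for a balanced one-way layout
# (independent oracle for the REML fitter: they coincide at interior optima)
anova_oneway_vc <- function(y, group) {
  group <- as.factor(group)
  r <- as.vector(table(group))[1L]
  stopifnot(all(table(group) == r))
  g <- nlevels(group)
  means <- tapply(y, group, mean)
  msb <- r * sum((means - mean(y))^2) / (g - 1)
  msw <- sum((y - means[group])^2) / (g * (r - 1))
  list(sigma_b = (msb - msw) / r, sigma_w = msw, msb = msb, msw = msw)
}

# closed-form restricted log-likelihood for the balanced one-way model with
# intercept-only fixed part (eigen-decomposition of V)
oneway_reml_loglik <- function(y, group, sig_b, sig_w) {
  group <- as.factor(group)
  r <- as.vector(table(group))[1L]
  g <- nlevels(group)
  n <- length(y)
  lam1 <- sig_w + r * sig_b # group-mean eigenvalue
  means <- tapply(y, group, mean)
  ssb <- r * sum((means - mean(y))^2)
  ssw <- sum((y - means[group])^2)
  -0.5 * ((n - 1) * log(2 * pi) + g * log(lam1) + (n - g) * log(sig_w) +
            log(n / lam1) + ssw / sig_w + ssb / lam1)
}

# one-strain, one-batch steady-state simulator with true R = sd_a^2/(sd_a^2+sd_e^2)
sim_oneway <- function(R, n_groups = 50L, n_rep = 5L, seed = 1L) {
  cfg <- synthetic_config(
    n_per_strain = stats::setNames(n_groups, "G"), n_days = n_rep, n_batches = 1L,
    mu = 0, nu = 0, tau = 1, sd_animal = sqrt(R), w = rep(1, n_rep),
    sd_strain = 0, sd_batch = 0, sd_resid = sqrt(1 - R), kappa = 1,
    measure = "y", seed = seed)
  generate_habituation(cfg)$table
}

spec_oneway <- model_spec("y", "animal_id")

# hand-built window series for recommendation-rule tests
fake_series <- function(R, ci_low, start_days, width = 3L, measure = "m",
                        factor = "animal_id") {
  tab <- data.frame(start_day = start_days, end_day = start_days + width - 1L,
                    R = R, ci_low = ci_low, ci_high = pmin(1, R + 0.2),
                    p_lrt = 0.01, p_permut = 0.01, failed = FALSE)
  structure(list(measure = measure, factor = factor, width = width, seed = 1L,
                 table = tab, results = vector("list", length(R))),
            class = "window_series")
}
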