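test_that("REML matches the balanced-ANOVA closed form at interior optima", {
  # the fixed worked example: 3 groups x 2 replicates
  tab <- toy_oneway(c(0, 1, 10, 11, 20, 21), g = 3, r = 2)
  fit <- fit_vc_lmm(tab, model_spec("m", "animal_id"))
  expect_equal(unname(fit$sigma2[["animal_id"]]), 99.75, tolerance = 1e-7)
  expect_equal(fit$sigma2_resid, 0.5, tolerance = 1e-7)

  # parameterised over random balanced designs with interior optima
  for (case in list(c(g = 5, r = 3, seed = 11), c(g = 8, r = 4, seed = 12),
                    c(g = 20, r = 6, seed = 13))) {
    y <- withr::with_seed(case[["seed"]], {
      g <- case[["g"]]; r <- case[["r"]]
      rep(stats::rnorm(g, 0, 3), each = r) + stats::rnorm(g * r)
    })
    tab <- toy_oneway(y, case[["g"]], case[["r"]])
    oracle <- anova_oneway_vc(y, rep(seq_len(case[["g"]]), each = case[["r"]]))
    if (oracle$sigma_b <= 0) next # only interior optima are equivalent
    fit <- fit_vc_lmm(tab, model_spec("m", "animal_id"))
    expect_equal(unname(fit$sigma2[["animal_id"]]), oracle$sigma_b,
                 tolerance = 1e-6)
    expect_equal(fit$sigma2_resid, oracle$sigma_w, tolerance = 1e-6)
  }
})

test_that("group variance clamps to zero at the boundary with a flag", {
  tab <- toy_oneway(c(0, 2, 0, 2, 0, 2), g = 3, r = 2)
  fit <- fit_vc_lmm(tab, model_spec("m", "animal_id"))
  expect_identical(unname(fit$sigma2[["animal_id"]]), 0)
  expect_true(fit$boundary[["animal_id"]])
  # with the group component at zero the model collapses to iid, so the REML
  # residual is the overall sample variance SS_total/(n-1) = 6/5
  expect_equal(fit$sigma2_resid, 1.2, tolerance = 1e-6)
})

test_that("restricted_loglik agrees with the balanced closed form", {
  y <- withr::with_seed(21, rep(stats::rnorm(6, 0, 2), each = 3) + stats::rnorm(18))
  tab <- toy_oneway(y, 6, 3)
  spec <- model_spec("m", "animal_id")
  g <- rep(seq_len(6), each = 3)
  for (vc in list(c(animal_id = 1, residual = 1), c(animal_id = 4, residual = 0.5),
                  c(animal_id = 0.01, residual = 2))) {
    expect_equal(restricted_loglik(tab, spec, vc),
                 oneway_reml_loglik(y, g, vc[["animal_id"]], vc[["residual"]]),
                 tolerance = 1e-9)
  }

  # at the optimum it equals the maximized value and dominates perturbations
  fit <- fit_vc_lmm(tab, spec)
  opt <- c(animal_id = unname(fit$sigma2[["animal_id"]]), residual = fit$sigma2_resid)
  ll_opt <- restricted_loglik(tab, spec, opt)
  expect_equal(ll_opt, fit$loglik, tolerance = 1e-7)
  for (f in c(0.7, 1.4)) {
    pert <- opt; pert[["animal_id"]] <- opt[["animal_id"]] * f
    expect_lte(restricted_loglik(tab, spec, pert), ll_opt + 1e-10)
  }

  # sigma_g -> 0 limit equals the fixed-effects-only restricted likelihood
  n <- length(y)
  s2_hat <- sum((y - mean(y))^2) / (n - 1)
  ll_fixed <- -0.5 * ((n - 1) * (1 + log(2 * pi * s2_hat)) + log(n))
  expect_equal(restricted_loglik(tab, spec, c(animal_id = 1e-12, residual = s2_hat)),
               ll_fixed, tolerance = 1e-6)
})

test_that("multi-factor REML reproduces lme4 on study-like data", {
  skip_if_not_installed("lme4")
  sim <- generate_habituation(studylike_scenario(), seed = 4)
  spec <- model_spec("distance_cm", c("animal_id", "strain", "experiment"))
  fit <- fit_vc_lmm(sim$table, spec)
  df <- as.data.frame(sim$table)
  lf <- suppressMessages(lme4::lmer(
    value ~ 1 + (1 | animal_id) + (1 | strain) + (1 | experiment),
    data = df[df$measure == "distance_cm", ], REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- stats::setNames(vc$vcov, vc$grp)
  tot <- sum(ref)
  for (g in c("animal_id", "strain", "experiment")) {
    expect_equal(fit$sigma2[[g]], ref[[g]], tolerance = 1e-4 * tot)
  }
  expect_equal(fit$sigma2_resid, ref[["Residual"]], tolerance = 1e-6 * tot)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
})

test_that("fits are invariant to group relabeling and equivariant to scale", {
  sim <- generate_habituation(synthetic_config(
    n_per_strain = c(A = 10, B = 8), n_days = 4, seed = 31))
  tab <- sim$table
  spec <- model_spec("distance_cm", c("animal_id", "strain"))
  fit <- fit_vc_lmm(tab, spec)

  # permute animal labels
  ids <- unique(tab$animal_id)
  relabel <- stats::setNames(sample(ids), ids)
  df2 <- as.data.frame(tab)
  df2$animal_id <- unname(relabel[df2$animal_id])
  fit2 <- fit_vc_lmm(behavior_table(df2), spec)
  expect_equal(fit2$sigma2, fit$sigma2, tolerance = 1e-6)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)

  # affine response transform: variances scale by a^2
  df3 <- as.data.frame(tab)
  df3$value <- 2.5 * df3$value + 100
  fit3 <- fit_vc_lmm(behavior_table(df3), spec)
  expect_equal(fit3$sigma2, fit$sigma2 * 2.5^2, tolerance = 1e-4)
  expect_equal(fit3$sigma2_resid, fit$sigma2_resid * 2.5^2, tolerance = 1e-4)
})

test_that("adding a random factor never decreases the restricted likelihood", {
  for (seed in 41:43) {
    sim <- generate_habituation(synthetic_config(
      n_per_strain = c(A = 8, B = 8, C = 8), n_days = 4, seed = seed))
    tab <- sim$table
    ll1 <- fit_vc_lmm(tab, model_spec("distance_cm", "animal_id"))$loglik
    ll2 <- fit_vc_lmm(tab, model_spec("distance_cm", c("animal_id", "strain")))$loglik
    ll3 <- fit_vc_lmm(tab, model_spec("distance_cm",
                                      c("animal_id", "strain", "experiment")))$loglik
    expect_gte(ll2, ll1 - 1e-6)
    expect_gte(ll3, ll2 - 1e-6)
  }
})

test_that("simulation honors the seeding contract and the fitted moments", {
  tab <- sim_oneway(0.5, n_groups = 20, n_rep = 4, seed = 6)
  fit <- fit_vc_lmm(tab, spec_oneway)
  a <- simulate_from_fit(fit, nsim = 3, seed = 99)
  b <- simulate_from_fit(fit, nsim = 3, seed = 99)
  c <- simulate_from_fit(fit, nsim = 3, seed = 100)
  expect_identical(a, b)
  expect_false(identical(a, c))

  # empirical variance of many simulations matches the fitted total variance
  big <- simulate_from_fit(fit, nsim = 200, seed = 7)
  tot <- sum(fit$sigma2) + fit$sigma2_resid
  expect_equal(mean(apply(big, 2, stats::var)), tot, tolerance = 0.15 * tot)
})

test_that("degenerate inputs raise classed errors", {
  const <- toy_oneway(rep(1, 6), 3, 2)
  expect_error(fit_vc_lmm(const, model_spec("m", "animal_id")),
               class = "habrep_degenerate_data_error")

  one_level <- behavior_table(data.frame(
    animal_id = "m1", strain = "s", experiment = "e",
    day = 1:4, measure = "m", value = c(1, 2, 3, 4)))
  expect_error(fit_vc_lmm(one_level, model_spec("m", "animal_id")),
               class = "habrep_identifiability_error")

  tab <- sim_oneway(0.5, n_groups = 5, n_rep = 2, seed = 1)
  fit <- fit_vc_lmm(tab, spec_oneway)
  expect_error(restricted_loglik(tab, spec_oneway, c(animal_id = -1, residual = 1)),
               class = "habrep_spec_error")
})
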