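test_that("point repeatability is the variance share of the factor", {
  tab <- toy_oneway(c(0, 1, 10, 11, 20, 21), g = 3, r = 2)
  fit <- fit_vc_lmm(tab, model_spec("m", "animal_id"))
  expect_equal(point_repeatability(fit, "animal_id"), 99.75 / 100.25,
               tolerance = 1e-6)

  clamped <- fit_vc_lmm(toy_oneway(c(0, 2, 0, 2, 0, 2), 3, 2),
                        model_spec("m", "animal_id"))
  expect_identical(point_repeatability(clamped, "animal_id"), 0)

  expect_error(point_repeatability(fit, "strain"), class = "habrep_spec_error")
})

test_that("repeatabilities sum to at most one and respect invariances", {
  for (seed in 1:4) {
    sim <- generate_habituation(synthetic_config(
      n_per_strain = c(A = 10, B = 8, C = 6), n_days = 4, seed = seed))
    fit <- fit_vc_lmm(sim$table,
                      model_spec("distance_cm", c("animal_id", "strain", "experiment")))
    Rs <- vapply(c("animal_id", "strain", "experiment"),
                 function(g) point_repeatability(fit, g), 0)
    expect_true(all(Rs >= 0 & Rs <= 1))
    expect_lte(sum(Rs), 1)
  }

  # R is invariant under affine response transforms
  sim <- generate_habituation(synthetic_config(
    n_per_strain = c(A = 12, B = 10), n_days = 4, seed = 9))
  fit <- fit_vc_lmm(sim$table, model_spec("distance_cm", "animal_id"))
  df2 <- as.data.frame(sim$table)
  df2$value <- -3 * df2$value + 7
  fit2 <- fit_vc_lmm(behavior_table(df2), model_spec("distance_cm", "animal_id"))
  expect_equal(point_repeatability(fit2, "animal_id"),
               point_repeatability(fit, "animal_id"), tolerance = 1e-5)
})

test_that("bootstrap and permutation are reproducible under a fixed seed", {
  tab <- sim_oneway(0.5, n_groups = 15, n_rep = 4, seed = 8)
  set <- resampling_settings(n_boot = 30, n_permut = 15, seed = 42)
  ci1 <- bootstrap_ci(tab, spec_oneway, "animal_id", set)
  ci2 <- bootstrap_ci(tab, spec_oneway, "animal_id", set)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  expect_identical(attr(ci1, "R_boot"), attr(ci2, "R_boot"))
  p1 <- permutation_test(tab, spec_oneway, "animal_id", set)
  p2 <- permutation_test(tab, spec_oneway, "animal_id", set)
  expect_identical(as.numeric(p1), as.numeric(p2))
})

test_that("true zero repeatability piles bootstrap mass on the boundary", {
  tab <- sim_oneway(0, n_groups = 20, n_rep = 4, seed = 17)
  ci <- bootstrap_ci(tab, spec_oneway, "animal_id",
                     resampling_settings(n_boot = 100, seed = 3))
  expect_identical(unname(ci[1]), 0)
})

test_that("permutation p is uniform-ish under the null and minimal under separation", {
  # exchangeable null: mean p near 0.5 over replicates
  ps <- vapply(1:20, function(s) {
    tab <- sim_oneway(0, n_groups = 8, n_rep = 3, seed = 100 + s)
    as.numeric(permutation_test(tab, spec_oneway, "animal_id",
                                resampling_settings(n_boot = 1, n_permut = 20,
                                                    seed = s)))
  }, 0)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)

  # perfectly separated groups: observed R never strictly exceeded, so p sits
  # at the floor up to tie-preserving permutations (those that reassemble the
  # same partition of residuals reproduce R exactly)
  tab <- toy_oneway(c(0, 0.01, 100, 100.01, 200, 200.01), 3, 2)
  set <- resampling_settings(n_boot = 1, n_permut = 50, seed = 2)
  p <- permutation_test(tab, model_spec("m", "animal_id"), "animal_id", set)
  expect_gte(as.numeric(p), 1 / 50)
  expect_lte(as.numeric(p), 6 / 50)
  # exact mode pins the tie set precisely: 3! * 2!^3 of 6! permutations
  p_ex <- permutation_test(tab, model_spec("m", "animal_id"), "animal_id",
                           exact = TRUE)
  expect_equal(as.numeric(p_ex), 48 / 720, tolerance = 1e-12)
})

test_that("exact permutation matches a brute-force enumeration oracle", {
  for (vals in list(c(1.2, 1.9, 5.3, 6.1), c(2, 7, 3, 5))) {
    tab <- toy_oneway(vals, g = 2, r = 2)
    spec <- model_spec("m", "animal_id")
    p_pkg <- as.numeric(permutation_test(tab, spec, "animal_id", exact = TRUE))
    # oracle: clamped method-of-moments R over all residual permutations
    g <- rep(1:2, each = 2)
    mom_R <- function(y) {
      vc <- anova_oneway_vc(y, g)
      sb <- max(vc$sigma_b, 0)
      sb / (sb + vc$sigma_w)
    }
    r0 <- vals - mean(vals)
    perms <- habrep:::all_permutations(4L)
    Rs <- vapply(perms, function(p) mom_R(mean(vals) + r0[p]), 0)
    p_oracle <- mean(Rs >= mom_R(vals) - 1e-8)
    expect_identical(p_pkg, p_oracle)
  }
})

test_that("boundary-corrected LRT behaves at zero and rejects real structure", {
  # clamped component: statistic 0 -> p = 0.5
  tab0 <- toy_oneway(c(0, 2, 0, 2, 0, 2), 3, 2)
  lr0 <- lrt(tab0, model_spec("m", "animal_id"), "animal_id")
  expect_equal(lr0$statistic, 0, tolerance = 1e-6)
  expect_equal(lr0$p, 0.5, tolerance = 1e-6)

  # strong structure: tiny p, statistic > 0
  tab1 <- sim_oneway(0.6, n_groups = 30, n_rep = 5, seed = 4)
  lr1 <- lrt(tab1, spec_oneway, "animal_id")
  expect_gt(lr1$statistic, 10)
  expect_lt(lr1$p, 1e-3)
  expect_gt(lr1$p, 0)
})

test_that("rpt on a single factor agrees with the direct fit and ignores factor order", {
  tab <- sim_oneway(0.5, n_groups = 12, n_rep = 4, seed = 14)
  set <- resampling_settings(n_boot = 15, n_permut = 8, seed = 5)
  res <- rpt(tab, "y", "animal_id", settings = set)
  fit <- fit_vc_lmm(tab, spec_oneway)
  expect_equal(res$animal_id$R, point_repeatability(fit, "animal_id"),
               tolerance = 1e-9)

  sim <- generate_habituation(synthetic_config(
    n_per_strain = c(A = 10, B = 8), n_days = 4, seed = 15))
  a <- rpt(sim$table, "distance_cm", c("animal_id", "strain"), settings = set)
  b <- rpt(sim$table, "distance_cm", c("strain", "animal_id"), settings = set)
  for (g in c("animal_id", "strain")) {
    expect_identical(a[[g]]$R, b[[g]]$R)
    expect_identical(a[[g]]$ci_low, b[[g]]$ci_low)
    expect_identical(a[[g]]$p_permut, b[[g]]$p_permut)
  }
})

test_that("adjusting for a mean-shifting covariate removes its share from R", {
  # strain shifts means only; because strain is constant within animal, the
  # single-factor animal component absorbs it, so conditioning on strain
  # reduces R toward the pure individual share (the 'slightly reduced'
  # adjusted values seen in habituation data)
  cfg <- synthetic_config(n_per_strain = c(A = 15, B = 15, C = 15), n_days = 4,
                          n_batches = 1, mu = 0, nu = 0, tau = 1,
                          sd_animal = 1, w = rep(1, 4), sd_strain = 2,
                          sd_batch = 0, sd_resid = 1, kappa = 1,
                          measure = "y", seed = 23)
  tab <- generate_habituation(cfg)$table
  set <- resampling_settings(n_boot = 10, n_permut = 5, seed = 1)
  unadj <- point_repeatability(fit_vc_lmm(tab, model_spec("y", "animal_id")),
                               "animal_id")
  adj <- adjusted_repeatability(tab, "y", "animal_id", "strain", set)
  expect_lte(adj$R, unadj)
  # adjusted R targets sd_animal^2 / (sd_animal^2 + sd_resid^2) = 0.5
  expect_lt(abs(adj$R - 0.5), 0.15)

  # degenerate single-level covariate: identical to the unadjusted fit
  one <- generate_habituation(synthetic_config(
    n_per_strain = c(A = 12), n_days = 4, n_batches = 1, seed = 3))$table
  adj1 <- adjusted_repeatability(one, "distance_cm", "animal_id", "strain", set)
  un1 <- point_repeatability(fit_vc_lmm(one, model_spec("distance_cm", "animal_id")),
                             "animal_id")
  expect_equal(adj1$R, un1, tolerance = 1e-9)
})

test_that("repeatability estimates recover the generative shares", {
  for (share in c(0, 0.2, 0.6)) {
    Rh <- vapply(1:60, function(s) {
      tab <- sim_oneway(share, n_groups = 50, n_rep = 5, seed = 7000 + s)
      point_repeatability(fit_vc_lmm(tab, spec_oneway), "animal_id")
    }, 0)
    expect_lte(abs(mean(Rh) - share), 0.03)
  }
})
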