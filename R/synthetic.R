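#' Configuration of the synthetic habituation generator
#'
#' Defines the generative model for synthetic open-field habituation data:
#'
#' `y[i, d] = mu + nu * exp(-(d - 1) / tau) + w[d] * a[i] + s[strain(i)] +
#'  b[batch(i)] + e[i, d]`
#'
#' with `a ~ N(0, sd_animal^2)`, `s ~ N(0, sd_strain^2)`,
#' `b ~ N(0, sd_batch^2)`, and residuals `e[i, 1] ~ N(0, (kappa * sd_resid)^2)`
#' on day 1 but `N(0, sd_resid^2)` afterwards. The exponential term is the
#' population-level novelty response that decays over days; the per-day
#' personality weights `w` let stable individual differences emerge only
#' after day 1 (default `w[1] = 0.3`, `w[d] = 1` for `d >= 2`); `kappa`
#' inflates day-1 noise, mimicking stress/anxiety-driven scatter on first
#' exposure. Both day-1 mechanisms are independently settable so either
#' hypothesis can be simulated alone.
#'
#' The default numbers are distance-travelled-like (cm): they put the day-1
#' population mean near 940 and the post-decay mean near 350, with a
#' steady-state single-factor animal repeatability of about 0.53.
#'
#' @param n_per_strain Named integer vector, animals per strain.
#' @param n_days Number of daily trials.
#' @param n_batches Number of experimental batches; animals are interleaved
#'   deterministically into batches within strain.
#' @param mu Baseline mean (response units).
#' @param nu Day-1 novelty elevation (response units).
#' @param tau Novelty decay constant (days, > 0).
#' @param sd_animal SD of individual (animal) intercepts.
#' @param w Per-day personality weight vector in `[0, 1]`; recycled or
#'   truncated to `n_days`.
#' @param sd_strain SD of strain effects.
#' @param sd_batch SD of batch effects.
#' @param sd_resid Residual SD.
#' @param kappa Day-1 residual inflation factor (>= 0).
#' @param measure Measure name written into the table.
#' @param seed Default seed used by [generate_habituation()] when none is
#'   passed there.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_strain = c(A = 38L, B = 15L, C = 15L),
                             n_days = 7L, n_batches = 2L,
                             mu = 350, nu = 590, tau = 0.6,
                             sd_animal = 110,
                             w = c(0.3, rep(1, 6)),
                             sd_strain = 60, sd_batch = 20,
                             sd_resid = 120, kappa = 2,
                             measure = "distance_cm", seed = 1L) {
  if (is.null(names(n_per_strain)) || any(!nzchar(names(n_per_strain)))) {
    stop_habrep("config_error", "n_per_strain must be a named vector")
  }
  if (any(n_per_strain < 2L)) {
    stop_habrep("config_error", "need >= 2 animals per strain")
  }
  if (!is_count(n_days, 1L) || !is_count(n_batches, 1L)) {
    stop_habrep("config_error", "n_days and n_batches must be positive integers")
  }
  if (tau <= 0) stop_habrep("config_error", "tau must be > 0")
  sds <- c(sd_animal = sd_animal, sd_strain = sd_strain,
           sd_batch = sd_batch, sd_resid = sd_resid)
  if (any(sds < 0) || kappa < 0) {
    stop_habrep("config_error", "standard deviations and kappa must be >= 0")
  }
  w <- rep_len(as.numeric(w), n_days)
  if (any(w < 0 | w > 1)) stop_habrep("config_error", "w entries must lie in [0, 1]")
  structure(list(
    n_per_strain = stats::setNames(as.integer(n_per_strain), names(n_per_strain)),
    n_days = as.integer(n_days), n_batches = as.integer(n_batches),
    mu = mu, nu = nu, tau = tau, sd_animal = sd_animal, w = w,
    sd_strain = sd_strain, sd_batch = sd_batch, sd_resid = sd_resid,
    kappa = kappa, measure = measure, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic habituation dataset with known ground truth
#'
#' Draws one dataset from the generative model in [synthetic_config()].
#' The returned ground truth records the realized animal, strain and batch
#' effects plus the implied repeatability values for the steady-state days
#' (`w[d] = 1`): `R_star = sd_animal^2 / (sd_animal^2 + sd_strain^2 +
#' sd_batch^2 + sd_resid^2)` (multi-factor decomposition) and `R_single =
#' sd_animal^2 / (sd_animal^2 + sd_resid^2)`. The same seed always yields an
#' identical table; batch assignment is deterministic (interleaved within
#' strain) so that only the Gaussian draws consume randomness.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List with `table` (a [behavior_table()]) and `truth` (class
#'   `ground_truth`).
#' @examples
#' sim <- generate_habituation(synthetic_config(seed = 7))
#' summary(sim$table)
#' sim$truth$R_star
#' @export
generate_habituation <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- as.integer(seed %||% config$seed)
  strains <- names(config$n_per_strain)
  n_animal <- sum(config$n_per_strain)
  animal_strain <- rep(strains, config$n_per_strain)
  animal_id <- sprintf("m%03d", seq_len(n_animal))
  # deterministic interleaved batch assignment within strain
  batch_of <- unlist(lapply(config$n_per_strain, function(n)
    rep_len(seq_len(config$n_batches), n)), use.names = FALSE)
  batch_labels <- sprintf("exp%d", seq_len(config$n_batches))
  animal_batch <- batch_labels[batch_of]

  draws <- withr::with_seed(seed, list(
    a = stats::rnorm(n_animal, 0, config$sd_animal),
    s = stats::rnorm(length(strains), 0, config$sd_strain),
    b = stats::rnorm(config$n_batches, 0, config$sd_batch),
    e = stats::rnorm(n_animal * config$n_days)
  ))
  names(draws$a) <- animal_id
  names(draws$s) <- strains
  names(draws$b) <- batch_labels

  day <- rep(seq_len(config$n_days), times = n_animal)
  animal_ix <- rep(seq_len(n_animal), each = config$n_days)
  novelty <- config$mu + config$nu * exp(-(day - 1) / config$tau)
  resid_sd <- ifelse(day == 1L, config$kappa * config$sd_resid, config$sd_resid)
  value <- novelty +
    config$w[day] * draws$a[animal_ix] +
    draws$s[animal_strain[animal_ix]] +
    draws$b[animal_batch[animal_ix]] +
    resid_sd * draws$e

  tab <- behavior_table(data.frame(
    animal_id = animal_id[animal_ix],
    strain = animal_strain[animal_ix],
    experiment = animal_batch[animal_ix],
    day = day, measure = config$measure, value = unname(value),
    stringsAsFactors = FALSE
  ))
  tot <- config$sd_animal^2 + config$sd_strain^2 + config$sd_batch^2 + config$sd_resid^2
  truth <- structure(list(
    animal_effects = draws$a, strain_effects = draws$s, batch_effects = draws$b,
    R_star = config$sd_animal^2 / tot,
    R_single = config$sd_animal^2 / (config$sd_animal^2 + config$sd_resid^2),
    seed = seed, config = unclass(config)
  ), class = "ground_truth")
  list(table = tab, truth = truth)
}

#' Calibrated scenario mimicking the bundled study design
#'
#' Returns a [synthetic_config()] with the study-like design used throughout
#' the package's examples: 68 male mice in three inbred strains (38 C57BL/6J,
#' 15 BALB/cJ, 15 129S1/SvImJ), 7 daily open-field trials, two experimental
#' batches, a strong day-1 novelty elevation that decays within about two
#' days, individual intercepts that only express fully from day 2, modest
#' strain and small batch components. Two calibrations are provided:
#' distance-travelled-like (cm) and average-activity-like (percent).
#'
#' @param measure `"distance_cm"` or `"activity_pct"`.
#' @param seed Seed stored in the config.
#' @return A [synthetic_config()].
#' @export
studylike_scenario <- function(measure = c("distance_cm", "activity_pct"),
                               seed = 1L) {
  measure <- match.arg(measure)
  n <- c("C57BL/6J" = 38L, "BALB/cJ" = 15L, "129S1/SvImJ" = 15L)
  if (measure == "distance_cm") {
    synthetic_config(n_per_strain = n, n_days = 7L, n_batches = 2L,
                     mu = 350, nu = 590, tau = 0.6, sd_animal = 110,
                     w = c(0.3, rep(1, 6)), sd_strain = 60, sd_batch = 20,
                     sd_resid = 120, kappa = 2, measure = measure, seed = seed)
  } else {
    synthetic_config(n_per_strain = n, n_days = 7L, n_batches = 2L,
                     mu = 31, nu = 30, tau = 0.6, sd_animal = 6,
                     w = c(0.3, rep(1, 6)), sd_strain = 3, sd_batch = 1,
                     sd_resid = 5, kappa = 2, measure = measure, seed = seed)
  }
}

#' Generate a two-measure study-like dataset
#'
#' Convenience wrapper drawing both calibrated measures of
#' [studylike_scenario()] into a single table (distance and activity draws are
#' independent; animals, strains and batches are shared).
#'
#' @param seed Integer seed.
#' @return List with `table` (both measures) and `truth` (list of per-measure
#'   ground truths).
#' @export
generate_studylike <- function(seed = 1L) {
  dist <- generate_habituation(studylike_scenario("distance_cm"), seed = seed)
  act <- generate_habituation(studylike_scenario("activity_pct"), seed = seed + 1L)
  tab <- behavior_table(rbind(as.data.frame(dist$table), as.data.frame(act$table)))
  list(table = tab,
       truth = list(distance_cm = dist$truth, activity_pct = act$truth))
}
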