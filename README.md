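# habrep

**How long should laboratory animals be habituated to a test apparatus before
the experiment starts?** habrep answers this question from the habituation
data themselves. It is aimed at behavioral scientists running assays that
need a familiar environment (open-field baseline locomotion, wheel running,
burrowing, nest building): instead of copying an arbitrary habituation
length from the literature, you run the habituation phase, feed the daily
measurements to habrep, and get back a variance decomposition, a
repeatability trajectory, and a concrete recommended habituation length.

## The statistic at the core

Repeated measurements `y` (one trial per animal per day) are decomposed with
a Gaussian random-intercept mixed model fitted by REML,

    y = Xβ + Σ_g Z_g u_g + ε,   u_g ~ N(0, σ²_g I),   ε ~ N(0, σ²_ε I),

with grouping factors `g` ∈ {animal ID, strain, experimental batch}. The
repeatability (intraclass correlation) of factor `g` is its share of the
random variance,

    R_g = σ²_g / (Σ_h σ²_h + σ²_ε),

reported with a parametric-bootstrap percentile CI (500 runs), a permutation
p-value (100 permutations), and a boundary-corrected likelihood-ratio test
(p = ½·P(χ²₁ ≥ LRT)). Because novelty-driven day effects depress full-period
repeatability, habrep re-estimates single-factor R on sliding windows of
adjacent days (seven daily trials → windows 1–3, 2–4, …, 5–7) and applies a
plateau rule — R ≥ 0.4, CI excluding zero, drift ≤ 0.15 across later
windows — to find the first window with stable between-individual
differences. If that window starts on day *s*, testing can begin on the
window's last day: minimum habituation *s* − 1 days, recommended
*s* + width − 2 days.

A synthetic-data module generates habituation datasets with known ground
truth (exponential novelty decay, day-1 noise inflation, individual
intercepts that only express fully from day 2, strain and batch components),
so the entire pipeline is validated by parameter recovery without any
external data. A bundled example table
(`inst/extdata/synthetic_habituation.csv`, 68 animals × 7 days × 2
measures) is synthetic, drawn from this generator.

## Worked example

```r
library(habrep)

# a study-like dataset: 68 mice in 3 strains, 7 daily open-field trials,
# 2 batches, distance travelled (cm) and average activity (%)
sim <- generate_studylike(seed = 1)

# 1. day effects: is day 1 different?
friedman_dunn(sim$table, "distance_cm", control_day = 1)

# 2. which factor explains the variance over the whole period?
rpt(sim$table, "distance_cm", c("animal_id", "strain", "experiment"),
    settings = resampling_settings(n_boot = 500, n_permut = 100, seed = 1))

# 3. when do individual differences stabilize, and how long to habituate?
ws <- lapply(c("distance_cm", "activity_pct"), function(m)
  window_repeatability(sim$table, m, "animal_id",
                       settings = resampling_settings(seed = 1)))
recommend_start_day(ws)
```

Output (abridged):

```
Friedman test (chi-square approximation): Q = 161.6029, df = 6, p = 2.71e-32 (n = 68 animals)
Dunn's comparisons vs day 1 (Bonferroni-adjusted):
 day     z p_unadjusted p_adjusted
   2 5.319    1.043e-07  6.260e-07
   3 9.487    2.380e-21  1.428e-20
   ...

Repeatability, response 'distance_cm' (3 random factors)
      factor       R ci_low ci_high    p_lrt p_permut
1  animal_id 0.03260      0 0.09923 0.110567     0.15
2     strain 0.06278      0 0.23523 0.001043     0.01
3 experiment 0.00000      0 0.00000 0.500000     1.00

Window repeatability: measure 'distance_cm', random factor 'animal_id', width 3
 start_day end_day     R ci_low ci_high    p_lrt p_permut failed
         1       3 0.000  0.000   0.132 5.00e-01     1.00  FALSE
         2       4 0.359  0.214   0.500 6.37e-07     0.01  FALSE
         3       5 0.458  0.310   0.596 2.31e-10     0.01  FALSE
         4       6 0.456  0.322   0.578 2.85e-10     0.01  FALSE
         5       7 0.415  0.249   0.559 9.39e-09     0.01  FALSE

Habituation recommendation
  criteria: R >= 0.40, drift <= 0.15, CI excludes 0: TRUE
  distance_cm: first repeatable day 3, minimum 2 day(s), recommended 4 day(s)
  activity_pct: first repeatable day 2, minimum 1 day(s), recommended 3 day(s)
  overall: habituate for 4 day(s) before testing
```

Reading it: the Friedman test says day 1 differs massively from later days
(novelty). Over the full 7 days the animal's identity explains only a small
share of the variance — the day-1 novelty variance swamps it, which is why
full-period repeatability alone is misleading. The window trajectory shows
the first window (days 1–3) unstable and later windows at a plateau; with
the default plateau criteria the report recommends the habituation length
shown, meaning testing can start once that many daily exposures are done.
Because the window-2 plateau of the distance-like calibration sits near the
R ≥ 0.4 threshold, the recommendation on simulated cohorts of this size
fluctuates between 3 and 4 days across seeds — itself a useful reminder
that near-threshold plateaus at n ≈ 68 are genuinely ambiguous.

A thin command-line wrapper with `simulate`, `rpt`, `windows` and
`habituation` subcommands is included at `inst/cli/habrep`; the vignette
(`vignettes/habituation-repeatability.Rmd`) documents the model, the
numerical choices, the generator calibration, and the limitations.

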