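# cprkinemat

Kinematic analysis of rescuers performing continuous chest compressions
(CCC–CPR).

High-quality chest compressions — at least 50 mm deep at 100–120 per minute —
are the core survival predictor in cardiac arrest, yet there is little
quantitative guidance on *how a rescuer's body should be positioned* to
achieve and sustain that depth. Studies instrumenting kneeling rescuers with
inertial motion-capture suits while a manikin logs compression depth have
related the rescuer's joint angles and shoulder-girdle sway to compression
quality. `cprkinemat` implements that analysis pipeline end to end for
researchers in resuscitation biomechanics, together with a simulator that
generates the two measurement streams such an experiment produces, so every
stage can be validated against known ground truth.

## What it computes

**Kinematic features.** From landmark trajectories of a reduced nine-segment
body chain (hands, forearms, upper arms, trunk, upper legs, with the lower
legs as ground contacts):

- knee and elbow flexion angles (LKFA, RKFA, LEFA, REFA; 0° = straight limb),
- trunk inclination above the horizontal plane,
- the compression-axis deviation α — the angle between the palm → C7‑Th1
  line and the vertical. The vertical component of a compression force *F*
  applied at deviation α is *F·cos(α)*: still 98% of maximum at α = 10°,
  and about 91% at α = 25° (`vertical_force_fraction()`).

**Sway metrics.** The C7‑Th1 sensor trajectory, projected into the horizontal
or sagittal plane of the manikin's chest, is summarised the way posturography
summarises centre-of-pressure paths: the path length PL (total trajectory
length, mm) and the ellipse area EA (the 95% prediction ellipse of the
positions, `π · χ²₀.₉₅,₂ · √(λ₁λ₂)` from the covariance eigenvalues, mm²).

**Pipeline.** The manikin's depth log and the body-sensor stream do not share
a clock; `synchronize()` aligns them by cross-correlating the depth signal
with the negated vertical palm excursion. `detect_cycles()` finds individual
compressions (peak prominence + minimum separation), and
`build_feature_table()` assembles one row per minute: kinematics on the first
30 s of the minute, depth/rate over the full minute, with rows labelled
`deep`/`shallow` at a configurable depth threshold (default 40 mm).

**Statistics.** `standardized_ols()` regresses depth on rate, PL, LKFA and
LEFA, reporting raw coefficients *b*, standardized coefficients
β = b·sₓ/s_y, standard errors, t, p, adjusted R² and the overall F.
`compare_groups()` contrasts any feature across the depth groups (Shapiro–Wilk
gate routing to Student's t or an in-package Mann–Whitney U with exact
enumeration for small groups).

**Calibrated generator.** `generate_feature_table()` draws per-interval rows
whose *population* standardized coefficients equal a target β and whose
population R² hits a target (default 0.418), by solving the predictor
equicorrelation ρ from βᵀR(ρ)β = R² (ρ ≈ −0.166 at the defaults). This is the
workhorse for parameter-recovery studies of the regression.

## Worked example

```r
library(cprkinemat)

cfg <- trial_config(pose = reference_posture("correct"), duration_s = 300,
                    depth_mm = 45, depth_cv = 0.12, clock_offset_s = 0.8,
                    seed = 42)
trial <- generate_trial(cfg)
tab <- build_feature_table(trial$kinematic, trial$manikin, threshold_mm = 40)
tab[, c("minute_idx", "depth_mm", "rate_cpm", "pl_mm", "ea_mm2", "lkfa", "group")]
#>   minute_idx depth_mm rate_cpm pl_mm ea_mm2 lkfa group
#> 1          1    45.25      110  4046  496.4  109  deep
#> 2          2    44.31      110  4059  485.1  109  deep
#> 3          3    45.01      110  4012  494.7  109  deep
#> 4          4    44.73      110  4084  501.3  109  deep
#> 5          5    45.12      110  4129  493.5  109  deep
attr(tab, "lag_s")
#> [1] 0.8      # the injected 0.8 s clock offset, recovered
```

Depth and rate come back at their configured values (45 mm, 110 cpm), the
left knee flexion at its configured 109°, and the synchronizer recovers the
clock offset exactly. PL (~4 m per 30-s window) combines the configured
10 mm sway ellipse with 1 mm sensor noise.

Regression on a calibrated feature table:

```r
ft <- generate_feature_table(stats_gen_config(n_rows = 2000, seed = 42))
fit <- standardized_ols(ft[, c("rate_cpm", "pl_mm", "lkfa", "lefa")],
                        ft$depth_mm)
fit
#>   term        estimate std.error   beta se_beta statistic  p.value
#> 1 (Intercept) 12.3      1.62     NA     NA           7.62 3.98e-14
#> 2 rate_cpm     0.152    0.00734   0.375  0.0180     20.8  5.40e-87
#> 3 pl_mm       -0.00149  0.000104 -0.260  0.0181    -14.4  1.24e-44
#> 4 lkfa         0.177    0.0102    0.316  0.0182     17.3  1.30e-62
#> 5 lefa        -0.160    0.0124   -0.235  0.0181    -13.0  5.12e-37
#> adjusted R^2 = 0.422; F(4, 1995) = 365.47, p = 3.03e-236; residual SE = 3.075
```

The fitted standardized β sit around their population values
(0.364, −0.294, 0.291, −0.239) with adjusted R² near the 0.418 calibration
target. `tidy()` and `glance()` return these as tibbles; `autoplot()` methods
cover trials, pose series and sway ellipses, and `plot_feature_groups()`
draws the deep-vs-shallow box plots.

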