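---
title: "Models and methods behind cprkinemat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cprkinemat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprkinemat)
```

`cprkinemat` analyses the body kinematics of a kneeling rescuer performing
continuous chest compressions on a manikin. This vignette explains the models
the package implements, the choices made where the experimental conventions
leave room, and what its synthetic data can and cannot tell you about real
recordings.

## The measurement setting

Two devices observe one physical process. An inertial motion-capture suit
tracks the rescuer's body and exports landmark (joint-centre) positions at a
fixed rate; a sensored manikin logs compression depth on its own clock. The
package's frame is manikin-centred: x runs fore-aft along the manikin's
longitudinal axis, y lateral, z vertical, all in millimetres.

The body is reduced to a nine-segment chain — hands, forearms, upper arms,
trunk and upper legs, with the lower legs lying flat as ground contacts — the
segments that move meaningfully in a kneeling compression posture. Spine
curvature, head, and feet are not modelled: the angular features below do not
need them.

## Angular features

All flexion angles use the 0°-when-straight convention: the angle between the
proximal segment axis (proximal landmark → joint) and the distal axis (joint
→ distal landmark). Full joint-coordinate-system conventions would require
segment orientation triads; since the features of interest are uniaxial
flexion values, planar angles between adjacent segment axes reproduce them
without inventing unmeasured axes.

- Knee flexion: thigh axis (hip → knee) vs shank axis (knee → ankle).
- Elbow flexion: upper-arm axis (shoulder → elbow) vs forearm axis
  (elbow → palm centre).
- Trunk inclination: elevation of the hip-midpoint → C7‑Th1 axis above the
  horizontal plane (90° = upright).
- Compression-axis deviation α: the angle between the palm → C7‑Th1 line and
  the vertical. The line approximates the direction along which the rescuer's
  weight is delivered; the vertical (sternum-perpendicular) component of a
  force F applied along it is F·cos(α). An equivalent convention measures the
  same angle from the chest plane, α_chest = 90° + α; the package
  standardizes on deviation-from-vertical, 0–90°.

Per-window summaries use the mean of the per-frame angles. Whether published
joint-angle summaries refer to whole-cycle means or values at maximal
compression is generally unstated; the window mean is used because it is
stable and matches how depth and rate are summarised. Frames with degenerate
geometry (coincident landmarks) are flagged, never dropped, so the pose
series always has one row per input frame.

## Sway metrics

The C7‑Th1 trajectory, projected into the horizontal (x, y) or sagittal
(x, z) plane, is summarised with the two standard posturography statistics:

- **Path length (PL)**: the summed Euclidean distances between consecutive
  projected positions. No filtering is applied by default; sensor noise
  inflates PL, so an optional moving-average smoother is available
  (`smooth_window` in `build_feature_table()`, default off) and its use
  should be reported alongside results.
- **Ellipse area (EA)**: the area of the 95% prediction ellipse — centred at
  the sample mean, axes along the covariance eigenvectors, semi-axes
  √(χ²₀.₉₅,₂·λᵢ) with χ²₀.₉₅,₂ = 5.991. For bivariate normal sway this
  contains 95% of positions in expectation. "Contains 95% of positions" is
  sometimes read empirically instead; `method = "quantile"` rescales the
  ellipse to the 95th percentile of the observed squared Mahalanobis
  distances, making the inside fraction exactly 0.95 for any distribution.
  EA is an area and is reported in mm²; sway summaries quoted in "mm" for an
  ellipse area are best read as mm².

The headline PL/EA are computed on the horizontal projection; the sagittal
projection is available through `project_trajectory()`.

## The trial simulator

`generate_trial()` exists so that every downstream stage can be tested
against known ground truth. It poses the chain at a configured posture and
superimposes, per frame:

1. **Compression stroke.** A raised-cosine depth cycle at `rate_cpm` whose
   palm vertical excursion equals `depth_mm`, applied as a rigid vertical
   oscillation of the whole sensor cloud. The rescuer rides the recoiling
   chest, so the configured joint angles are carried through the cycle
   exactly; the alternative — pivoting the upper body about the knees —
   shifts window-mean knee angles by several degrees away from their
   configured values, which would make the simulator useless as ground truth
   for the angle extractor. The cost is that intra-cycle angle modulation is
   not emulated (see limitations).
2. **Depth variability.** A smooth random envelope with cycle-to-cycle
   coefficient of variation `depth_cv` (default 0.05, a typical human
   variability scale). Both streams share it, since they observe the same
   motion; it is also what makes synchronization well-posed — a perfectly
   periodic signal has no unique lag. Floor contact caps a rare over-deep
   stroke at the palm rest height.
3. **Sway.** An ellipse traced by the C7‑Th1 sensor, fore-aft semi-amplitude
   `sway_amp_mm` (default 10 mm) and lateral semi-amplitude half of that,
   phase-locked to the compression cycle. At the defaults this yields a
   horizontal-plane PL of roughly 2.5–4 m per 30-s window, the scale observed
   in real rescuers.
4. **Fatigue drift.** Linear per-minute changes to depth and/or pose angles
   (`drift`, default none).
5. **Noise.** I.i.d. Gaussian position noise, `noise_sd_mm` (default 1 mm,
   the scale of good optical/inertial landmark estimates).

The manikin stream is the palm excursion clipped at zero with
`clock_offset_s` added to its time stamps. The sampling rate defaults to
60 Hz, typical for inertial motion-capture exports. Identical configurations
(including `seed`) produce bit-identical output.

**Geometry conventions.** Knees rest on the floor a hip-half-width (100 mm)
either side of the mid-sagittal plane; shanks lie flat pointing backwards;
hip height follows from knee flexion and thigh length (an independent hip
height would over-determine the chain). Shoulders sit a half-width (180 mm)
either side of C7‑Th1; both palms meet at the manikin midline, a configurable
60 mm ahead of the shoulders, and the arms close the chain with the
configured elbow flexion split symmetrically about the shoulder→palm line.
The manikin chest height is therefore *emergent* (the palm rest height,
~57 mm at the default posture and anthropometry); configurations whose
nominal stroke would push the palm below the floor are rejected as
non-physical. Default segment lengths (hand 75, forearm 250, upper arm 300,
trunk 520, upper leg 460, lower leg 420 mm) are adult-scale conventions.

**Posture presets.** `reference_posture("correct")` is the configuration
reported for rescuers who achieve adequate depth: knee flexion 109° (left) /
97° (right), elbow flexion 14.1° (left) / 3.7° (right), trunk 23.4° above
horizontal. `"shallow"` reduces both knee flexion angles by 8°. The direction
follows the positive standardized effect of left knee flexion on depth and
the practical guidance that knee flexion should exceed 90°; narrative
accounts of knee-angle changes during deeper compressions are ambiguous about
sign, and the preset resolves the ambiguity in favour of the regression.

## Synchronization, cycles, windows

- `synchronize()` maximizes the normalized cross-correlation between the
  manikin depth and the negated vertical palm excursion over a ±5 s lag grid
  at the kinematic sample period. Both devices watch the same cycles, so the
  correlation peak is sharp; a peak below 0.5 aborts with an error rather
  than returning a meaningless lag.
- `detect_cycles()` takes local maxima with ≥ 10 mm prominence and ≥ 0.25 s
  separation (taller peaks win ties). Windows with fewer than two peaks get
  an undefined rate and a flag, never a fabricated value.
- `build_feature_table()` computes kinematic features on the first 30 s of
  each minute and depth/rate over the full minute — mirroring a protocol that
  records kinematics for 30 s at the top of each minute while depth/rate are
  averaged per 60 s. Both window lengths are arguments. Windows are half-open
  [start, end). Incomplete trailing minutes yield no row.
- `group_by_depth()` labels rows `deep` when mean depth ≥ threshold. The
  default threshold is 40 mm (a pragmatic minimum for manikins with stiff
  chests); 50 mm — the guideline target — is a one-argument change.

## The calibrated feature generator

`generate_feature_table()` works entirely in standardized space: predictors
z ~ N(0, R(ρ)) with equicorrelation ρ, standardized depth βᵀz + ε,
ε ~ N(0, 1 − R²). Given target β = (0.3639, −0.2939, 0.2909, −0.2391) for
(rate, PL, LKFA, LEFA) and target R² = 0.418, the solver picks the single ρ
with βᵀR(ρ)β = R² (≈ −0.166), erroring with the attainable R² range when no
positive-definite solution exists. Physical units come from configurable
means/SDs — rate (110, 10) cpm, PL (2600, 700) mm, LKFA (103, 7)°,
LEFA (9, 6)°, depth SD 4 mm about a 42 mm mean. These scales are conventions
chosen so that the implied raw coefficients land near published raw
regression coefficients for these predictors; the raw intercept is derived
from the chosen means rather than taken from any published equation, whose
mixed standardized/raw form does not pin down the predictor means.

One consequence worth flagging: with β_PL < 0, deeper intervals have *lower*
PL in generated tables — the conditional (regression) sign. Narrative
summaries of sway sometimes report the opposite *marginal* association
(longer paths in the deeper group). Under an equicorrelation structure the
marginal PL–depth correlation, (R β)_PL ≈ −0.36, cannot flip sign, so the
generator cannot reproduce both the coefficient table and that marginal
direction; it follows the coefficients, which are the quantitative anchor.

```{r calibration}
beta <- default_depth_betas()
rho <- solve_equicorrelation(beta, 0.418)
rho
R <- matrix(rho, 4, 4); diag(R) <- 1
drop(t(beta) %*% R %*% beta) # population R^2, exactly the target
```

## Statistical layer

`standardized_ols()` is ordinary least squares (QR-based, via the standard
linear-model fitter) with standardized coefficients β_j = b_j·s_xj/s_y and
their standard errors scaled identically, so t and p are shared between raw
and standardized forms. Rank-deficient designs error with the names of the
collinear columns. `compare_groups()` gates on per-group Shapiro–Wilk
normality at α = 0.05 — Student's t when both groups pass, otherwise the
Mann–Whitney U. The U statistic uses midranks; p values come from exact
enumeration of group assignments when either group has ≤ 8 observations
(capped at 5·10⁵ combinations), otherwise from the tie-corrected normal
approximation with a 0.5 continuity correction. P values are two-sided
throughout. Groups of fewer than 3 (or more than 5000) observations skip the
normality gate and route to the U test. No multiple-testing correction is
applied across features; per-minute rows from one rescuer are treated as
exchangeable observations, as the grouping analyses do.

## Problem sizes used in validation

The test suite and the reproduction script size their simulations to be
decisive yet quick: posture round trips use 60-s noiseless trials (3601
frames); synchronization is exercised over injected offsets
{−2, −0.5, 0, 0.7, 1.25, 2} s on 60-s trials; ellipse coverage uses 10⁵
bivariate-normal points; and regression recovery uses 50 replicates of 10⁴
rows, enough to pin mean β̂ to ±0.02 and mean adjusted R² to ±0.02 of their
calibration targets.

## What passing tests do and do not show

The simulator emulates cyclic, posture-stable compressions with Gaussian
sensor noise, smooth depth variability and deterministic elliptical sway. It
does **not** emulate: intra-cycle joint-angle modulation (the stroke is a
rigid translation), non-stationary or chaotic sway, sensor dropout and soft
tissue artefacts, orientation-estimation drift in inertial suits, rescuer
swaps, or interruptions. Consequently, green round-trip tests validate the
*estimators* (angles, PL/EA, synchronization, cycle detection, regression)
against a controlled truth; they do not certify accuracy on real suit exports,
where preprocessing quality dominates. The calibrated generator matches the
first- and second-moment structure of per-interval features, not their
time-series dependence: real per-minute rows from one rescuer are serially
correlated, so standard errors from real data need repeated-measures
handling that is outside this package's scope.

## Known limitations

- The compression-axis deviation is derived from two landmarks; it measures
  posture, not force, and inherits sway noise of the C7‑Th1 sensor.
- EA on noiseless simulated data reflects the deterministic sway ellipse
  (a few hundred mm²); realistic EA magnitudes require the noise and drift
  the generator adds, and real rescuers are messier still.
- The Mann–Whitney exact path enumerates assignments; for one tiny group
  against a very large one it falls back to the normal approximation when
  enumeration would exceed its cap.
- The regression treats rows as independent; see above.
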