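# gaitload

Gyroscope-based gait analysis of thoracic-pelvic sway and coordination
under manual load carriage.

Carrying hand-held loads — at one's sides or in front of the body —
systematically alters trunk and pelvis kinematics during walking, a risk
marker for work-related low-back injury. `gaitload` turns raw tri-axial
angular-velocity recordings from four body-worn gyroscopes (T6, S1, right
thigh, right shank; 80 Hz, degrees/s) into eleven per-gait-cycle
parameters and covariate-adjusted mixed-effects summaries, for
biomechanists and ergonomists studying load-carriage adaptations with
wearable sensors.

The pipeline:

* **Preprocessing** — zero-phase second-order Butterworth low-pass (2 Hz;
  two-pass gain $|H(f)|^2$, −6 dB at cutoff); gyro-bias removal;
  drift-limited per-cycle trapezoidal integration to angular displacement
  (trial-level integration + 0.75 Hz high-pass available via config).
* **Gait events** — mid-swing peaks of the shank sagittal angular
  velocity; heel-strike as the first local minimum after each peak,
  toe-off as the last before it; cycles delimited by consecutive
  heel-strikes, with sub-sample refinement and polarity auto-flip.
* **Stride length** — double-segment (thigh + shank) pendulum model:
  per-sub-phase segment rotations $\Delta\theta$ from integrated sagittal
  angular velocity, chord geometry $2L\sin(\Delta\theta/2)$, stance +
  swing displacement under left/right symmetry.
* **Sway and coordination** — per-cycle peak-to-peak ROM of T6 and S1 in
  the coronal/transverse/sagittal planes; continuous relative phase from
  amplitude-normalized phase portraits,
  $\phi(t) = \mathrm{atan2}(\bar\omega, \bar\theta)$, with the mean
  absolute wrapped pelvic−thoracic difference as the per-cycle mean
  relative phase (0° in-phase … 180° anti-phase); ensemble curves on a
  0–100% gait-cycle grid.
* **Statistics** — per-parameter linear mixed-effects models
  (mode × load + centered relative speed, participant intercept +
  covariate slope + participant-by-condition component), Satterthwaite
  Type-III F tests, estimated marginal means at the covariate mean, and
  Bonferroni-adjusted pairwise contrasts; `tidy()`/`glance()` methods and
  `autoplot()` displays.
* **Synthetic gait generator** — four-site trials with exact ground truth
  for events, stride length, sway amplitudes and imposed thoracic-pelvic
  phase lags; presets for two repeated-measures study designs
  (9 × 8 × 2 trials / 720 analyzed cycles and 10 × 8 × 1 trials / 797
  analyzed cycles), condition-effect presets, and a simulated rigid
  pendulum fixture for validating the integration chain.

## Worked example

```r
library(gaitload)

design   <- generate_design("expt1", master_seed = 1)  # 144 trials
features <- process_design(design)                     # 720 cycles
res      <- analyze_gait(features, responses = "mrp_coronal")
res$models$mrp_coronal
```

```
<gait_lmm> response: mrp_coronal
  model: full (participant intercept + covariate slope + condition component)
                     term         F df1   df2         p
1              carry_mode 2268.9172   1 53.87 1.029e-45
2                    load   59.0989   3 55.96 2.388e-17
3 centered_relative_speed    0.4061   1  4.11 5.577e-01
4         carry_mode:load  327.0096   3 55.83 2.235e-35
```

The carrying mode, load level and their interaction all shift coronal
thoracic-pelvic coordination in this simulated cohort. The estimated
marginal means (degrees, at the covariate mean) show where:

```r
emm_table(res$models$mrp_coronal)
#>   carry_mode load emmean    se
#>       side   NL 110.90 3.094
#>   anterior   NL 110.74 3.096
#>       side    L 115.78 3.099
#>   anterior    L  85.01 3.094
#>       side    M 117.25 3.094
#>   anterior    M  87.37 3.092
#>       side    H 132.67 3.095
#>   anterior    H  79.50 3.096
#>     pooled   NL 110.82 3.036
```

Coordination grows more out-of-phase with load in the side carry (110.9°
at no load to 132.7° at 13.6 kg) and more in-phase in the anterior carry
(down to 79.5°), so the Bonferroni mode contrasts separate at every loaded
level but not at the shared empty-handed reference:

```r
bonferroni_contrasts(res$models$mrp_coronal) |>
  dplyr::filter(family == "mode_within_load")
#>   by        contrast estimate   se    p_adj
#>   NL side - anterior    0.156 1.20 8.98e-01
#>    L side - anterior   30.774 1.22 2.87e-32
#>    M side - anterior   29.882 1.20 1.07e-31
#>    H side - anterior   53.171 1.20 1.11e-44
```

These estimates recover the generator's imposed condition offsets (for
example +23.6° side-high and −30.2° anterior-high relative to a ~110°
no-load lag). A thin CLI wraps the same functions:
`gaitload simulate … | gaitload process … | gaitload analyze …`.

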