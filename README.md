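# onhmorph

Optic nerve head (ONH) morphometrics from segmented OCT geometry, for
studying how axial myopia reshapes the glaucomatous disc.

Myopic eyes are elongated, and the stretching tilts and reorients the optic
nerve head. That confounds the OCT metrics glaucoma care relies on —
circumpapillary retinal nerve fiber layer (RNFL) thickness and neuroretinal
rim width — which are judged against normative databases of mostly
non-myopic eyes. `onhmorph` measures the disc from the *Bruch's membrane
opening* (BMO), the objective anatomical aperture visible in OCT, instead of
the subjective photograph-based disc margin:

* **BMO ovality index** — minor/major axis ratio of the ellipse fit (by
  direct constrained conic least squares) to the 48 BMO points projected
  onto the BMO plane; 1 = circular.
* **BMO tilt angle** — angle between the normals of total-least-squares
  planes fit to the BMO points and to the peripheral Bruch's membrane
  boundary (BMB) points: tilt = arccos |n₁·n₂|. An independent
  cross-validation variant takes membrane reference points at a fixed
  1700 µm radius instead of the scan edges.
* **BMO rotation angle** — angle of the undirected semimajor axis against
  the temporal horizontal, individualized by the fovea–BMO-center (FoBMO)
  angle and folded into [0°, 90°].
* **BMO area** — πab of the fitted ellipse, mm².
* **BMO-MRW** — minimum rim width: shortest distance from each BMO point to
  the ILM polyline of its radial scan.
* **RNFL thickness and peripapillary choroidal thickness (PCT)** from the
  3.5 mm circle scan, the latter as the distance along the local Bruch's
  membrane normal; all thickness metrics reported globally and in the six
  Garway-Heath sectors (T/ST/SN/N/IN/IT), placed relative to the FoBMO axis.

Cohort statistics mirror clinical practice for paired-eye data: axial myopia
grouping (AL ≤ 24 / 24–26 / > 26 mm), eye-level linear mixed models with a
patient random intercept (REML), Satterthwaite degrees of freedom, pairwise
group contrasts, Pearson correlations, and the Edwards semi-partial
R² = (ν₁/ν₂·F)/(1 + ν₁/ν₂·F) as effect size.

Because segmented ONH geometry of this kind is not publicly deposited, the
package ships a seeded synthetic generator (`simulate_eye()`,
`simulate_cohort()`) that emits radial-scan and circle-scan geometry with
exact, configurable ground truth — every stage of the pipeline is testable
closed-loop without any download.

## Worked example

Simulate one highly myopic eye (true tilt 3.4°, rotation 36.7°, ovality
0.85, 5 µm point noise) and measure it:

```r
library(onhmorph)

params <- synthetic_eye_params(true_tilt_deg = 3.4, true_rotation_deg = 36.7,
                               true_ovality = 0.85, point_noise_sd_um = 5)
eye <- simulate_eye(params, seed = 42)

compute_bmo_morphometrics(eye$scans)
#> BMO morphometrics, eye synthetic:
#>   ovality index 0.848 | tilt 3.43 deg | rotation 36.4 deg | area 2.034 mm^2

crossval_tilt(eye$scans)      # fixed-radius variant: 3.43 deg
compute_mrw(eye$scans)$summary
#> Sector summary (um): global 198.7
#>     T    ST    SN     N    IN    IT
#> 146.1 179.2 222.8 230.5 247.0 180.3
```

The measured values sit within the noise of the configured truths; with
`point_noise_sd_um = 0` they match to 1e-6.

Simulate a clustered cohort (452 eyes, 277 patients, two eyes for many
patients) whose true tilt rises with axial length at 0.45 °/mm, and fit the
random-intercept mixed model:

```r
spec <- table1_cohort_spec()
spec$outcomes$tilt_deg <- outcome_spec(mean = c(no = 1.7, mild = 2.0, high = 3.4),
                                       sd = 1.3, patient_sd = 0.6,
                                       slope_al = 0.45, lower = 0, upper = 89)
tab <- simulate_cohort(spec, seed = 42)
fit <- fit_lmm(tab, "tilt_deg", fixed = "al_mm")
fit
#> Linear mixed model for `tilt_deg` (REML, Satterthwaite df): 452 eyes, 277 patients, 0 dropped
#>   patient SD 0.5076, residual SD 1.252
#>          term estimate      se    df    ci_lo  ci_hi         p
#> 1 (Intercept)  -8.4290 1.28037 307.9 -10.9484 -5.910 1.984e-10
#> 2       al_mm   0.4322 0.05173 311.6   0.3305  0.534 2.175e-15
```

The slope estimate 0.432 (95% CI 0.331–0.534) °/mm recovers the configured
0.45 within its confidence interval, with degrees of freedom between the
patient and eye counts as the within-patient correlation demands.

An end-to-end run (simulate → quality filter → morphometrics → thickness →
statistics, with CSV outputs and an exclusion log) is available through
`run_pipeline(run_config(...))`, and a thin command-line wrapper lives at
`inst/scripts/onhmorph.R` (`simulate`, `morph`, `thickness`, `stats`,
`pipeline` subcommands; exit codes 0/2/3).

## Package layout

* `R/` — geometry (`fit_plane`, `fit_ellipse_2d`, `project_to_plane`),
  morphometrics (`compute_bmo_morphometrics`, `crossval_tilt`), thickness
  (`compute_mrw`, `compute_rnfl_thickness`, `compute_pct`, `sectorize`),
  statistics (`fit_lmm`, `group_comparison`, `semi_partial_r2`,
  `pearson_corr`), synthetic data, JSON/YAML/CSV I/O, pipeline runner.
* `vignettes/onh-morphometry.Rmd` — the measurement model, conventions and
  design decisions in detail.
* `tests/testthat/` — unit, property and closed-loop recovery tests.
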