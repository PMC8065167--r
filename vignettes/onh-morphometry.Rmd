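---
title: "Optic nerve head morphometrics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optic nerve head morphometrics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onhmorph)
```

## The measurement problem

In axially myopic eyes the optic nerve head is stretched and reoriented, which
confounds the standard glaucoma metrics (circumpapillary RNFL thickness,
neuroretinal rim width) that are referenced against normative databases of
mostly emmetropic eyes. `onhmorph` quantifies the three-dimensional
configuration of the disc from the *Bruch's membrane opening* (BMO) — the
objective, OCT-visible aperture through which the axons exit — rather than
from the subjective clinical disc margin seen on photographs.

The package consumes segmented scan geometry, not raw images: per eye, 24
radial B-scans (7.5° apart) each contribute two BMO points, two peripheral
Bruch's-membrane-boundary (BMB) points at the scan edges, and an internal
limiting membrane (ILM) polyline; a 3.5 mm circle scan contributes per-A-scan
boundary depths (ILM, RNFL posterior, BM posterior, choroid posterior).
Automated layer segmentation itself (deep-learning or instrument software) is
upstream of this package and out of scope.

## Morphometric model

All geometry lives in physical micrometers in a right-handed frame
(x temporal→nasal, y inferior→superior, z anterior→posterior). Left eyes are
mirrored into this OD frame exactly once on ingest (en-face x negated, FoBMO
angle sign flipped), guarded by a `normalized` flag.

Given the 48 pooled BMO points and 48 pooled BMB points:

1. **Plane fits.** A plane is fit to each point set by *orthogonal* (total)
   least squares — the eigenvector of the smallest eigenvalue of the centered
   scatter matrix. A functional fit of z on (x, y) would make the result
   depend on the arbitrary device frame; the orthogonal fit is rotation
   invariant, which matters because the tilt angle is defined from these
   planes. Normal signs are fixed (positive z, ties towards +x then +y) and
   the tilt uses |cos|, so the sign convention is observationally irrelevant.
2. **Tilt angle** = arccos |n_BMO · n_BMB| ∈ [0°, 90°].
3. **Projection.** BMO points are projected orthogonally onto the BMO plane
   and expressed in the in-plane basis (e₁, e₂), where e₁ is the unit
   projection of the temporal horizontal axis onto the plane and
   e₂ = n × e₁. This anchors in-plane angles to the temporal axis, as the
   rotation convention requires. The basis degenerates only at 90° tilt.
4. **Ellipse fit.** A direct least-squares conic fit with the ellipse
   constraint 4ac − b² = 1 (Halir–Flusser's numerically stable partitioning
   of the Fitzgibbon method), after centering/scaling for conditioning. The
   constrained fit is exact on noiseless conic samples and always returns an
   ellipse; in pathological configurations it falls back to second-moment
   (covariance) axes and flags the result.
5. **Ovality index** = semi-minor / semi-major ∈ (0, 1].
   **BMO area** = πab in mm².
   **Rotation angle** = the undirected major-axis angle minus the FoBMO
   angle, folded into [0°, 90°].

### Conventions that the source definitions leave open

* **Fold range.** Whether the rotation angle lives in [0°, 90°] or [0°, 180°)
  is not fixed by the definition (group means near 36° cannot disambiguate).
  The fold into [0°, 90°] is adopted: it treats the major axis as undirected
  and represents both typical group means (~36°) and large single-eye values
  (e.g. 72.4°).
* **Near-circular openings.** At ovality above 0.99 the major-axis direction
  is numerically meaningless, so the rotation is reported as 0 with a
  `circular` flag rather than as noise.
* **In-plane vs en-face angle.** The axis angle is measured inside the BMO
  plane against the projected temporal axis. An en-face convention would
  differ at second order in the tilt (< 0.06° at 4° tilt), far below the
  population spread; the in-plane choice keeps the ellipse fit and the angle
  in one coordinate system.
* **Cross-validation tilt.** The independent tilt variant replaces the
  scan-edge BMB points with reference points at a fixed 1700 µm en-face
  radius from the BMO center, interpolating the membrane linearly along each
  scan. On a planar membrane both estimates coincide exactly.

## Thickness metrics

* **BMO-MRW**: per BMO point, the minimum Euclidean distance to the scan's
  ILM polyline (minimum over point-to-segment projections); 48 values per
  eye, averaged globally and by sector.
* **RNFL thickness**: RNFL posterior minus ILM depth per A-scan of the
  3.5 mm circle.
* **Peripapillary choroidal thickness (PCT)**: choroid posterior minus BM
  posterior. "Perpendicular" is implemented as the distance along the local
  BM normal in the unrolled B-scan plane — the axial separation times
  cos(φ), with the BM inclination φ from central differences along the arc
  (one-sided at the profile ends). A plain axial mode is selectable. With
  boundary noise the finite-difference slope is biased away from zero, which
  biases normal-mode PCT downward by ≈1% at 3 µm noise on a 768-A-scan
  profile; this is inherent to the unsmoothed local-normal definition and is
  documented rather than corrected.

Sector summaries use the Garway-Heath map at the instrument's published
limits in FoBMO-relative angle ψ: temporal [315°, 45°), superotemporal
[45°, 85°), superonasal [85°, 125°), nasal [125°, 235°), inferonasal
[235°, 275°), inferotemporal [275°, 315°). The six sector names are standard;
the degree limits are the reporting convention adopted here. Sector means are
arithmetic means of member A-scans (or member BMO points for MRW) and the
global value is the mean over all members, so it always equals the
count-weighted mean of the sector means.

Scans with quality score strictly below 15 dB are excluded; a score of
exactly 15 is included. (The source material states the rule once as
"quality score < 15" excluded and once as "> 15 dB" included; the strict
"< 15 excludes" reading is adopted.)

## Synthetic geometry generator

Because no public dataset carries this segmented geometry, the generator is
first-class, tested code and defines the study conditions for every
closed-loop check:

* The BMO ellipse (semi-major a, semi-minor a·ovality) is constructed
  *inside* a plane tilted by the true tilt about an in-plane axis relative to
  the flat membrane plane, with its major axis set so the measurement
  convention (fold of in-plane axis angle minus FoBMO) returns exactly the
  configured rotation. Truth and measurement definitions therefore coincide
  by construction, and with all noise at zero the pipeline reproduces every
  configured value to ≤ 1e-6.
* Each radial scan contributes the two ellipse points lying along its
  en-face direction, plus two membrane points on a 2500 µm ring at the scan
  edges.
* The ILM polyline of each half-scan is a straight rim segment placed at
  exactly the configured minimum-rim-width distance from the true BMO point
  (15° inclination by default), joined by cup and peripheral vertices that
  are provably never the closest feature for rim widths under ~500 µm. The
  noiseless MRW truth is therefore exact, not approximate.
* Thickness profiles (MRW, RNFL, choroid) can be constants, per-sector
  values (piecewise constant in ψ, making sector-mean truths exact), or
  arbitrary functions of ψ.
* Noise: isotropic Gaussian on every BMO/BMB point and ILM vertex (default
  SD 5 µm, a plausible device-scale segmentation jitter) and independent
  Gaussian depth noise on each circle-scan boundary (default 3 µm). The
  default quality score is 25 dB (passing); exclusion logic is exercised by
  overriding it.
* Left eyes are emitted in the mirrored OS device frame to exercise
  laterality handling end to end.

What the generator does **not** emulate: speckle or any raster-image
properties, segmentation failure modes, peripapillary atrophy, staphyloma,
or curvature of Bruch's membrane (the synthetic membrane is planar, which
makes the primary and fixed-radius tilt estimates nearly collinear rather
than merely highly correlated). Passing closed-loop tests therefore
demonstrates correctness of the measurement pipeline under the stated noise
model, not robustness to real-world segmentation pathology.

The cohort simulator reproduces the study's statistical structure: group
sizes are exact; patients are filled with two eyes until the eye budget
forces one-eye patients; axial length is drawn from a truncated Gaussian per
group — (−∞, 24], (24, 26], (26, ∞) mm — with the latent location solved by
root finding so the *truncated* mean equals the configured group mean; eyes
of one patient share a Gaussian random intercept per outcome; and outcome
truths can be linked linearly to axial length. Group SDs default to values
derived from the reported 95% confidence intervals (sd = halfwidth·√n/1.96).

## Statistical pipeline

Eye-level outcomes are modeled as `outcome ~ fixed effects + (1 | patient)`
fit by REML (lme4), with Satterthwaite denominator degrees of freedom and
type-III F-tests (lmerTest). Confidence intervals use the t quantile at the
per-contrast df. The Edwards semi-partial R² for an effect with F statistic
F and degrees of freedom ν₁, ν₂ is (ν₁/ν₂·F) / (1 + ν₁/ν₂·F); marginal
(type-III) F statistics are used, since the sequential alternative is not
identified by the source description. No multiplicity adjustment is applied
anywhere; pairwise group contrasts are t-tests of regression parameters with
the relevant reference level, marked at p < 0.05. Patient-level variables
use one row per patient (ANOVA for continuous, chi-squared for categorical).

Two degenerate cases are handled exactly rather than numerically:

* one eye per patient — the random intercept is unidentifiable and REML
  optimizers misbehave; the model provably reduces to OLS, so the OLS fit
  (exact residual df) is returned, flagged;
* outcome and covariates exactly constant within every patient — the model
  reduces to the patient-level regression (residual variance 0); the
  collapsed fit is returned with the spread assigned to the intercept.

Negative variance components are clipped at zero with a boundary flag, the
standard constrained-REML behavior.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use 200 eyes per recovery target,
200 replicate cohorts (~450 eyes each) for slope recovery, and 1000
replicates of a 84-eye null cohort for type-I-error calibration — sizes at
which Monte-Carlo error is comfortably below the recovery tolerances while a
full run stays in the minutes range on one core. Noiseless closure is
asserted at 1e-6 relative; plane/ellipse oracle agreement at 1e-9; the
calibration band is 5% ± 3 binomial standard errors. Collinearity in the
plane fit is declared when the second eigenvalue falls below 1e-12 of the
largest; the ellipse fit rejects inputs with fewer than 5 points.

## Known limitations

* The rotation angle is undefined for circular openings and unstable near
  ovality 1; consumers should respect the `circular` flag.
* Normal-mode PCT carries the ≈1% finite-difference noise bias described
  above.
* The generator's planar membrane cannot probe how the fixed-radius tilt
  variant diverges from the primary tilt on strongly curved membranes.
* `fit_lmm` covers random-intercept models only — no random slopes, no
  longitudinal correlation structures, and no imputation of missing values
  (listwise deletion with reporting).
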