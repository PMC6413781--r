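---
title: "Quantifying pigmentation outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pigmentation outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

melaquant implements the measurement and analysis chain used to quantify
melanin pigmentation in small trials of oculocutaneous albinism (OCA):
automated scoring of iris transillumination (TI) photographs, aggregation
and reliability analysis of a human grading panel, the melanin (M) index
from diffuse reflectance spectra, chemical hair-melanin markers, and
longitudinal change-from-baseline models. A synthetic-cohort generator with
explicit ground truth ties the stages together for validation. This
vignette explains each model, the tunable parameters, and the design
choices made where the methodology left room.

## Semiquantitative iris TI scoring

In albinism, light reflected from the retina shines back through a
melanin-deficient iris; the amount of transillumination is therefore an
inverse marker of iris melanin. Photographic grading uses an 8-point scale
(0 = no transillumination, 8 = maximal). The automated counterpart works on
an annotated anterior-segment photograph:

1. **Geometry.** An operator supplies the iris circle (centre, radius) and
   the pupil radius (`iris_geometry()`). The package performs no
   segmentation; the annotation is an input, as in manual practice.
2. **Sampling layout.** The iris bounding square is divided into four
   quadrants through the centre and each quadrant into four equal
   sub-squares; the 16 sub-square centres — offsets of (±R/4, ±3R/4) in each
   axis — carry sampling disks (`sampling_layout()`). The nominal disk
   radius is 75 px at a reference iris radius of 1000 px (the scale of a
   hand-drawn circle on a native 3504 × 2336 frame) and scales linearly
   with the annotated radius; both the disk radius and the reference are
   arguments.
3. **Masked smoothing and measurement.** At each retained site the red
   channel is smoothed with a Gaussian kernel (`blur_sigma`, default 25 px
   at the reference scale) and averaged over the disk ∩ annulus pixels;
   the mean of per-site means maps linearly to the score:
   `score = 8 × mean(red) / 255`.

Two geometric hazards motivate the masking rules. The four inner sites can
dip into the pupil, through which the *retinal red reflex* — saturated red,
unrelated to iris melanin — is visible; the four corner sites can leave the
iris circle entirely. Disks are therefore intersected with the open annulus
`pupil_radius < r < iris_radius`, and sites whose disk has no overlap at
all are excluded and reported with a reason. For the same reason the
Gaussian smoothing is a *normalised masked* blur: the smoothed value at an
annulus pixel is a Gaussian-weighted average of annulus pixels only, so
neither the bright pupil nor the dark background bleeds into the signal.
This makes the score of a constant-red annulus exactly equal to the plain
mean, independent of `blur_sigma` and disk size — a tested property — and
makes the score insensitive to the (tool-dependent) blur convention.

The linear 0–8 map is the simplest monotone calibration consistent with
0 = no transmitted light and 8 = fully saturated reflex; whether historical
analyses rescaled against a per-session reference is unknowable, so the map
is a declared convention of this package, isolated in one place.

## The grading panel and its reliability

Human grading uses the same 0–8 scale with one-decimal resolution. Panel
aggregation is two-stage (`panel_scores()`): each grader's grades are
averaged over the (typically two) images of an eye-visit, then averaged
across graders. Reliability (`intergrader_icc()`) treats graders as a
random sample and participants as targets: a two-way random-effects,
absolute-agreement intraclass correlation computed from the ANOVA mean
squares of the participants × graders matrix of per-grader image means.
The single-measure form ICC(A,1) — the reliability of one grader — is
primary because it is the conservative choice; the average-measure form
ICC(A,k) is reported alongside. Confidence intervals use the
mean-square/Satterthwaite construction of McGraw & Wong; the
average-measure interval is the Spearman–Brown transform of the
single-measure one. Panels are required to be complete by default;
`allow_missing = TRUE` enables complete-case analysis.

Agreement between the automated and human routes (`method_correlation()`)
is a Spearman rank correlation over eye-visit pairs pooled across eyes and
visits, matching how the two score sets are compared graphically.

## The melanin index

Diffuse reflectance spectrophotometry measures percent reflectance (PR) at
10 nm steps from 400–700 nm against a white standard. Melanin content is
summarised in the 640–670 nm band, where haemoglobin absorbs little:

$$E = \frac{(PR_{650} + PR_{660} + 0.5\,PR_{640} + 0.5\,PR_{670})/3}{100},
\qquad M = 100 \log_{10}(1/E).$$

A perfect reflector gives M = 0; a uniform 10% band gives M = 100; scaling
the band by 10 shifts M by exactly −100. Replicates (five per body site per
visit) are aggregated by averaging their M indices — M being the analysed
quantity — with wavelength-wise spectrum averaging available as an
alternative (`summarize_site(aggregate = "mean-spectrum")`); the two
differ by a Jensen gap when replicates differ. Hair spectra are processed
identically under the site label `hair`. Session quality is screened by
`calibration_check()` (white ≈ 100%, light trap ≈ 0%, default tolerance
±2 percentage points). A related "AM index" appears in some reports without
a printed definition; it is deliberately not computed here.

## Hair melanin markers

PTCA (an oxidation product proportional to eumelanin) and 4-AHP (a
hydrolysis product proportional to pheomelanin) are consumed as
concentrations in ng/mg hair. `marker_change_summary()` reports the mean
and sample (n−1) SD of change from each participant's earliest baseline,
and adds a per-record PTCA/4-AHP ratio as a convenience output of this
package (flagged as such; it is not part of the original reporting
conventions).

## Longitudinal analysis

Change from baseline (`change_from_baseline()`) uses each unit's earliest
visit with data as baseline and reports both conventions used for
endpoints: the *directional* mean (SD) of signed changes and the
*absolute* mean (SD) of their magnitudes. With eye-level data the summary
is given per eye (OD, OS) and pooled over all eye-level changes (OU).

`fit_longitudinal()` fits, by REML via `nlme::lme`, a linear mixed model
with visit month as a categorical fixed effect (baseline reference), so
each coefficient is the modelled mean change from baseline at that visit.
Participants contribute a random intercept and, by default, a random slope
in months; when both eyes are analysed together, an eye-within-participant
random intercept nests eyes inside participants. No eye fixed effect is
included by default — eyes enter only through nesting. The random
intercept induces the classical compound-symmetry marginal covariance
(equal variances, equal correlations regardless of time gap); a separate
exchangeable residual correlation on top of the random intercept would be
weakly identified at these sample sizes, so it is not added.

If the intercept + slope model fails to converge — an optimizer error or a
slope standard deviation collapsing below 10⁻⁶ of the residual SD — the
model is refitted with a random intercept only, with a message and a
`fallback_applied` flag. This automatic cascade mirrors what an analyst
does when a small cohort cannot support a slope variance. Confidence
intervals and p-values use the normal approximation on the fixed effects
by default (`df_method = "contain"` exposes the containment-t
alternative); at the validation scale below, the normal intervals achieve
close to nominal coverage, while in 5-participant cohorts they should be
read as approximate. P-values are labelled by `significance_label()` under
the 0.05 / 0.10 ("significant" / "moderately significant") convention with
no multiplicity adjustment — the convention of exploratory pilot analyses.

## The synthetic cohort

`cohort_truth()` fixes the generating model; `generate_cohort()` draws a
full input bundle deterministically from it (each data stream is seeded
independently from the master seed, so e.g. the grade table is identical
whether or not images are generated).

The latent eye-visit score is
$$L(i,e,t) = \mu + b_i + s_i t + c_{ie} + \delta_t, \qquad
b_i \sim N(0, \sigma_b^2),\; s_i \sim N(0, \sigma_s^2),\;
c_{ie} \sim N(0, \sigma_e^2),$$
clamped to [0, 8]. Grades add a grader bias γ_g ~ N(0, 0.3²) and per-grade
noise ε ~ N(0, 0.5²), are clamped, and are rounded to one decimal. Images
encode L in the annulus red channel with Gaussian pixel noise
(`image_noise_sd`, default 3 intensity units) and a saturated red pupil,
so the scorer's pupil masking is genuinely exercised. Spectra are rendered
so that the melanin band reflects exactly `100 × 10^(−m/100)` for the
replicate's target m — the index inverts them exactly — while off-band
wavelengths follow a rising ramp the index must ignore.

Defaults mirror the emulated study design: 5 participants, two eyes,
visits at months 0, 3, 6, 9, 12, 15, 18 (the two baseline visits collapsed
to month 0; `second_baseline = TRUE` adds a month-1 baseline to exercise
the earliest-baseline rule), 18 graders, 2 images per eye-visit. True visit
effects ramp to +1.0 score units at month 12 and hold. Where the emulated
study prints a quantity, the default truth uses it (hair marker baselines
and shifts, site-level M-index shifts, the 4.6-letter month-12 gain);
variance components are never printed at participant level, so
σ_b = 1.0, γ-SD = 0.3, ε-SD = 0.5 follow the stated design regime and
σ_s = 0.03/month, σ_e = 0.2, and the reflectometry/hair dispersions are
package choices held fixed. The eye-level intercept c_ie is likewise a
package addition (the latent model would otherwise be identical in both
eyes, making eye nesting vacuous); `eye_sd = 0` removes it.

`simulate_latent_scores()` is the lightweight companion used for
estimator-validation studies: latent trajectory plus independent
measurement noise, *without* clamping, so the generating process matches
the fitted model exactly and recovery is unbiased. What passing tests on
these synthetic data do **not** show: robustness to real-world iris
texture, flash artefacts, annotation error, grader drift over sessions, or
missing-visit patterns — none of which the generator emulates.

## Numerical conventions and validation scales

* Pixels are addressed by 0-based continuous coordinates; a pixel belongs
  to a disk or annulus if its centre does (annulus bounds strict).
* Site exclusion uses the exact geometric disk–annulus overlap test; the
  test suite checks it against a dense sampling oracle on random
  geometries.
* An 8-bit annulus level quantises the latent score with a maximum
  round-trip error of 8 × 0.5/255 ≈ 0.016 score units.
* Grades round half to even at one decimal (R's rounding); ties in the
  Spearman correlation use midranks.
* ICC requires non-constant grades and ≥2 participants and graders;
  degenerate perfect agreement reports a [1, 1] interval.
* The estimator-calibration study in the test suite and acceptance script
  uses 200 cohorts of 100 participants with residual SD 0.5 — large enough
  that the month-12 bias bound (0.02 score units) and the 90–99% coverage
  band are sharp, while one run stays under a minute. The end-to-end
  pipeline check uses the default 5-participant cohort (140 rendered
  images) and verifies byte-identical reruns.

## Known limitations

* The 0–8 calibration of the automated score is linear by convention;
  agreement with human panels is monotone rather than unit-for-unit (the
  automated range is typically compressed), which is why the method
  comparison is rank-based.
* The renderer produces flat, noise-perturbed annuli; it validates the
  measurement chain, not the photography.
* Normal-approximation intervals are anti-conservative for very small n;
  the containment-t option mitigates but does not remove this.
* Visits are analysed at nominal months; actual-date offsets are out of
  scope, as are imputation of missing visits and multiplicity adjustment.
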