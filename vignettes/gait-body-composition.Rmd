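---
title: "Center-of-mass gait dynamics and body composition: methods"
author: "comgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center-of-mass gait dynamics and body composition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comgait)
```

## The problem

Mobility decline in older adults is usually assessed with contact
instruments or clinical batteries such as the Short Physical Performance
Battery (SPPB). A camera plus a pose estimator offers a contactless
alternative: a PoseNet-style network emits, per video frame, 17 COCO-
numbered keypoints with pixel coordinates and confidence scores. From
those, `comgait` derives a small set of dynamic gait features and relates
them to static body-composition indicators measured by bioimpedance
(InBody-style devices), with particular interest in early sarcopenia
screening.

## The feature model

For each frame the center of mass (CoM) is the unweighted mean of five
upper-body keypoints -- nose (0), left/right shoulder (5, 6) and
left/right hip (11, 12):

$$x_{center} = \frac{1}{|K|}\sum_{i\in K} x_i,\qquad
  y_{center} = \frac{1}{|K|}\sum_{i\in K} y_i,\qquad |K| = 5.$$

Between consecutive frames, the **center displacement** is the Euclidean
distance

$$d_t = \sqrt{(x_{c,t}-x_{c,t-1})^2 + (y_{c,t}-y_{c,t-1})^2}
  \quad\text{(pixel/frame)},$$

and the **directional shift** is the arctangent of the step ratio

$$\theta_t = \arctan\frac{y_{c,t}-y_{c,t-1}}{x_{c,t}-x_{c,t-1}}
  \in (-\pi/2, \pi/2).$$

The ratio form is deliberately literal. Its degenerate cases are fixed by
convention: $\theta = +\pi/2$ for a purely downward step
($\Delta x = 0$, $\Delta y > 0$), $-\pi/2$ for purely upward, $0$ for a
stationary CoM. A full signed `atan2` angle is available
(`computeDynamics(..., angleMethod = "atan2")`) but is not the default,
because the ratio definition is the one the per-participant summaries are
built on.

Per participant, `aggregateFeatures()` reports the mean and sample
variance ($n-1$ denominator) of the directional shift and the mean
displacement. Two definitions of "directional shift magnitude" are
supported because the field uses both and they have different units:

* `mode = "angular"` (default): mean of $|\theta_t|$, radians. Bounded by
  $\pi/2$ and scale-free (invariant to camera distance).
* `mode = "horizontal"`: mean of $|\Delta x_t|$, pixel/frame. Shares the
  unit of the displacement but scales with camera geometry.

Both are computed in every pipeline run; the run log records the
alternative so the choice is always auditable. The default is angular
because a scale-free summary is more comparable across participants when
camera distance is not normalised (scale normalisation is out of scope
here).

A single dropped frame removes the two frame pairs it participates in;
gaps are never bridged, because a displacement computed across a gap
conflates several steps and inflates the tail of the distribution.

## Repairing pose sequences

Keypoints with confidence below `minScore` (default 0.3 -- pose
estimators emit many usable detections around 0.5--0.7, and 0.3 is a
common floor below which localisation is unreliable) are treated as
missing. Runs of at most `maxGap = 5` frames flanked by valid detections
are repaired by per-coordinate linear interpolation between the nearest
valid neighbours; longer runs and boundary runs are dropped rather than
extrapolated. Every repair and drop is logged per frame and keypoint.
All quantiles in the package (confidence summaries, percentile
thresholds, boxplot summaries) use the linear-interpolation definition
between closest order statistics (R type 7), fixed once so that every
module and every oracle agrees.

## Outlier filtering

Per-frame displacement streams from pose estimators are right-skewed
with a long tail: isolated frame freezes and detection jumps produce
displacement spikes far above the walking signal. The package cleans the
pooled cohort stream with a percentile threshold (default the 95th,
removing the top 5%); 90 and 99 are retained for sensitivity analysis.
"Exceeding" is strict, so values equal to the threshold are kept.
Removing a frame pair's displacement also removes its directional-shift
entry: a corrupted displacement implies a corrupted angle for the same
pair. Thresholding is pooled across the cohort by default (one global
distribution); a per-participant scope is available where camera
geometry differs between recordings. An IQR fence is intentionally not
offered: it presumes distributional symmetry that these streams lack.

## SPPB walking test

Only the 4-metre walking test is scored (the balance and chair-stand
components measure different constructs and are out of scope). Each of
the two recorded trial times is scored 0--4, and a combined score is
computed on the mean of the available times, matching protocols that
record the average of two walks. The cut points (4.82 s / 6.20 s /
8.70 s) are the standard SPPB gait-speed categories; they are a package
default, fully overridable in the run config, and are a design choice
rather than a measured fact. The mean of the two per-trial scores is
logged as an alternative combined score.

## Body-composition validation

Records carry 21 bioimpedance indicators plus demographics. Validation
enforces the identities such a table must satisfy -- $ICW + ECW = TBW$
(within 0.05 L), $ECW/TBW$ ratio consistency (0.001), and the BMI
definition (0.3 kg/m²) -- with tolerances sized to absorb the one-to-
three-decimal rounding of printed tables. Violations warn by default and
become errors with `strict = TRUE`. SMI is stored as given and **not**
recomputed as $SMM/h^2$: device reports use appendicular muscle mass as
the SMI numerator, so recomputing from whole-body SMM would corrupt
valid data. Sarcopenia risk uses the AWGS 2019 cutoffs, strictly below
7.0 kg/m² (male) and 5.7 kg/m² (female).

## The statistical battery

Variables are screened with the Shapiro--Wilk test at $\alpha = 0.05$
before Pearson correlation; cells involving variables that fail the
screen are annotated, not suppressed, since the correlation itself is
still a descriptive quantity. Pearson cells use pairwise-complete
observations and record their own $n$ -- printed reports that show one
cohort size while their test statistics imply another are exactly the
ambiguity this avoids. The two-sided p-value comes from the exact
transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom,
which is also the slope t-statistic of the corresponding simple
regression; that identity is asserted in the test suite at $10^{-10}$.
Spearman cells are Pearson on average ranks with the same transform.
Markers follow the usual rule (*** $p<0.001$, ** $p<0.01$, * $p<0.05$)
and are always derived from the cell's own p-value, so a marker can
never disagree with its parenthesised p. No multiplicity correction is
applied by default -- the battery is exploratory -- and Benjamini--
Hochberg is available by flag. Sex-stratified grids repeat the analysis
per stratum and flag strata below 10 rows as low-n, since small,
imbalanced subgroups (for example, a handful of female participants)
support only cautious interpretation.

## The synthetic cohort

No raw multimodal cohort of this kind is publicly deposited, so the
package ships a generator that emulates the study conditions and makes
every stage testable:

* **Latent structure.** Each participant has a mobility factor
  $m \sim N(0,1)$. Indicators are
  $\mu_i + \sigma_i(\rho_i m + \lambda_i b + \sqrt{1-\rho_i^2-\lambda_i^2}\,e_i)$
  with a shared body-size factor $b$ producing the strong mutual
  correlations bioimpedance panels show in practice. The default
  $\mu_i, \sigma_i$ are the reference cohort's descriptive statistics
  (N = 19); the default $\rho_i$ plant muscle/water correlations of
  about +0.41 to +0.56 and fat correlations of about -0.05 to -0.26.
  A single-factor coupling was chosen over a full copula because it is
  the simplest structure that realises the signed pattern; it is
  swappable via the parameter table.
* **Derived indicators.** $TBW = ICW + ECW$ exactly and
  $ECW/TBW$ is the computed ratio, so generated records pass validation
  with zero warnings. Their effective correlations with $m$ are implied,
  not planted; `impliedCorrelations()` reports the closed-form value for
  TBW and a delta-method linearisation for the ratio. One honest
  consequence: with both water compartments loading positively on $m$
  and on the shared size factor, the implied ratio correlation is small
  and *positive* (about +0.10) -- a single-factor model cannot also
  reproduce a negative ratio correlation, and no attempt is made to
  force one. Weight is derived from BMI and height, and TBW/FFM is drawn
  from its own marginal rather than derived, so its row-level ratio is
  not constrained.
* **Gait.** Latent mobility sets the participant's true mean directional
  shift ($0.36 \pm 0.15$ rad, floored at 0.05), which scales the
  dispersion of Gaussian step angles plus a sinusoidal sway component
  (1.8 Hz, matching step cadence). Step lengths are log-normal
  (median 2.6 px/frame); a fraction `outlierRate = 0.05` of frames is
  spiked multiplicatively (about 8--25x, direction randomised) to mimic
  frame-freeze jumps, giving the right-skewed long tail the filter is
  designed for. Keypoints sit at anthropometric offsets around the CoM
  (zero-sum over the five CoM keypoints, so the designed CoM is exact)
  with 0.3 px jitter; 2% of frames carry one low-confidence CoM keypoint
  to exercise the repair path.
* **Confidence scores.** Scaled-Beta draws with per-participant mean
  targets in (0.60, 0.67) and upper bounds in (0.805, 0.825), plus a few
  near-ceiling detections per trial; per-participant means then fall in
  0.59--0.68 and maxima in 0.77--0.83, the documented operating range of
  the upstream estimator.
* **Walk times.** Inverse to a latent walking speed only weakly coupled
  to mobility (correlation 0.15), reflecting the observation that timed
  4-m performance and directional variability measure different things.
* **Determinism.** All randomness flows from one master seed through
  named substreams (demographics, latent factors, indicators, per-
  participant pose, walk), so modules can be regenerated independently
  and the same seed is bit-reproducible.
* **Fast path.** `level = "dynamics"` skips keypoint materialisation and
  emits statistically equivalent frame dynamics directly (the keypoint
  jitter enters as its CoM-average); simulation studies such as type-I
  calibration use it to run thousands of replicates.

What the generator does **not** emulate: photorealistic appearance,
biomechanically exact gait (stride mechanics, double support), camera
perspective and lens distortion, keypoint-specific failure modes such as
left/right swaps, and any real dependence of body composition on sex and
stature beyond simple height offsets. Passing recovery tests therefore
show that the pipeline is statistically faithful to its own model, not
that the model is a complete account of real recordings.

## Numerical choices and problem sizes

Quantiles are type 7 everywhere. Sample variances use $n-1$; a single
frame pair reports variance 0 with a warning instead of failing a whole
cohort run. Degenerate correlation cells (zero variance, fewer than 3
pairs) become NA cells with a warning inside grids, and hard errors when
requested directly. Perfect regression fits report $t = \infty$ with a
warning. The test suite sizes simulations to what the statistics need:
parameter recovery uses one cohort of 2000 participants at 150 frames
(sampling error of $r$ about 0.015, attenuation from estimation noise
about 0.01, against a tolerance of 0.05), and type-I calibration uses
10,000 independent null replicates at $n = 17$ with 40-frame dynamics
(binomial standard error 0.2% against a 1% band), one cell per
replicate.

## Known limitations

Pixel-space features are camera-dependent; only the angular mode is
scale-free. The directional shift treats the CoM as a point and ignores
limb kinematics. The single-factor generator cannot plant arbitrary
correlation matrices (notably for derived ratios). Walk-trial scoring
assumes the standard cut points unless overridden. Stratified analyses
inherit whatever imbalance the cohort has; the low-n flag is a caution,
not a correction.
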