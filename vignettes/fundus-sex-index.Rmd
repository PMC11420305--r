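---
title: "Quantifying masculine and feminine fundus features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying masculine and feminine fundus features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sex can be predicted from a color fundus photograph far better than
chance, but deep networks that do so are black boxes.  An interpretable
alternative quantifies a fixed panel of 42 fundus parameters — retinal
vessel angles, the papillomacular position, optic-disc ovality, and
red/green/blue intensities with the tessellation fundus index at nine
loci — and feeds them to an L2-regularized binomial logistic regression.
The model's leave-one-out cross-validated predictive value for the
female class, a number between 0 and 1, is the *fundus sex index*:
values below 0.5 describe a "masculine" fundus, values above 0.5 a
"feminine" one.  The index can then be treated as a continuous sex
tendency and correlated with sex-differentiated body measures — body
height and axial length — both pooled and within each sex.

Because the population dataset behind this design is not publicly
deposited, the package pairs the measurement and modelling pipeline with
a synthetic cohort generator whose ground truth is fully known.  Every
empirical claim in this vignette is recomputed by the package's tests or
by `scripts/acceptance.R`.

## The 42 parameters

From an image plus landmark annotations (`extract_features()`), in the
frozen order of `feature_names()`:

* **ST-RA, IT-RA, ST-VA, IT-VA** — supratemporal/infratemporal retinal
  artery and vein angles, in degrees, between the ray from the
  optic-disc centre to the vessel's crossing point on a measurement
  circle (208 px diameter) and the *temporal horizontal* — the
  horizontal ray from the disc centre toward the fovea's side.  Reported
  as magnitudes.
* **PMP** — papillomacular position: the signed angle between the
  disc-centre horizontal and the disc-centre-to-fovea line, positive
  when the fovea is inferior.
* **Ovality ratio** — minimum disc diameter over maximum, computed as
  the ratio of the smallest to largest directional width of the
  boundary point set over 3600 uniformly spaced directions.
* **R, G, B, TFI at L1..L8 and F** — mean channel intensities (0-255)
  and the tessellation fundus index TFI = R/(R+G+B) over eight
  peripapillary circles (96 px diameter) and one foveal circle (32 px).
  L1 is the lateral (temporal) circle, centred on the disc-to-fovea
  line; the remaining circles sit 45 degrees apart on a ring concentric
  with the disc, proceeding through the superior quadrant.

Numerical conventions, stated once and frozen: pixel coordinates are
0-based with the origin at the top-left and y increasing downward; a
pixel belongs to a sampling circle when its centre lies strictly inside
the disk; the protocol's "96-pixel" style sizes are read as *diameters*
(`circle_diameters()`, configurable, since diameter-vs-radius is not
fixed by the protocol's wording); the peripapillary ring radius is the
maximum disc semi-diameter plus the sampling radius, making the circles
tangent to the disc margin.  Defining the temporal reference from the
fovea's side (rather than "image left") makes all angles independent of
left/right image orientation.  An all-black sampling circle would make
TFI undefined; it is recorded as missing and such records are dropped
listwise before model fitting.

## The ridge model and the index

With features x_i (z-scored within the training data), labels y_i = 1
for female, coefficients beta and unpenalized intercept, the package
maximizes the penalized log-likelihood

    sum_i [ y_i x_i b - log(1 + exp(x_i b)) ] - lambda * sum_j b_j^2

by damped Newton (IRLS) iterations to a gradient norm below 1e-8 (at
most 200 iterations).  For lambda > 0 the objective is strictly concave,
so the maximizer is unique; the tests verify it against exhaustive grid
search of the same objective on a toy problem and against an
independent coordinate-descent implementation.  The penalty is chosen
by 10-fold cross-validated held-out log-likelihood over a log-spaced
grid, ties broken toward the larger (more conservative) penalty; a
single penalty is then reused across all leave-one-out folds.  That
reuse mirrors a single-model workflow and technically lets the full
sample influence each fold's penalty — a small, documented leakage that
does not touch the held-out subject's label or features in the per-fold
fit itself.

**Leave-one-out cross-validation.**  `loocv_index()` fits one model per
subject, recomputing standardization constants within each training
fold, and predicts the held-out subject; the n out-of-fold predictions
are the fundus sex index values, and their AROC against sex (computed
as the Mann-Whitney U over n1\*n0, ties one half) summarizes
diagnostic performance.

One design choice deserves emphasis.  Pooled LOOCV scores have a known
pathology: each fold's class prevalence depends on which class was held
out (removing a female leaves fewer females), so with an unpenalized
intercept every held-out female receives a systematically *lower*
predicted probability than every held-out male.  Under a null signal
with a strongly shrinking penalty this drives the pooled AROC toward 0
rather than 0.5.  The package therefore class-reweights every training
fold to a constant balanced (50/50) effective prevalence.  Because the
target is a constant, a subject's own label provably cannot influence
their prediction (the tests assert exact invariance), fold intercepts
no longer encode the held-out class, and the null AROC concentrates
around 0.5.  With an informative signal the reweighting is essentially
inert (the default cohort is near-balanced anyway).

## The synthetic cohort

`cohort_config()` describes a screening population of adults aged 40+;
its defaults are the study conditions used throughout the tests and the
acceptance script:

* n = 1,653 right eyes, 838 men and 815 women;
* per-sex Gaussian covariates truncated at 4 SD: height 163.7 ± 6.3 /
  151.1 ± 5.8 cm, axial length 23.71 ± 0.83 / 23.28 ± 0.88 mm,
  refraction −0.24 ± 1.47 / −0.05 ± 1.76 D (male / female);
* age 52.8 ± 9.4 / 54.0 ± 10.8 years, drawn from the normal whose
  left-truncation at 40 has exactly these observed moments (naively
  truncating a normal with these parameters at 40 would inflate the
  female mean more than the male one and manufacture a spurious age
  difference);
* 33 primitive scene quantities (6 geometric, 27 channel means) with
  the means/SDs of `default_feature_model()`, chosen as typical values
  for 45-degree right-eye fundus photographs; the nine TFI features are
  derived from the channel truths, never sampled independently.

**Sex effects** enter the primitives additively on the standardized
scale — the simplest structure consistent with a mean-difference
description.  The default direction pattern follows the sex differences
reported for this measurement family (rounder discs, larger vessel
angles and stronger red tessellation in men; higher peripapillary
green/blue and foveal green in women), and the whole pattern is scaled
at configuration time so that the *oracle* AROC — the best achievable
by any classifier, computed in closed form from the Gaussian two-class
Mahalanobis distance Delta as pnorm(Delta/sqrt(2)) — equals 0.80, the
accuracy regime reported for ridge-based sex classification in this age
group.  The per-feature magnitudes are order-of-magnitude modelling
choices exposed in the configuration, not measured population values.

**Latent coupling.**  One standard-normal "femininity" factor per
subject loads (loading 0.5) on every informative feature in its female
direction and on axial length at the configurable within-sex
correlation `index_axial_rho` (default −0.13): within either sex, a
more feminine fundus goes with a shorter eye.  Height is conditionally
independent of the factor given sex, so any pooled index–height
correlation is purely a between-sex composition effect.  Note that the
*observed* index–axial correlation is attenuated relative to the
configured coupling by the factor's imperfect recovery
(corr(index, factor) < 1); the configured value is recovered on the
factor itself, and the attenuated observed value is reported as its own
quantity.

**Rendering.**  `render_image()` rasterizes a scene at 768 × 768 × 8-bit
RGB (resolution is a package choice; the source photographs' native
resolution is unknown): a flat fundus-colored background, the disc as a
filled tilted ellipse whose minor/major ratio is the ovality truth, 32
boundary landmark points on that ellipse, four vessel polylines through
their measurement-circle crossing points, and the nine locus color
patches painted last so that circle-sampled means equal the configured
truths up to quantization.  The phantom is deliberately metrological
rather than photorealistic: patches overpaint vessel segments inside
sampling circles, vessels are straight, and there is no texture.  The
disc semi-major axis is drawn in [78, 94] px so that adjacent
peripapillary circles can never share a pixel (ring radius at least
126 px keeps neighbouring centres more than 96 px apart).  Landmarks
are emitted in floating point, so angle recovery is exact; ovality is
recovered within 1 − cos(pi/32) ≈ 0.005 (the width deficit of a
32-point boundary polygon) and channel means within 0.5 of 255ths.

**What passing tests do and do not show.**  The generator produces
Gaussian, additively-structured features with a single latent factor,
straight vessels and noiseless landmarks.  Passing round-trip and
recovery tests therefore establishes the *pipeline's* correctness —
geometry, sampling, fitting, cross-validation, reporting — not the
photographic realism of the phantom, and says nothing about landmark
annotation error, media opacity, illumination gradients, or non-Gaussian
population structure in real photographs.

## Association stage

`build_report()` computes Pearson and Spearman correlations (Spearman
as Pearson on midranks, p-values from the t approximation) of the index
with height and axial length in all subjects, men, and women — both
coefficients are always reported because the source literature is
inconsistent about which was used; Mann-Whitney U sex comparisons
(normal approximation with tie correction, two-sided) for age,
refraction, axial length, height and the index; the OLS of the index on
height and sex with standardized coefficients; and, when features are
supplied, a bidirectional p-value stepwise regression of axial length
on the index plus all 42 parameters (enter p < 0.05, remove p ≥ 0.10 —
the defaults of the classic statistical packages for this procedure).
Significance is flagged at p < 0.001, appropriate for a cohort of this
size.  Because the index is itself built from the 42 parameters, its
stepwise selection against them is a genuinely hard collinearity test
and is seed-dependent; the report records whether it survives.

## Problem sizes and reproducibility

Everything is seeded: a cohort configuration carries one integer seed
(default 20050501), `simulate_cohort()` seeds the stream once, and a
rerun reproduces covariates, features and landmark files byte for byte;
`run_pipeline()` writes a manifest with md5 digests of every output.
The test suite exercises the full default cohort (1,653 LOOCV fits,
about 10 s), 100-scene render round-trips, 200-seed coupling-recovery
and 500-seed stepwise-null simulations; these sizes were chosen so the
whole suite completes in a few minutes while keeping every Monte-Carlo
band at least ~3 standard errors wide.

## Known limitations

* No automatic landmark detection: the extractor consumes annotations,
  as in the semi-automated protocol it implements.
* Right eyes only; left-eye mirroring is out of scope.
* The single-factor latent structure cannot represent feature-specific
  axial-length couplings, and the configured coupling applies to the
  factor, not directly to the observed index (see attenuation above).
* The penalty is reused across LOOCV folds (see leakage note).
* The ovality reference algorithm is the 3600-direction width scan;
  an exact rotating-calipers variant would be a drop-in replacement but
  is not implemented.
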