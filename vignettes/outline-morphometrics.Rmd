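---
title: "Three-dimensional outline morphometrics of convergent stone tools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-dimensional outline morphometrics of convergent stone tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`lithomorph` quantifies the shape of pointed ("convergent") stone tools from
the closed three-dimensional contour of their sharpest edge. The method chain
is the standard outline-morphometric one, adapted to objects that have only
three operationally homologous points: the tip of the point (L1) and the two
opposite corner angles (L2, L3, named clockwise on a piece oriented tip-up,
ventral face forward). Everything else on the contour is a pseudo-landmark
without point-wise homology.

```{r}
library(lithomorph)
```

## The analysis chain

**1. Equal-arc resampling.** Digitized contours arrive as an ordered closed
polyline starting at L1 and traversed clockwise. `resample_outline()` places
`n` points (default 196) by linear interpolation at arc positions
$i \cdot \mathrm{perimeter}/n$ along the closed piecewise-linear curve.
Interpolation is chordwise, not spline-based: contours are digitized densely
on 3D models, and the analysis operates on polylines throughout. Equal
spacing here means equal *arc* increments along the source curve; chords of
the resampled polygon are equal only in the smooth limit (a chord spanning a
corner is shorter than its arc), and the exact fixed points of the resampler
are contours whose chords are already equal. L2 and L3 are carried as
metadata rather than forced onto resampled positions — equal spacing and
anchor coincidence are mutually exclusive in general.

**2. Anchor-landmark Procrustes superimposition.** Position, orientation and
scale are removed by a generalized Procrustes fit computed *only on the
three anchor landmarks*; each specimen's fitted similarity transform is then
propagated to its 196 pseudo-landmarks (`gpa_anchors()`,
`align_outlines()`). This is deliberate: these artifacts have no stable
major axis, so the usual first-ellipse normalization of Fourier descriptors
would be unstable, whereas the three corner angles give a reproducible
anatomical frame. Reflections are excluded from the rotation fit because
dorsal/ventral chirality is meaningful for a flake. Two conventions the
design leaves open are settled as follows and exposed as switches:

* *Scale reference* (`scale_ref`): each specimen is scaled by the centroid
  size of its anchor triangle (default, the standard choice when fitting a
  subset) or of its full 199-point configuration. The choice rescales
  eigenvalue magnitudes without changing the qualitative structure.
* *Orientation gauge*: after convergence the consensus is rotated to a
  canonical pose (L1 on +y, triangle plane spanning x–y, L2 at positive x),
  which removes the arbitrary global rotation of any Procrustes fit. This
  makes alignment exactly invariant to similarity transforms of the inputs
  (tested to 1e-8) and puts reconstructions in the tip-up, ventral-front
  orientation used for display.

Centroid size for allometry is always computed from the *raw* millimetre
coordinates of all 199 points, never from aligned ones (aligned anchor
triangles have centroid size 1 by construction).

**3. Tangent projection.** Aligned configurations, flattened to
597-vectors, are orthogonally projected onto the tangent space at the
unit-normalized full consensus $\hat m$:
$v \mapsto v - (v \cdot \hat m)\hat m + \hat m$ (Kendall tangent
coordinates). For configurations close to the consensus the displacement is
second-order small; the projection simply licenses Euclidean multivariate
statistics downstream.

**4. 3D elliptic Fourier analysis.** Each coordinate of the closed curve is
expanded independently in the arc parameter:
$x(t) = a_0 + \sum_n a_n \cos\frac{2\pi n t}{T} + b_n \sin\frac{2\pi n t}{T}$,
likewise $y$ with $(c_0, c_n, d_n)$ and $z$ with $(e_0, e_n, f_n)$ — the
third dimension adds one constant and two coefficients per harmonic to the
classical 2D formulation. No normalization by the first ellipse is applied
anywhere: orientation information is preserved on purpose, having already
been standardized by the Procrustes step. By default the Fourier input is
the 196 pseudo-landmarks only; L2/L3 drove the alignment and inserting them
breaks equal spacing. Because the wording of the original design is
ambiguous on this point, `include_anchors = TRUE` interleaves them at their
perimeter-minimizing positions (the chord-length parameterization remains
valid for unequal spacing), and `compare_variants()` evaluates both modes.

Two forward estimators are provided (`efa_forward(method = )`):

* `"trapezoid"` (default): the chord-length parameterized formulation that
  integrates the closed polygon exactly. It handles unequal spacing, but as
  an exact integral of the piecewise-linear interpolant it attenuates
  harmonic $n$ of a smooth curve by $\mathrm{sinc}^2(\pi n / k)$ — about
  1.2% at $n = 12$, $k = 196$. The attenuation is identical for every
  specimen, so PCA structure downstream is essentially unaffected.
* `"projection"`: least-squares projection on the truncated Fourier basis at
  uniform parameter spacing — the discrete Fourier transform of the samples.
  It recovers band-limited curves exactly and is the exact right inverse of
  `efa_inverse()` whenever $2N + 1 \le k$; exact round-trip and
  Nyquist-limit properties are stated (and tested) for this estimator, since
  no polygon-quadrature estimator can satisfy them.

Harmonic power $P_n = (a_n^2 + \dots + f_n^2)/2$ and its cumulative fraction
(`harmonic_power()`, `choose_harmonics()`) guide the harmonic count; the
analysis default is 12 harmonics, which on smooth tool-like outlines carries
well over 95% of the power (over 99% on the original study's material).

**5. Shape space.** `pca_fit()` runs covariance PCA (coefficients share
units, so no standardization) on the coefficient matrix. The three constants
are excluded from the variable set by default — after alignment they encode
only residual location — but their means are kept so reconstructions sit at
the consensus location. Eigenvector signs are fixed (largest loading
positive) for cross-platform determinism. `reconstruct_at()` rebuilds the
outline at mean $+ s \cdot$ eigenvector through the inverse transform;
extreme shapes default to $s = \pm 2\sqrt{\lambda}$ (observed score ranges
can be substituted — both conventions circulate).

**6. Inference.** Pillai's trace is *the* MANOVA statistic: its
F-approximation reproduces the characteristic denominator degrees of freedom
of the published designs exactly — $(k{=}9, g{=}3, N{=}37) \to 18/54$,
$(5, 3, 37) \to 10/62$, $(15, 2, 37) \to 15/21$ — where Wilks/Rao would not
(52 instead of 54 for the 9-variable design). The closed form is implemented
in `pillai_df()` as an independent cross-check of the model-fit route.
Factors with any class smaller than the number of variables are excluded at
pipeline level, mirroring the under-sampling rule of the original design;
the PC counts per factor default to action 9, trace side 5, localization 15.
Discriminant analysis (`lda_fit()`, pooled within-group covariance,
proportional priors) visualizes the separations, with
`df_extreme_shapes()` mapping discriminant directions back through the PC
eigenvectors into coefficient space for inverse-Fourier rendering.
Allometry is tested by multivariate regression of the leading PC scores on
log centroid size and on cube-root volume; `size_volume_correlation()`
reports the headline $r^2$ for centroid size against cube-root volume (the
two estimators on commensurate linear scales) alongside the log/log and
log/cube-root pairings, since the original wording mixes transforms.
p-values are unadjusted throughout, as in the original analysis.

## The synthetic assemblage generator

`generate_assemblage()` exists so that every stage and every statistical
property can be validated without museum data. It emulates a level-sized
assemblage of convergent flint tools:

```{r}
cfg <- assemblage_config(n_specimens = 37, seed = 1)
a <- generate_assemblage(cfg)
a
head(a$sizes, 3)
```

Each outline is a rounded-corner triangle: a tip wedge of `tip_angle`
degrees blended by quadratic Béziers into the two base corners, base width
`scale` mm, height `elongation` times the width, base sheared horizontally
by `asymmetry` and bowed by `base_convexity`, out-of-plane bowing
`ventral_bow * scale * sin(pi * s)` with `s` the arc position from the tip,
Gaussian digitization noise added per coordinate, then equal-arc resampling.
Anchors sit at the construction's curvature maxima (tip and base corners).

The defaults are fixed once as realistic study conditions, not tuned:
37 specimens; base width $38 \pm 8$ mm (centroid sizes then span roughly
110–440 mm, the size range typical of such flakes); elongation
$1.3 \pm 0.22$; tip angle $45^\circ \pm 9^\circ$; digitization noise 0.3 mm
per coordinate (laser-scan accuracy plus manual placement error on the 3D
model); factor class probabilities 0.3/0.4/0.3 (action T/L/P), 0.3/0.3/0.4
(side R/L/LR), 0.45/0.55 (localization), 0.6/0.25/0.15 (material, with no
shape effect — its rarest class routinely falls below the variable count and
is excluded by the pipeline rule, as happened in the original study).
Ground-truth effects are additive shifts on the shape *parameters*, not on
coefficients, so recovery tests are interpretable. Volumes use the analytic
proxy planform area × 0.15 scale — the pipeline only consumes volume as a
scalar covariate.

What the generator does *not* emulate: knapping scars and retouch
irregularity (synthetic outlines are smoother than real edges, so cumulative
harmonic power concentrates slightly differently), raw-material texture, and
measurement error correlated along the contour. Passing tests on synthetic
data therefore validate the *machinery* — superimposition, Fourier algebra,
test calibration — not archaeological conclusions.

One emergent property worth knowing: because digitization noise is constant
in millimetres while tool size varies, small synthetic tools are relatively
noisier, which induces a genuine (if weak) shape–size association. Null
calibrations of the allometry test therefore simulate scores independent of
size directly rather than through the generator.

## Calibration results the package itself computes

`manova_calibration()` regenerates fresh assemblages and runs the complete
chain per replicate. At the default null conditions (no class shifts,
$k = 9$ PCs, $\alpha = 0.05$, 2000 replicates) the empirical type-I error of
the whole pipeline is within the nominal band (the acceptance suite asserts
0.03–0.07), class separations of two pooled SDs in tip angle are detected
essentially always, and elongation-dominated assemblages put elongation on
PC1 with $|r| > 0.9$ in at least 18 of 20 seeds. These are recomputed, not
quoted, by `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Procrustes convergence: RMS consensus change below `1e-10`, at most 100
  iterations, deterministic iteration order; non-convergence is an error,
  not a warning. Collinear anchor triangles abort with the specimen named.
* Consecutive duplicate contour points (zero-length chords) are dropped
  before resampling; an all-coincident contour is a degenerate-outline
  error.
* The L1/first-semi-landmark identity is enforced on ingestion with a 1e-6
  mm tolerance: larger disagreements warn and snap L1 onto the contour.
* Fourier coefficients above the Nyquist limit of the sampling trigger a
  warning; zero total harmonic power is an error.
* PCA requires at least 3 specimens, 2 variables, and a non-constant matrix;
  missing values are rejected rather than imputed.
* All delimited output is written at full precision (`%.17g`), so
  write-then-read round-trips are exact to 1e-12 and repeated runs are
  byte-identical.

## Problem sizes used by the shipped checks

Module tests run on 8–14 specimen assemblages with 48–96-point contours;
the acceptance suite uses the full study conditions (37 specimens,
196 points, 12 harmonics) with 2000 calibration replicates and 20 recovery
seeds. These sizes were chosen as the smallest that exercise every code
path at the study's own dimensionality.

## Reproducing a published analysis

Given the original study's deposited coordinate, factor and size tables
(exported to the package's CSV layouts), `compare_variants()` runs the
pipeline under all four combinations of the two genuinely under-specified
choices (anchor inclusion in the Fourier input; Procrustes scale reference)
and tabulates leading eigen percentages, mean centroid size and the
size–volume $r^2$ per variant, so the best-matching configuration can be
identified empirically. The acceptance suite contains the corresponding
checks; they require the tables locally
(`options(lithomorph.study_data_dir = ...)`) since the data are not
redistributable with the package.

## Known limitations

* Anchor-only superimposition means pseudo-landmark variation never
  influences alignment; gross digitization errors on the anchors propagate
  to the whole configuration.
* No sliding semi-landmarks or bending-energy alignment: pseudo-landmark
  correspondence is purely arc-length based.
* The trapezoid EFA estimator's $\mathrm{sinc}^2$ attenuation slightly
  shrinks high harmonics (identically across specimens); use
  `method = "projection"` when exact band-limited algebra matters.
* The discriminant visualizations inherit the usual small-N caveats of LDA
  with k of up to 15 variables on 37 specimens; they are descriptive
  companions to the MANOVAs, not classifiers.
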