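---
title: "Methods: the CDR-profile generative classifier and its companions"
author: "spagen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CDR-profile generative classifier and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spagen)
```

## The problem

Glaucoma thins the neuroretinal rim — the tissue between the optic cup and
the optic disc boundary — and this geometric signature is visible in fundus
photographs once the cup and disc have been segmented.  `spagen` implements
a two-stage pipeline around that observation: (1) reduce a cup/disc label
mask to a 24-direction cup-to-disc ratio (CDR) profile plus the cup-to-disc
area ratio (CDAR); (2) classify the eye with a hierarchical Gaussian
generative model of the profile.  A compact fully convolutional
segmentation network, evaluation metrics and synthetic-data generators
complete the toolchain so that every stage can be exercised and tested
without clinical images.

## The profile model

Let $Y_{i,d}$ be the CDR of eye $i$ in direction $d = 1,\dots,24$ (15°
spacing).  The model is

$$Y_{i,d} = \beta_0 + \beta_{G,0} I_G + \beta_{CDAR}\,\mathrm{CDAR}_i
  + \sum_{k=1}^{2}\big[\beta^{(g)}_{s,k}\sin(2\pi k d/24)
  + \beta^{(g)}_{c,k}\cos(2\pi k d/24)\big] + z_i + e_{i,d},$$

where $g \in \{G, H\}$ is the diagnostic group (glaucomatous/healthy) with
its own four Fourier coefficients, $z_i \sim N(0, \sigma_z^2)$ is a per-eye
random effect shared by all directions, and $e_{i,d} \sim N(0,
\sigma_g^2)$ is independent directional noise whose variance may be
group-specific ($\sigma_G^2, \sigma_H^2$) — glaucomatous rims are more
irregular, so their residual variance is allowed to be larger.  Two
harmonics suffice because healthy cup/disc boundaries are close to
ellipses; the low-order Fourier terms capture ellipse-like eccentricity,
while genuine rim deformation shows up in the residual.

Marginally a profile is multivariate normal with compound-symmetric
covariance $V_g = \sigma_z^2 J + \sigma_g^2 I$, whose two eigenvalues
($\sigma_g^2$ with multiplicity 23, $\sigma_g^2 + 24\sigma_z^2$ with
multiplicity 1) give closed forms for the inverse and determinant;
`log_density()` never performs a dense solve, and the tests compare it to
one.

Counting free parameters: 1 prior probability + 11 fixed effects
($\beta_0$, $\beta_{G,0}$, $\beta_{CDAR}$, 8 Fourier) + 3 variance
components = **15** for the full model; dropping CDAR or sharing the noise
variance gives the 14- and 13-parameter variants reported by
`count_parameters()`.

## Fitting, posterior and the Rim Deformation Score

`spagen()` maximizes the exact Gaussian likelihood.  For fixed variances
the fixed effects have a closed-form generalized-least-squares solution,
so the variances alone are optimized numerically (Nelder–Mead on the log
scale, single start — the profiled Gaussian likelihood is well behaved
here, and the starting values come from method-of-moments estimates of the
OLS residuals).  The prior $p_G$ defaults to the training prevalence and
can be overridden.

A new eye is scored by the Bayes posterior
$p_{new,G} = p_G f_G / (p_G f_G + p_H f_H)$, computed in log space.  The
Rim Deformation Score is
$\mathrm{RDS} = \tfrac12\big[d_M^2(Y, \mu_H) - d_M^2(Y, \mu_G)\big]$
with squared Mahalanobis distances under each group's own covariance.  When
the two covariances are equal, the prior-adjusted posterior log-odds equal
the RDS exactly, so posterior thresholding at $p_{th}$ and RDS
thresholding at $\log[p_{th}/(1-p_{th}) \cdot p_H/p_G]$
(`rds_threshold()`) make identical decisions — a property the test suite
asserts to $10^{-8}$.  With unequal group variances the posterior carries
an extra $\tfrac12\log(|V_H|/|V_G|)$ term, so decisions are always made
from the posterior (Mahalanobis distances are used in their squared form;
taking the unsquared distance would break the log-odds identity, which is
why the squared reading was adopted).

The CDAR-only reference configuration (`cdar_discriminant()`) is a
two-parameter logistic discriminant — intercept and slope on CDAR — scored
by the same ROC machinery.  Its exact composition is a design choice here;
it is deliberately the smallest model that uses the area ratio at all.

## Profile geometry

The ray origin is the disc-region centroid — the one point that is stable
under boundary noise and matches the near-elliptical anatomy; 0° points
along the positive column axis (3 o'clock) and angles turn
counter-clockwise, with no left/right-eye anatomical re-anchoring.  Radii
are measured by marching each ray in 0.25-px steps and taking the distance
to the centre of the outermost covered pixel, so a single-pixel region has
zero extent.  A direction whose ray meets no cup pixel contributes CDR 0;
ratios are clipped to $[0,1]$.  Optionally (`smooth = "ellipse"`) radii
are taken on total-least-squares ellipses fitted to the boundary pixels,
emulating pipelines whose reference annotations are fitted ellipses.  Cup
pixels outside the disc are relabelled to disc with a warning, after which
cup ⊆ disc always holds.  vCDR is the ratio of vertical (row-axis) pixel
extents; CDAR the ratio of pixel counts.

Rasterization limits accuracy to roughly one pixel of radius, which for
semi-axes of 20 px and more keeps every profile value within 0.02 of the
analytic ray–ellipse value — the tolerance used throughout the tests.

## The segmentation network

The U-shaped network follows the mobile inverted-bottleneck design: a
full-resolution convolution stem, seven encoder stages of MBConv blocks
(1×1 expansion, depthwise convolution, squeeze-and-excitation channel
reweighting, linear 1×1 projection, residual where shapes allow), five of
which halve the resolution, then a decoder whose blocks upsample with a
2×2 stride-2 transposed convolution, concatenate the encoder feature map
of the same resolution, and apply two 3×3 convolution + batch
normalization + ReLU pairs.  The head is a 1×1 convolution with per-pixel
softmax.  Forward and backward passes are implemented directly on R
arrays (convolutions as kernel-offset accumulations of strided-slice
matrix products); the backward pass is verified against numerical
gradients to ~$10^{-9}$ relative error.

Choices the architecture description leaves open were fixed as follows:
per-pixel cross-entropy loss by default with soft Dice as an option; Adam
with learning rate $10^{-3}$ by default; decoder widths halving from the
deepest encoder width; random (He) initialization — no pretrained encoder.
The published parameter total of comparable full-scale networks
(≈12.6 M) depends on decoder widths that are not pinned down, so
`effunet_n_params()` reports counts rather than asserting one.  The
`width` multiplier scales every channel count; tests run a two-stage,
width-0.25 instantiation on 32–64 px images, which keeps the whole suite
on one CPU core in minutes while exercising exactly the same code paths
as a full-scale network.

The black-border removal threshold is a maximum channel value below
10/255, matching the pseudo-fundus generator's border so the
preprocessing and the generator agree by construction.

## Synthetic data: what it does and does not show

`sample_profiles()` is the forward model above, with CDAR drawn per group
from Beta laws (method-of-moments from mean/spread) so the covariate stays
in $[0,1]$.  The default generating truth — $\beta_0 = 0.25$,
$\beta_{G,0} = 0.12$, $\beta_{CDAR} = 0.4$, mild two-harmonic shapes,
$\sigma_z^2 = 0.004$, $\sigma_G^2 = 0.006 > \sigma_H^2 = 0.003$, glaucoma
fraction 0.26 (a typical screening-study prevalence), CDAR means 0.50 vs
0.35 with spread 0.12 — was chosen once to give a realistic operating
point: healthy mean CDR near 0.4, glaucomatous near 0.6, a CDAR-only
AUROC near 0.8 and a full-model AUROC near 0.997, i.e. the area ratio
alone is informative but clearly weaker than the profile model.  Profiles
are clipped to $[0,1]$ after noise (the quantity is a ratio); at the
default operating point the clipping rate is far below 1% and is reported
so tests can keep it there.

`render_masks()` rasterizes a disc/cup ellipse pair and returns the
analytic profile from the ray–ellipse closed form, giving the geometry
stage an exact oracle; `render_pseudo_fundus()` colours the regions with
separated intensity distributions plus noise and a black field border.
Passing tests on these fixtures demonstrates the correctness of the
geometry, the likelihood, the fitting and the training machinery.  They
do not demonstrate clinical performance: real fundus images have vessels,
texture, illumination gradients and annotation ambiguity that the
generators deliberately omit, and real rim deformation need not follow a
two-harmonic Fourier law.

## Numerical notes

* Variances are optimized on the log scale; $\sigma_z^2$ may approach the
  boundary at 0 and is recovered as a very small positive number (the
  tests accept ≤ 0.005 when the truth is 0 at $n = 1000$).
* Zero noise variances are accepted by the parameter container for
  noiseless forward simulation, but density evaluation requires them
  strictly positive.
* ROC thresholds are midpoints between consecutive distinct scores plus
  $\pm\infty$; the top-left-corner rule breaks ties towards higher
  sensitivity.  AUROC uses midranks, so ties are handled exactly.
* Segmentation metrics pool pixels over the evaluation set by default
  (per-image averaging is a flag); which convention published tables use
  is often unstated, so both are available.
* Problem sizes used by the test suite — 500 eyes for parameter recovery,
  1000 + 4000 for Bayes-consistency, 64 px single-image overfitting for
  the network — are the package's chosen desk-scale study conditions.

## Known limitations

* The CDAR coefficient is shared between groups (no interaction), so CDAR
  shifts both group means equally; its discriminative contribution enters
  through the group-specific intercept and the covariate's distribution,
  exactly as the model equation specifies.
* Compound symmetry is the only supported correlation structure; angular
  neighbourhood correlation beyond the shared random effect is not
  modelled.
* The segmentation module is a faithful, compact implementation intended
  for moderate image sizes on CPU; it makes no claim to the throughput of
  GPU frameworks.
* No confidence intervals are provided for AUROC.
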