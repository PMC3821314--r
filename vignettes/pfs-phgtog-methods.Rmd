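---
title: "Pyramid-histogram finger-vein recognition with personalized feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyramid-histogram finger-vein recognition with personalized feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinog)
```

## The problem

Near-infrared imaging makes the blood-vessel network inside a finger visible
as a pattern of dark curvilinear ridges on a brighter background. That
pattern is stable per person and differs between people (and between fingers
of the same person), which makes it a usable biometric. `veinog` implements
a complete recognition pipeline for such images: preprocessing, a
spatial-pyramid descriptor combining gray, texture and shape information,
per-subject sparse feature selection, nearest-class-center matching, and the
standard biometric evaluation protocol.

Because real finger-vein databases are typically private, the package ships
a synthetic generator that emulates the relevant structure of such data, so
every stage is exercisable and testable without any download.

## The descriptor: PHGTOG

Each preprocessed 96 × 64 image is described by the concatenation of three
spatial-pyramid histograms. A spatial pyramid at level $l$ splits the image
into a $2^l \times 2^l$ grid; a descriptor with $K$ bins per cell and levels
$0..L$ therefore has length $K \sum_{l=0}^{L} 4^l$. Level 0 captures global
composition, finer levels local layout.

* **PHG** (pyramid histogram of gray): per-cell intensity histograms with
  $K = 4$ equal-width bins over $[0, 255]$ (last bin closed), levels 0–2 →
  84 dimensions.
* **PHT** (pyramid histogram of texture): each pixel gets an 8-bit local
  binary pattern, one comparison per 8-neighbor, ordered clockwise from the
  top-left; bit $i$ is 1 iff the center is *strictly brighter* than neighbor
  $i$ (so constant regions code as all zeros, and a pixel brighter than all
  its neighbors as all ones). The bits are kept as a vector — the cell
  histogram is the componentwise sum of bit vectors, $K = 8$, levels 0–2 →
  168 dimensions. Note the comparison direction is the mirror of the common
  LBP convention (neighbor ≥ center); it matches the worked examples this
  descriptor is defined by.
* **PHOG** (pyramid histogram of oriented gradients): Sobel gradients give a
  magnitude and an unsigned orientation in $[0°, 180°)$ per pixel; pixels
  above an Otsu threshold on magnitude form the edge support, and each
  support pixel votes its magnitude into one of $K = 4$ orientation bins
  (edges at 0/45/90/135/180), levels 0–3 → 340 dimensions.

Each block is normalized to sum to one per image, and the three blocks are
concatenated into the 592-dimensional **PHGTOG** vector. Level weights for
PHOG are uniform by default and exposed in `pyramid_config()`. An
alternative per-feature min–max rescaling over a training table is available
via `pyramid_config(norm = "minmax")` for ablation; sum-to-unity is the
default because each pyramid block is a distribution-like object whose mass,
not range, is the meaningful scale.

Two numerical conventions matter and are fixed deterministically: grid-cell
boundaries for sides not divisible by $2^l$ fall at $\lfloor i \cdot n / 2^l
+ 0.5 \rfloor$ (half-up, so a 97-px side splits 49/48), and LBP codes are
computed once on the full image with replicate border padding before being
binned into cells, which avoids cell-boundary padding artifacts and makes
every pyramid level resum exactly to the whole-image statistic — a
conservation law the tests verify for all three blocks.

## Personalized feature selection (PFS-PHGTOG)

Different subjects are distinguished by different parts of the descriptor
(one finger by its ridge geometry, another by its texture statistics).
For each enrolled subject $i$ the package fits a one-vs-rest LASSO
regression on the training features,

$$\min_w \tfrac{1}{2}\sum_{j=1}^m (y_j - w^\top x_j)^2 + \lambda \lVert w \rVert_1,
\qquad y_j \in \{+1, -1\},$$

with no intercept and no feature standardization (standardizing would
silently reweight the L1 penalty; it is available as an option). The support
of $w$ — indices with $|w_j| > 10^{-8}$ — is the subject's personalized
mask. Matching then happens in each subject's own masked space.

The solver is glmnet's coordinate descent with the penalty mapped onto the
objective above (`lambda_glmnet = λ/m`); the test suite validates it against
two independent oracles: the closed-form soft-thresholding solution on
orthonormal designs and a brute-force cyclical coordinate-descent
implementation on general small instances.

**Choosing λ.** The penalty is parameterized relative to each subject's
critical value $\lambda_{\max} = \lVert X^\top y\rVert_\infty$ (above which
$w = 0$). The default is `lambda_rel = 1e-5`. This is deliberately light:
sum-normalized histogram features are small and strongly correlated, so even
tiny penalties prune aggressively — at `lambda_rel = 0.01` the masks
collapse to fewer than ten features and recognition fails, while at `1e-5`
the masks settle around half of the 592 dimensions, the regime in which a
reduced template still carries enough information to match on (on the
default synthetic benchmark the mean mask is ≈ 303 features). Empty masks
(possible at large λ) fall back to the full feature set with a warning.

## Matching and evaluation

A subject's template is its **class center**: the componentwise mean of its
enrollment features, computed after masking in PFS mode (masking and
averaging commute). A probe is scored by Euclidean distance
$D(f, T_i) = \lVert f - T_i \rVert_2$ in the center's space. Verification
accepts when $D \le$ threshold (boundary inclusive); closed-set
identification takes the argmin over all centers, ties broken toward the
smallest subject id with a message.

In PFS mode each candidate's distance lives in that candidate's own masked
space; raw distances are compared across spaces by default, which mirrors
the direct use of the distance rule but means per-subject score scales
differ. An optional `dim_normalize` flag divides each distance by
$\sqrt{|\text{mask}|}$ for ablation, since this comparability gap has no
canonical resolution.

The evaluation protocol builds $N \cdot t$ genuine pairs (every test sample
against its own center) and $N(N-1)\cdot c$ imposter pairs (the first $c$
test samples of each class against every other center; $c = 2$ by default,
so 136 classes with 10 test samples give 1,360 and 36,720 pairs). The ROC
sweeps every observed score as an accept-if-$\le$ threshold:
$\mathrm{FAR}(t)$ is the fraction of imposter distances $\le t$,
$\mathrm{FRR}(t)$ the fraction of genuine distances $> t$. The EER is the
value at the exact FAR = FRR crossing when a swept threshold achieves one,
otherwise linearly interpolated between the bracketing thresholds; the
extreme operating points are the FAR at the smallest threshold with
FRR = 0 and the FRR at the largest threshold with FAR = 0.

## The synthetic generator

Each subject is a fixed template of 3–6 random quadratic Bézier curves
spanning the image roughly along the finger axis, stroked with a Gaussian
cross-profile (σ 1.5–3 px) at 70–130 intensity units below a background of
200. A sample render applies one global rigid transform — rotation about
the image center and translation, sampled uniformly within the jitter
bounds — followed by additive Gaussian intensity noise, clipped to
$[0, 255]$. The transform is applied to the curve control points in
continuous coordinates before rasterization, which is the same rigid motion
as warping the rendered image but avoids a second resampling pass. RNG
substreams are keyed by (seed, subject, sample), so datasets are
bit-reproducible and adding subjects or samples never perturbs existing
ones.

Default conditions: 96 × 64 images (matching the preprocessing target size,
so synthetic data can bypass ROI extraction), jitter up to 3 px and 3°, and
noise σ = 10 on the 0–255 scale — values in the range of the small
finger-placement shifts and sensor noise one sees between repeated captures
on a guided device.

What the generator deliberately does **not** model: illumination
non-uniformity, device fixed-pattern artifacts, finger silhouettes,
non-rigid deformation, and photorealistic NIR scattering. Two consequences
for interpreting results follow. First, with zero jitter and zero noise,
repeated renders are pixel-identical, so the pipeline's error rates are
exactly zero — a separability limit the tests assert. Second, because the
remaining noise is i.i.d. across pixels and subject identity is spread over
the whole descriptor, discarding features cannot reduce the verification
error here: on this benchmark PFS-PHGTOG tracks full PHGTOG to within one
score quantum but does not beat it. The selection machinery's gain on real
data comes precisely from the shared, uninformative structure this
generator omits, so passing benchmarks here demonstrate correctness of the
pipeline, not a real-data accuracy advantage of selection.

## Preprocessing

The chain is gray conversion (ITU-R BT.601 weights for color input),
ROI extraction, bilinear resize to 96 × 64, and gray normalization.
ROI detection thresholds the Sobel gradient magnitude at the Otsu level,
takes the largest connected component as the finger contour, and crops to
its minimum/maximum column, keeping all rows (the guided capture fixes the
vertical placement; the horizontal extent is what varies). The resize uses
pixel-center alignment, so a 96 × 64 input is reproduced exactly and
constant images stay constant. Gray normalization is histogram
equalization — remapping through the empirical CDF, a monotone map under
which an already-uniform histogram is a fixed point and constant images
pass through unchanged; mean–variance standardization (mean 127.5, sd 50,
clipped) is available as an option. Every stage is deterministic, and stage
tags enforce forward-only progress through the chain.

## Problem sizes used by the test suite

The recognition benchmark in the tests runs 40 subjects × 30 samples
(20 enroll / 10 test, 2 imposter probes per class pair: 400 genuine and
3,120 imposter pairs), the package's chosen balance between statistical
resolution (EER quantum 1/400 on the genuine side) and a suite that stays
pleasant to run. The training-size sweep retrains the selection stage at
8, 12, 16 and 20 enrollment samples against a fixed test partition. Solver
oracles run on instances of ≤ 10 dimensions, where brute-force coordinate
descent is exact for practical purposes.

## Known limitations

* The PFS score-scale comparability across subjects is unresolved by the
  method itself; `dim_normalize` is an ablation, not a fix.
* ROI extraction assumes the finger contour dominates the gradient image;
  it is untested against real capture backgrounds.
* The EER of a finite protocol is a step function of the threshold;
  differences below one score quantum (1/#genuine) are not meaningful.
* LBP here is the 8-neighbor, radius-1, replicate-padded variant with the
  center-brighter convention; rotation-invariant and uniform-pattern
  variants are out of scope.
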