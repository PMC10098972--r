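---
title: "Radiometric-invariant cost volumes: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiometric-invariant cost volumes: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StereoHOG)
```

## The model

A rectified stereo pair relates a base pixel $(x, y)$ at disparity $d$ to
the matching-image pixel $(x - d, y)$. Under restricted lighting the two
views differ photometrically; we assume the linear radiometric model

$$ g_m = c \, g_b + t, \qquad c > 0, $$

which covers exposure/gain differences and a black-level offset but not
vignetting or saturation. Every component of the pipeline is chosen to be
exactly invariant under this model when no clipping occurs:

* Image gradients (central differences) are linear in the image, so they
  remove $t$ and scale by $c$.
* The gradient *direction* $\theta = \operatorname{atan2}(G_y, G_x)$ is
  unchanged by the positive scale $c$. Per pixel we histogram the
  directions of a $5\times5$ window into 12 bins of $30^\circ$ and
  normalize to unit sum. The two-argument arctangent matters: bins span
  all $360^\circ$, which the quotient $G_y / G_x$ alone cannot resolve.
* The *relative amplitude* $\rho(q) = \lVert\nabla I(q)\rVert /
  \lVert\nabla I(p)\rVert$ of each window pixel $q$ around centre $p$
  cancels $c$. The $25$ ratios are concatenated in raster order and
  L1-normalized.

Costs are L1 distances between descriptors (range $[0, 2]$ for
L1-normalized vectors), average-fused 1:1. The cost volume is denoised
slice-wise by a guided filter and fused across a vertical-only image
pyramid before winner-takes-all extraction.

Because all of this is exactly invariant, the package's invariance tests
can demand agreement to $10^{-6}$ rather than a loose statistical bound —
the observed residual is at the $10^{-15}$ floating-point level. Note this
requires float images: quantizing $c \, g + t$ to 8 bits (e.g. writing
PNG files) breaks exactness at the half-intensity-step level.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `window` | 5 | px | descriptor window side; also the guided-filter window, keeping one local linear model size |
| `nBins` | 12 | — | angle bins over $360^\circ$ |
| `fusionRatio` | 0.5 | — | weight of the angle metric (1:1 fusion) |
| `rgbThresh`, `gradThresh` | 30, 30 | intensity, intensity/px | adaptive-window gates; tuning parameters with no canonical value |
| `radius`, `eps` | 2, $10^{-4}$ | px, (guide units)$^2$ | guided filter; `eps` on the min–max-normalized guide |
| `sigmaX`, `sigmaY` | 2.5, 1.5 | px | homogeneity kernel widths |
| `nScales` | 3 | — | vertical pyramid depth |
| `wSimple`, `wComplex` | 0.3, 0.7 | — | finer-scale fusion weight in simple / complex texture |
| `lrcTol` | 1 | px | left-right consistency tolerance |

## Numerical and design choices

**Zero-gradient centres.** The amplitude ratio divides by the centre
gradient magnitude; below $10^{-6}$ the descriptor is undefined. We emit
the all-zero vector, flag the pixel, and charge the *neutral* amplitude
cost 1 (the midpoint of $[0, 2]$) at every disparity, so matching falls
back to the angle term and neighbourhood support instead of propagating
NaNs or fake certainty.

**Bin boundaries.** Half-open $[\text{lo}, \text{hi})$ bins; an angle of
exactly $2\pi$ wraps to bin 1. Zero-gradient pixels have no direction and
are excluded from the histogram and its normalizer.

**Amplitude layout.** "Histogram of amplitudes" admits two readings: a
positional vector (one entry per window pixel, raster order) or amplitudes
accumulated into the 12 angle bins. The positional layout is the default —
it keeps the spatial structure that makes the metric discriminative — and
`amplitudeLayout = "angular"` provides the accumulation variant.

**Adaptive windows.** Masks are computed once per base pixel (colour *and*
gradient-amplitude gates against the centre; the centre always kept) and
applied to the matching window at every candidate disparity. Re-evaluating
matching descriptors per disparity costs roughly the window area times
more work than the fixed-window path, so the pipeline default is
`adaptive = FALSE`; the thresholds (30/30 on 8-bit intensities) are
exposed as tuning parameters. The dedicated thin-bar scene shows the
mechanism: beside a high-contrast bar the fixed window drags background
pixels to the bar's disparity, the adaptive mask excludes the bar.

**Guided filter.** Exact box-filter implementation with shrinking windows
at the border (normalized counts); the per-window affine coefficients are
$a_k = \mathrm{cov}(I, p) / (\mathrm{var}(I) + \varepsilon)$,
$b_k = \bar p - a_k \bar I$, and each pixel averages the models of all
windows containing it. A literal per-window loop implementation is kept in
the test suite as the oracle; the two agree to $10^{-8}$ on random
$64\times64$ inputs. The guide is the *base* image: cost slices are
indexed by base pixels, so the matching image's edges would be spatially
misaligned with the slices (a `guide = "matching"` switch exists). The
guide is min–max normalized, an affine map, so filtering inherits the
radiometric invariance of the costs. Filtered costs are clamped at 0 to
keep the volume's non-negativity invariant against filter undershoot.

**Homogeneity indicator.** Texture is measured as
$(\!f_H * I)^2 + (f_V * I)^2$ where $f_H$ is a 2-d Gaussian negated on the
$x < 0$ half (and $f_V$ on $y < 0$). Sampled on an integer grid the
strict $x \ge 0$ convention leaves the $x = 0$ column positive, giving a
non-zero response to *constant* images — which would misclassify exactly
the regions the indicator exists to find. The map therefore uses the
antisymmetrized kernel (centre line zeroed), which responds zero on
constants, ignores intensity offsets, and scales as $c^2$ under gain — so
the quantile-based simple/complex split is invariant under the radiometric
model. `flippedGaussianKernel()` returns the literal sign convention by
default and the antisymmetric form with `zeroCentre = TRUE`. Pixels at or
below the median of the map (quantile configurable) are "simple"; ties
count as simple so a flat map classifies everything simple. Kernel support
is $\lceil 3\sigma \rceil$ per direction, replicate padding at borders.

**Cross-scale propagation.** Down-sampling is vertical-only (row pairs
averaged), so all scales share the disparity axis and no cost-curve
interpolation is needed. Descriptors, costs and filtering are recomputed
independently per scale. Propagating coarse→fine, every fine row $r$
draws from coarse row $\lfloor r/2 \rfloor$ — even and odd destination
rows share the source, the minimal consistent mapping — with the finer
scale's homogeneity class at the destination pixel selecting the weight
($w$ = 0.7 complex, 0.3 simple, applied to the finer volume). Where the
coarse entry is invalid the fine value is kept. The shared source row
produces mild horizontal stripes in the WTA disparity; they are inherent
to even/odd propagation and are left for a downstream cost-optimization
stage (out of scope here) to smooth, as such stages routinely do.

**WTA and LRC.** Ties break toward the smaller disparity. Invalid cost
entries (match outside the interior) are filled with the per-pixel maximum
valid cost so filtering does not bleed sentinels, but WTA masks them
explicitly rather than trusting the fill under ties. The right-image
disparity runs the identical pipeline on the horizontally mirrored,
role-swapped pair. `bad1.0` and `avgErr` are computed over LRC-valid
assessed pixels with `invalid` accounted separately
(`totBad = bad1.0 + invalid`); `allPixels = TRUE` switches to all-pixel
accounting.

## What the synthetic scenes do and do not show

The generator emulates what the matching theory needs: known
piecewise-constant integer disparity, dense seeded texture (smoothed
uniform noise over [30, 150] — headroom so that moderate gain/offset never
clips), constant-intensity homogeneous regions, exact forward-warp
occlusion (nearest surface wins, disocclusions filled by row-wise
background extension), the linear radiometric model, and optional additive
Gaussian noise — the noise model is a stand-in, chosen for want of a
physical speckle model. Scene geometry is chosen from the pipeline's
resolution arithmetic, not tuned: each scale resolves about 6 rows inward
from a band edge (window ±2, two cascaded box means ±4), so the reference
homogeneous band is a quarter of the image height (32 rows at the
128-row reference size) — partly ambiguous at one and two scales, resolved
at three — and the foreground plane sits far enough below the band that
coarse-scale windows cannot straddle both.

Passing these tests shows the algebra of the method is right and that
each mechanism moves its intended failure mode in the right direction. It
does not show performance on real endoscopic imagery: no photorealistic
texture statistics, no lens distortion or rectification error, no
vertical disparity, no saturation (which breaks the no-clipping premise of
the invariance), and integer ground truth only — sub-pixel accuracy is out
of scope throughout.

## Problem sizes

The shipped tests and the acceptance script run on 128×160 scenes with
`dmax = 16` for end-to-end checks (a size at which every mechanism —
occlusion band, homogeneous band, three usable scales — is comfortably
expressed), 64×64 inputs for the guided-filter oracle, and 16×16–48×72
instances for unit oracles. The full pipeline at the reference size runs
in a few seconds on one core.

## Known limitations

Large texture-less regions stay unresolved: the descriptor window cannot
perceive beyond its support, and three vertical halvings extend the reach
by only 4×. The adaptive-window thresholds are dataset-dependent. The
even/odd propagation stripes require a downstream optimizer to remove.
Costs are computed at integer disparities only.
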