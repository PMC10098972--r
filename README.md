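# StereoHOG

Dense stereo matching needs a per-pixel cost volume: for every pixel of the
base (left) image and every candidate disparity `d`, a number saying how
badly that pixel matches the pixel `d` columns to its left in the matching
(right) image. In binocular endoscopy the two views rarely agree
photometrically — restricted lighting and unequal camera settings produce a
gain/offset relation between them,

    g_m(p_m) = c · g_b(p_b) + t ,

so intensity-difference costs (AD/SD) mismatch systematically. StereoHOG
builds cost volumes from two descriptors that are *exactly invariant* under
this linear radiometric model and is aimed at people building traditional
(non-deep-learning) stereo pipelines for endoscopic or otherwise
radiometrically distorted rectified imagery.

## Method

For each pixel, over a small window (default 5×5):

* **HOG angle** — gradient directions `θ = atan2(G_y, G_x)` of the window
  pixels counted into 12 bins spanning 360°, normalized to unit sum.
  Gradients kill `t`; directions are unchanged by `c > 0`.
* **Relative HOG amplitude** — each window pixel's gradient magnitude
  `‖∇I‖` divided by the centre pixel's, concatenated in raster order and
  L1-normalized. The ratio cancels `c`.

The matching cost is the L1 distance between descriptors,

    C(p, d) = w · ‖H_b(p) − H_m(p − d)‖₁ + (1 − w) · ‖A_b(p) − A_m(p − d)‖₁ ,

with 1:1 fusion (`w = 0.5`) by default. Around strong gradient outliers
(e.g. a thin bright structure crossing a background window) an *adaptive
window* drops window pixels whose colour or gradient amplitude differs too
much from the centre; the mask is computed on the base image and travels
with the base pixel to every candidate disparity.

The volume is then denoised slice-by-slice with a **guided filter** (same
5×5 window, same local linear model), and low-texture reliability is
improved by **cross-scale propagation**: images are down-sampled 2:1
*vertically only* (so the disparity axis never needs interpolation), cost
volumes are rebuilt per scale, and coarse costs are blended into fine rows
with weights 0.3/0.7 selected by a texture-homogeneity classifier
(squared responses to sign-flipped Gaussian kernels, σx = 2.5, σy = 1.5).
Disparities come from winner-takes-all with a left-right consistency (LRC)
check, scored by Middlebury-style metrics (`bad1.0`, `bad2.0`, `invalid`,
`totBad = bad1.0 + invalid`, `avgErr`).

A synthetic scene generator (layered fronto-parallel planes, textured and
homogeneous regions, exact forward-warp occlusion masks, the linear
radiometric model plus optional noise) makes every stage testable without
external datasets; Middlebury PFM ground-truth files are read and written
natively.

## Worked example

```r
library(StereoHOG)

scene <- makeScene(128, 160, dmax = 16, layout = "two-plane", seed = 11)
pair  <- renderMatchingImage(scene, radiometricModel(c = 1.5, t = 20), seed = 12)
pair
#> StereoPair: 128 x 160, intensity range [46.2, 219.8]

cfg <- stereoConfig(dmax = 16)          # 5x5 windows, 1:1 fusion, 3 scales
res <- runPipeline(pair, cfg, gt = gtDisparity(scene),
                   evalMask = occlusionMask(scene))
res$disparity
#> DisparityMap: 128 x 160 (dmax = 16), 91.0% valid, disparities in [3, 10]
res$report
#> QualityReport (n = 19692): bad1.0 = 0.28%, bad2.0 = 0.28%, invalid = 5.50%, totBad = 5.78%, avgErr = 0.023 px
```

Despite the matching image being a gain-1.5/offset-20 distortion of the
warped base image, only 0.28 % of the assessed non-occluded pixels are more
than 1 px wrong; the 5.5 % `invalid` are almost entirely the occlusion band
left of the foreground plane plus image borders, which the LRC check is
supposed to reject. `runAblation(pair, cfg, axis = "scales", ...)` tabulates
the same report while varying one design axis (metric fusion, scale count,
filtering, adaptive windows).

A command-line driver with `generate`, `match`, `evaluate` and `ablate`
subcommands is installed at `inst/cli/stereohog.R`:

```sh
Rscript inst/cli/stereohog.R generate --layout two-plane --dmax 16 --seed 7 --outdir scene/
Rscript inst/cli/stereohog.R match --base scene/base.png --matching scene/matching.png \
    --dmax 16 --gt scene/gt.pfm --out disp.pfm --vis disp.png --report report.json
```

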