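Package: StereoHOG
Title: Radiometric-Invariant Cost Volumes for Dense Stereo Matching
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Dense stereo matching cost-volume generation for binocular
        endoscopy and other radiometrically distorted stereo imagery.
        Builds per-pixel histogram-of-gradient angle and relative
        amplitude descriptors that are invariant under the linear
        radiometric model g' = c*g + t, fuses them into a matching cost
        volume, denoises it slice-wise with a guided image filter, and
        sharpens low-texture regions with a vertical-only cross-scale
        cost propagation scheme. Includes winner-takes-all disparity
        extraction with left-right consistency checking, Middlebury
        style quality metrics, Middlebury PFM disparity file input and
        output, and a synthetic stereo scene generator with exact
        ground-truth disparity and occlusion masks for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, png, jsonlite
Suggests: testthat (>= 3.0.0), yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
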