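# wcesaliency

Saliency-based localization of gastrointestinal bleeding in wireless capsule
endoscopy (WCE) frames.

A capsule endoscope records tens of thousands of frames per examination, and
bleeding — small, dark-red, sharply contoured regions on pinkish mucosa under
nonuniform illumination — may appear in only a few of them. This package
flags candidate bleeding pixels by fusing three per-pixel saliency channels,
each a map in [0, 1]:

* **Edge saliency** `S1`: phase congruency over a Log-Gabor filter bank
  (5 scales × 6 orientations; wavelengths 6–96 px),

  `PC = |Σₙ (eₙ, oₙ)| / (ε + Σₙ √(eₙ² + oₙ²))`,

  where `eₙ, oₙ` are even/odd quadrature responses and `ε = 0.01`; the six
  orientation maps are combined by the maximum singular-value moment
  `½(Cx + Cy + √((Cx−Cy)² + 4Cxy²))` of the orientation-covariance matrix.
  Contrast-invariant, hence robust to the capsule's uneven lighting.
* **Intensity saliency** `S2`: a five-level rarity score of each pixel's
  gray-level histogram bin (levels {0, 0.25, 0.5, 0.75, 1}; thresholds
  `p̄ = 1/72` scaled by powers of `λ = 0.6`). Rotation invariant.
* **Color saliency** `S3 = r / (r + g + b + ε)`: the red proportion, ~0.8
  for blood versus ~0.49 for mucosa.

The fused map `S = (S1 + S2 + S3)/3` is binarized at its **mean value**, and
8-connected components of the mask become the suspected bleeding regions.
Pixel-wise evaluation against ground-truth masks (sensitivity, specificity,
accuracy, ROC/AUC), a 7-way channel-ablation runner, a noise-robustness
sweep (salt-and-pepper 2/4/6%, Gaussian variance 0.5/1/1.5%), and a
deterministic synthetic WCE-frame generator with pixel-accurate ground truth
are included. See `vignette("bleeding-localization")` for the full model,
parameter meanings, and known limitations.

## Worked example

```r
library(wcesaliency)

fx <- generate_fixture(fixture_spec(seed = 7))   # 480x480 synthetic frame
fx
#> synthetic WCE fixture 480 x 480, 6236 lesion pixel(s), seed 7

loc <- localize_bleeding(fx$image)
loc
#> bleeding localization: threshold 0.2515, 317 region(s), 75668 predicted pixel(s)

metrics(confusion(loc$mask, fx$gt_mask))
#> sensitivity 1.0000 | specificity 0.6903 | accuracy 0.6986

roc_curve(loc$fused, fx$gt_mask)
#> ROC over 201 thresholds | AUC = 0.9984
```

The fused saliency map ranks pixels almost perfectly (AUC 0.998): every
lesion pixel is recovered (sensitivity 1) and every lesion centroid lies in
a predicted region. The mean-value threshold, however, also admits a broad
ring around each lesion — the coarsest filters (96 px wavelength) respond
far from the contour, and on a clean synthetic background the map mean sits
low. That halo is intrinsic to the bare phase-congruency formulation on
quiet scenes and is discussed in the vignette; on busy clinical frames the
mean threshold sits much higher. Artifacts (saliency/mask/overlay PNGs,
region CSV, config YAML) are written by `run_localize(image, config,
out_dir)`, and `inst/cli/wcesaliency.R` exposes `localize` / `evaluate` /
`simulate` subcommands for shell use.

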