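---
title: "Saliency-based bleeding localization: model, parameters, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saliency-based bleeding localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcesaliency)
```

## The problem

Wireless capsule endoscopy (WCE) produces tens of thousands of frames per
examination; gastrointestinal bleeding appears in a handful of them as small,
dark-red regions with sharp contours on pinkish mucosa under strongly
nonuniform illumination. `wcesaliency` localizes candidate bleeding pixels by
imitating three cues a clinician uses — contour, luminance rarity, and
redness — each expressed as a per-pixel saliency map in $[0,1]$, then fused
and thresholded.

## The model

### Edge saliency from phase congruency

A bank of Log-Gabor filters is built in the frequency domain,

$$LG(\rho,\theta) = \exp\left(-\frac{\log^2(\rho/f_0)}{2\sigma_\rho^2}\right)
  \exp\left(-\frac{\Delta\theta^2}{2\sigma_\theta^2}\right),$$

with $n_s = 5$ scales and $n_o = 6$ orientations. The wavelength at scale
$s$ (1-based) is $\lambda_s = \texttt{min\_wave}\cdot\texttt{mult}^{s-1}$
(6, 12, 24, 48, 96 px with the defaults) and $f_0 = 1/\lambda_s$ in
cycles/pixel; $\Delta\theta$ is the wrapped angular distance to the
orientation angle $\theta_0 = k\pi/n_o$. The DC bin is forced to zero. Note
the defining relation is sometimes written with $f_0$ proportional to
$\texttt{min\_wave}\cdot\texttt{mult}^{s}$, which is dimensionally a
wavelength; we take the reciprocal so that scale 1 is the *smallest*
wavelength, the standard Log-Gabor construction.

Filtering a frame's luminance (0.299 R + 0.587 G + 0.114 B; the luma choice
is conventional) with each filter yields quadrature responses: the analytic
filter is twice the one-sided grid, so the even response's effective
spectrum is the two-lobed symmetric $LG(u) + LG(-u)$ and a cosine at the
filter center passes with unit gain — the classical even/odd wavelet-pair
convention. Per orientation, phase congruency combines scales:

$$PC(x,y) = \frac{\sqrt{\left(\sum_n e_n\right)^2 + \left(\sum_n o_n\right)^2}}
  {\varepsilon + \sum_n \sqrt{e_n^2 + o_n^2}},$$

a contrast-invariant measure that is near 1 where the scales agree in phase
(edges and lines) and near 0 in smooth regions; $\varepsilon = 0.01$
stabilizes the ratio where total filter amplitude is negligible. The six
orientation maps are combined through the orientation-covariance entries
$C_x = \sum_d (PC_d \sin\theta_d)^2$, $C_y = \sum_d (PC_d \cos\theta_d)^2$,
$C_{xy} = \sum_d PC_d^2 \sin\theta_d \cos\theta_d$, and the edge saliency is
the **maximum singular-value moment**

$$S_1 = \tfrac12\left(C_x + C_y + \sqrt{(C_x - C_y)^2 + 4C_{xy}^2}\right),$$

the larger eigenvalue of $[[C_y, C_{xy}],[C_{xy}, C_x]]$, large where edge
energy concentrates along one direction. (A literal transcription of the
moment that divides by $2(C_x - C_y)^2$ is singular whenever $C_x = C_y$;
the eigenvalue form is the unique symmetric-matrix maximization consistent
with the $C$ definitions.) The map is rescaled to $[0,1]$ by its maximum;
with six orientations the raw moment can reach about 3, and per-image max
rescaling is the simplest contract-preserving normalization. Since the
downstream mean threshold is invariant to positive rescaling, this choice
affects only the *relative weight* of the edge channel inside the fusion.

### Intensity saliency from histogram rarity

The luminance is quantized to $N = 256$ levels (`round half up`), the
histogram normalized to probabilities $p_k$, and each pixel scored by how
rare its gray level is:

$$S_2 = \begin{cases}
0 & p > \bar p\\
0.25 & \lambda\bar p < p \le \bar p\\
0.5 & \lambda^2\bar p < p \le \lambda\bar p\\
0.75 & \lambda^3\bar p < p \le \lambda^2\bar p\\
1 & p \le \lambda^3\bar p
\end{cases}$$

with $\bar p = 1/72$ and $\lambda = 0.6$. The step *values* are
$\{0, 0.25, 0.5, 0.75, 1\}$ and the $\lambda$ powers scale the interval
*boundaries*; this is the only reading that yields a five-level map filling
$[0,1]$. Because the histogram ignores spatial arrangement, $S_2$ is exactly
rotation invariant.

### Color saliency from red proportion

$$S_3 = \frac{r}{r + g + b + \varepsilon_c},$$

with $\varepsilon_c = 10^{-6}$ on $[0,1]$ channels (the stabilizer's exact
value is a free choice; it only guards black pixels). Dark-red blood scores
about 0.8 versus about 0.49 for pink mucosa, and the ratio is invariant to
uniform illumination scaling.

### Fusion, thresholding, regions

The fused map is the weighted mean $S = \sum_i w_i S_i$ with default
$w = (1/3, 1/3, 1/3)$; other weight patterns produce the channel ablations.
The binary bleeding mask is $S > \operatorname{mean}(S)$ — *strict*
inequality, so a constant map yields an empty mask, the only degenerate-safe
convention. Regions are 8-connected components (connectivity is otherwise
unspecified by the method; 8-connectivity avoids splitting diagonal lesion
necks), with no minimum-area filtering by default. An optional circular
field-of-view mask restricts both the threshold statistics and the
evaluation; it is off by default.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_scales`, `n_orientations` | 5, 6 | — | filter bank resolution |
| `min_wave` | 6 | px | smallest filter wavelength |
| `mult` | 2 | — | octave spacing of scales |
| `sigma_rho` | 0.75 | log-frequency | radial bandwidth |
| `sigma_theta` | 0.6 | rad | angular bandwidth |
| `epsilon` | 0.01 | amplitude | PC stabilizer / implicit noise gate |
| `n_bins` | 256 | — | one bin per 8-bit gray level |
| `p_bar` | 1/72 | probability | rarity threshold |
| `lam` | 0.6 | — | rarity interval decay |
| `eps_color` | 1e-6 | — | red-proportion stabilizer |
| `weights` | (1/3, 1/3, 1/3) | — | fusion weights |
| `n_thresholds` | 201 | — | ROC grid over $[0,1]$ |

## Numerical choices

* **Boundary handling.** Frequency-domain filtering assumes a periodic
  image; the wrap discontinuity at the frame border otherwise manufactures
  strong phase-congruent "edges" along the entire border, felt up to half
  the largest wavelength inwards. `pc_maps()`/`edge_saliency()` therefore
  reflect-pad the image by `ceiling(max wavelength / 2)` (48 px at the
  defaults) before the FFT and crop afterwards. `pc_orientation_map()`
  stays a pure unpadded evaluation so that oracle comparisons against a
  per-pixel loop are exact.
* **Quadrature gain.** Responses use twice the one-sided transfer (see
  above). With a literal one-sided grid, all amplitudes halve and
  $\varepsilon$ doubles in relative strength, noticeably degrading the
  contrast invariance of PC.
* **Clipping and guards.** PC is clipped to $[0,1]$ (floating point can
  exceed 1 by machine epsilon); an edge map whose maximum is below
  $10^{-12}$ is returned unrescaled instead of amplifying FFT residue;
  metric ratios with zero denominators are reported as `NaN`, never 0 — a
  silent 0 would corrupt aggregates.
* **ROC.** 201 uniform thresholds on $[0,1]$; a pixel is positive when its
  value strictly exceeds the threshold; the AUC is the trapezoid over the
  points sorted by false-positive rate, anchored at $(0,0)$ and $(1,1)$.
* **Coordinates.** (row, col), row 1 at the top, everywhere.

## The synthetic fixture generator

`generate_fixture()` emulates the aspects of a WCE frame each pipeline stage
keys on: pinkish mucosa (default RGB 0.80/0.45/0.40) under a smooth **linear
illumination ramp** in a random direction with peak-to-trough amplitude 0.3;
1–3 dark-red lesions (RGB 0.45/0.05/0.05) as anti-aliased ellipses with a
sharp 1.5 px contour and semi-axes 12–36 px; mild per-pixel Gaussian texture
(sd 0.002) shared across channels; an optional circular vignette; all
deterministic given the seed, with the ground-truth mask recording exact
lesion support.

Two generator decisions deserve their rationale. A *linear* ramp was chosen
over a radial bowl because its luminance histogram is near-uniform: every
illumination level is equally common, so the rarity channel flags lesions,
not illumination extremes (a radial field's value distribution has thin
tails at both ends that spuriously score as rare on roughly 8% of the
frame). The texture amplitude is kept small because the phase-congruency
measure used here has **no noise compensation by design** — it is
contrast-invariant, so any i.i.d. texture lights up the edge channel roughly
uniformly regardless of amplitude; the small default keeps all three
channels individually separating lesion from background, which is what makes
the channel-ablation tests informative.

What the generator does **not** emulate: real mucosal folds and
vasculature, specular highlights, gastric fluid, residue, motion blur, and
compression artifacts. Consequently, passing tests demonstrate the
*mechanics* of each stage (filters, maps, fusion, thresholding, metrics) and
the end-to-end plumbing, not clinical performance.

## Known limitations

The most consequential one: the **coarse-scale halo**. Filters with
wavelengths 48 and 96 px respond up to ~75 px away from a lesion contour; at
such distances only those coarse scales respond, and the few responding
scales are mutually in phase, so bare phase congruency (no frequency-spread
weighting) stays at 0.3–0.9 in a wide ring around every lesion. On a
clean synthetic background, the fused map's mean sits barely above the
background level, so the mean threshold includes much of this halo in the
predicted mask. On default fixtures this caps pixel accuracy around
0.7–0.85 with sensitivity 1 (the entire lesion is always recovered and
every lesion centroid falls inside a predicted region), while the fused
map's pixel-ranking quality is excellent (AUC > 0.99 in the acceptance
script). Busy real frames behave differently: dense mucosal structure
raises the fused mean and tightens the mask around strong lesions. In other
words, the mean-value threshold is adaptive to scene busyness, and a clean
synthetic scene is its worst case. For the same reason, on synthetic scenes
the color and intensity singleton channels can out-score the full fusion in
mean-threshold accuracy, inverting the ordering expected on clinical data.
A frequency-spread weighting term in the PC denominator would suppress the
halo, but it is deliberately out of scope for this implementation, which
follows the bare formulation.

Smaller caveats: the intensity channel depends on the full-frame histogram,
so results change if a field-of-view mask alters which pixels are counted
(the FOV option covers this); saliency PNGs quantize values to 8 bits; the
evaluation treats every pixel equally, with no per-lesion weighting.

## Problem sizes used by the test-suite

Oracle comparisons (loop-based PC, eigenvalue moment, confusion counting)
run on 32×32 images; property checks on 64–128 px frames; end-to-end,
ablation, and noise-robustness checks on full 480×480 fixtures (10, 2 and 3
seeds respectively), sizes chosen to exercise every code path at full frame
scale while keeping a default `devtools::test()` run around three minutes.
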