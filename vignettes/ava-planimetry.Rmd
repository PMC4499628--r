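---
title: "Semiautomatic planimetry of the aortic valve area on CT"
author: "avaplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiautomatic planimetry of the aortic valve area on CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avaplan)
```

## The measurement problem

In aortic stenosis the valve opening narrows; an aortic valve area (AVA)
below 1 cm² is considered severe and drives the decision for surgical or
transcatheter valve replacement. Planimetry measures the AVA directly: on
a contrast-enhanced CT reformat through the valve plane at maximal
systolic opening, the bright (contrast-filled) orifice is outlined and
its area computed as

$$\mathrm{AVA} = N_{\text{pixels}} \times s_r \, s_c \; \mathrm{mm}^2,$$

where $s_r, s_c$ are the pixel spacings in mm. Manual tracing is slow and
observer-dependent; `avaplan` implements a semiautomatic alternative in
which the user supplies only three seed points — the commissures, where
the cusps meet — and the rest of the chain is automatic.

`segment_ava()` runs that chain:

1. **Sinus of Valsalva (SOV) detection** (`detect_sov`): a central
   preliminary crop, a global histogram threshold (Otsu), a small
   morphological closing, removal of objects under 700 px and of objects
   touching the border, then the bounding box (plus padding) of the
   surviving component nearest the center.
2. **Normalization** (`normalize_8bit`): the crop is min–max rescaled to
   0..255, so all histogram arithmetic lives on a fixed 256-bin scale and
   no HU calibration is needed.
3. **Calcium detection** (`estimate_calcium_threshold`,
   `detect_calcium`): a per-image threshold (below) flags calcified
   pixels; with contrast agent on board the conventional fixed 130 HU
   rule is meaningless.
4. **Adaptive binarization** (`adaptive_binarize`): bright lumen becomes
   foreground by a local-mean threshold.
5. **Active contour** (`init_contour`, `compute_gvf`, `evolve_snake`):
   the circle through the three seeds is evolved under a gradient vector
   flow (GVF) field toward the orifice edge.
6. **Double masking and selection** (`mask_with_contour`,
   `select_ava_object`): the binarized image is masked first with the
   seed circle, then with the converged contour; objects under 40 mm² and
   objects far from the center are discarded; the survivor is the
   opening.
7. **Measurement** (`measure_area`): calcified pixels are excluded and
   the pixel count is converted to cm².

## The per-image calcium threshold

On the 256-bin histogram of the normalized crop (bin index = intensity):

1. `im_max` — the highest occupied bin.
2. `max_h` — the largest bin count.
3. `t_calc_est` — scanning *down* from `im_max`, the first bin whose
   count reaches `max_h / 3` (inclusive). On a contrast scan the modal
   class is the bright lumen, so this lands on the upper shoulder of the
   lumen peak.
4. `dr` — counting pixels from bin 0, the bin at which the cumulative
   count reaches half the total (the median intensity).
5. The threshold interpolates toward the maximum:
   $T_{calc} = T_{calcest} + (imMax - T_{calcest}) \cdot f$, with
   $f = 0.5$ for bright images ($dr > 0.7\, imMax$) and $f = 0.2$
   otherwise. Both branches keep
   $T_{calcest} \le T_{calc} \le imMax$. A tie $dr = 0.7\,imMax$ takes
   the darker branch, i.e. the lower, more inclusive threshold.

Pixels strictly above `t_calc` are calcium. Two practical refinements in
the pipeline (both configurable):

* **Minimum deposit size** (`calcium$min_deposit_mm2`, default 1 mm² —
  the conventional minimum lesion size in calcium scoring): isolated 1–2
  px above-threshold pixels are the bright tail of image noise, not
  deposits. Excluding them would pit a small orifice and can split it
  into fragments, of which only one would survive object selection.
* **Exclusion stage** (`calcium$exclude_stage`, default `"pre"`):
  calcified pixels are removed from the binarized image before the snake
  and selection. A calcified leaflet edge otherwise forms a bright bridge
  connecting the orifice to the sinus lumen, merging them into one
  object. The excluded area is never counted, in either mode.

## The GVF snake

The snake runs on the *binarized* image, whose edges are crisp. The edge
map is the gradient magnitude of the lightly smoothed
(`edge_sigma` = 1 px) binary image, normalized to [0, 1]. The GVF field
diffuses that gradient across homogeneous regions
($\mu$ = 0.2, up to 500 iterations, tolerance $10^{-3}$, explicit scheme
with the stability-bounded step), which is what gives the contour its
capture range: the seed circle can sit 10–20 px from the orifice edge
and still be drawn in.

Numerical choices that matter, and why:

* **Normalized external force.** The raw GVF magnitude decays to ~10⁻³
  on the plateau between the seed circle and the edge; a snake driven by
  it stalls. The contour therefore advances along the per-pixel *unit*
  direction field of the GVF (weight `kappa` = 1), the standard practice
  for GVF snakes. Normalization happens on the grid, before bilinear
  sampling, so opposing unit vectors on either side of an edge average
  out at the ridge and the contour settles instead of oscillating.
* **Semi-implicit internal forces.** Tension ($\alpha$ = 0.1) and
  rigidity ($\beta$ = 0.1) are solved implicitly through the cyclic
  pentadiagonal system $(I + \tau A)x_{t+1} = x_t + \tau F_{ext}$,
  $\tau$ = 1, which is unconditionally stable in the internal terms.
* **Convergence guard.** The mean-displacement test (tolerance 0.05 px)
  is only trusted after `min_iters` = 20 iterations: on the weak-force
  plateau the very first displacement can be tiny, and without the guard
  the snake would "converge" at its initialization.
* **Re-spacing.** Vertices are resampled to uniform arc length every 10
  iterations; a shrinking contour otherwise bunches its vertices.
* **Collapse handling.** A contour that implodes to under 1 px² raises
  an error from `evolve_snake`; the pipeline catches it and falls back
  to masking with the initial seed circle — the double mask and object
  selection still recover the opening.
* **Mask margin.** The converged contour is expanded 2 px along its
  outward normals (`select$mask_margin_px`) before the second masking.
  The snake tracks the edge to within a few tenths of a pixel but rounds
  the sharply curved commissural tips; with the margin, the binarized
  image — exact on two-valued data — decides the boundary pixels, and
  the contour merely localizes the object. The dark leaflet band around
  the orifice guarantees that anything over-captured by the margin forms
  a separate component and is discarded by selection.

## Binarization window and offset

`adaptive_binarize` marks a pixel foreground iff it exceeds its
local-window mean by more than `offset` (strictly; an epsilon absorbs
FFT round-off so a constant image binarizes to background). Two defaults
differ from the naive choice:

* **Window = whole crop** (the largest odd window that fits). Any window
  small enough to sit inside the bright opening centers the local mean on
  the pixel's own value, and noise then deletes ~half of the opening
  interior. With the whole-crop window the mean pools the dark leaflets
  and background everywhere, leaving a margin of tens of gray levels.
* **Offset = 10** (8-bit levels). With offset 0 a flat noisy region is
  foreground with probability ½, which percolates under 8-connectivity
  into large speckle components. Ten levels is ≳2 standard deviations of
  realistic reconstruction noise on this scale while leaving the
  ~110-level lumen–leaflet contrast untouched.

## Object selection rules

`select_ava_object` removes components smaller than 40 mm² and keeps the
component whose centroid is nearest the crop center. The filtering only
applies when the double-masked image holds more than one object; a
single object is accepted as the opening outright. When the size filter
would delete *every* object — possible in extreme stenosis, where the
true orifice itself is under 40 mm² — the pipeline keeps the
nearest-center component and warns (`select$fallback = "nearest"`);
calling `select_ava_object` directly with `fallback = "error"` raises an
explicit segmentation failure instead.

## The synthetic phantom

`generate_phantom` renders what the pipeline expects to see: tissue
background (gray level 40), a bright contrast-filled SOV disc (180,
radius 16 mm), darker leaflets (90) drawn as a 1.5 mm band hugging the
*outside* of the orifice outline plus thin radial commissure lines to
the wall, optional near-saturated calcific deposits (250, 1.2 mm radius,
seated at the coaptation waists), additive Gaussian noise clipped to
0..255, and exact pixel spacing. The default orifice is a smooth
triradiate curve $r(\theta) = R\,[w + (1-w)\,|\cos 1.5\theta|^{p}]$
($w$ = 0.45, $p$ = 2) scaled so its shoelace area hits the requested
value exactly — commissures are rounded clefts, not needle points, and a
discrete contour could not represent a zero-radius corner anyway.

Ground truth uses the same rasterization convention as every measurement
in the package: a pixel belongs to a polygon iff its center lies inside
(even-odd rule, half-open boundary convention), so
`orifice_area_cm2 == pixel count × pixel area` bit-exactly, and the
intensity edge coincides with the polygon boundary.

What the phantom does *not* emulate: partial-volume shading at
boundaries (edges are hard), beam-hardening streaks, blooming around
dense calcium, in-plane anatomy outside the root, and motion. Passing
the phantom suite therefore demonstrates the internal consistency and
numerical correctness of the chain under known geometry — not clinical
accuracy, which requires patient data.

## Verification at a glance

The test suite checks each stage against an independent oracle: the
calcium threshold against a hand-traced table covering both branches and
the inclusive-stop and tie conventions; the GVF field against a dense
Jacobi fixed-point solver (max |Δ| ≤ 10⁻⁴ on 32×32 edge maps); the
object filters against brute-force flood-fill labeling on random masks
(including the strict 700 px and 40 mm² boundaries); the rasterizer
against a half-plane point-in-triangle test; and the full pipeline
against phantom ground truth over orifices of 0.3–2.0 cm², spacings of
0.4–0.7 mm, noise SD 0–5 and 0–4 calcium deposits (areas within 5%, no
failures; the sweep uses 20 phantoms at 256² px, which keeps the whole
suite in the minutes range). Seed robustness is checked by re-running the
default phantom with ±2 px jitter on all three seeds (area CV < 6%,
echoing the low repeat-measurement variability semiautomatic planimetry
is meant to deliver). Agreement statistics are validated by exact hand
arithmetic, by 95% limits-of-agreement coverage on 10⁵ normal
differences, and by recovery of a −0.10 cm² bias injected into 1000
simulated 25-pair studies.

## Known limitations

* The bare snake contour underestimates the orifice by a sub-pixel rim
  concentrated at the commissural tips; the double masking removes the
  dependence, but users consuming `res$contour` directly should expect a
  few percent deficit on small orifices.
* The SOV detector assumes one dominant bright central object; unusual
  fields of view need a manual crop (the error message says so).
* The calcium threshold flags the brightest noise tail on calcium-free
  images; the minimum-deposit filter suppresses the consequences, but a
  genuinely sub-millimetre deposit is below the method's resolution.
* DICOM support covers single-frame Explicit VR Little Endian grayscale
  only; volumes and compressed transfer syntaxes are out of scope.

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec())
res <- segment_ava(ph$image, ph$truth$commissure_points)
res
#> <ava_result> AVA = 0.405 cm^2 (162 px, 0 calcified px excluded)
ph$truth$orifice_area_cm2
#> [1] 0.405
```
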