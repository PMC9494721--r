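---
title: "Models, parameters and design choices in nanosense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in nanosense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosense)
```

nanosense closes the loop between a synthetic microscope/electrochemistry
simulator and the vision and control algorithms of an automated
nanopipette platform for adherent cells. This vignette records the
models, the parameters that matter, and the design decisions taken where
the problem statement left the design open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The defocus contrast model

Transparent adherent cells are nearly invisible in focus. For a thin
phase object of thickness h (µm) and refractive-index difference Δn, a
defocused bright-field image obeys, to first order,

$$ I(\rho) = I_0\,\bigl(1 + \Delta f\,\Delta n\,\nabla^2 h(\rho)\bigr), $$

with Δf the signed defocus distance (µm). `render_cell_image()`
implements exactly this: the summed per-phantom thickness fields are
differentiated with a 5-point discrete Laplacian scaled by
`pixel_size`⁻² (so µm cancel and the contrast term is dimensionless),
multiplied by Δf·Δn, offset and scaled by I₀, then seeded Gaussian
camera noise is added and the result rounded and clipped to
8-bit levels. Consequences that the tests verify:

* Δf = 0 renders are uniform at I₀ (noise off);
* the pre-clipping contrast field is exactly linear in Δf, Δn and h_max,
  and negating Δf negates it;
* a paraboloid phantom of radius R has constant interior Laplacian
  −4·h_max/R², so its interior renders at the single gray level
  I₀(1 − 4·Δf·Δn·h_max/R²) — the closed-form oracle used in the
  acceptance suite (≤ 1 % at R ≥ 30 px, the slack covering 8-bit
  rounding).

**Sign convention.** Positive defocus is the side on which cell
interiors darken (interior Laplacian of a dome is negative). The
segmentation below is designed to return contours only on that side.

**Edge softening.** The analytic ellipsoid/paraboloid profiles end in a
hard support edge whose discrete Laplacian is a one-pixel rim an order
of magnitude stronger than the interior signal. Real adherent cells
feather out over microns; a rim that strong is an artefact, and it can
capture the Otsu threshold and break the intended branch behaviour of
the hybrid segmentation. Scenes therefore apply a Gaussian taper
(`edge_softness`, default 2 µm) to the thickness field before
differentiation. Ground-truth masks remain the analytic support
(`thickness_field > 0`), and the paraboloid interior oracle is
unaffected because convolving a quadratic with a unit-mass kernel leaves
its Laplacian unchanged away from the edge.

**Default phantom parameters** (free parameters of the stated world,
chosen once at realistic values): peak thickness h_max ∈ [3, 5] µm and
semi-axes 10–16 px at 1 µm/px — the scale of spread HUVEC/NIH-3T3
nuclei at the paper-scale resampled magnification; Δn = 0.035
(cytoplasm ≈ 1.37 vs medium ≈ 1.335); I₀ = 150; camera noise σ = 2 gray
levels. With these, contrast at Δf = 40 µm is ≈ 10–25 gray levels —
segmentable but far from saturation, as in real defocused frames.

## 2. Hybrid triangle/Otsu segmentation and the NOCC focus measure

The detection chain is: Gaussian blur (σ = 2 px) → grayscale → hybrid
binarization → morphological closing (disk r = 2) → inversion → outer
contours of 8-connected components → centroids. The contour count
(NOCC) doubles as the focus measure.

The hybrid rule compares the Otsu threshold with the histogram mode:

* `T_otsu < T_peak`: dark-cell regime (positive defocus); threshold at
  `T_otsu`.
* `T_otsu ≥ T_peak`: bright-cell regime (negative defocus); threshold
  from the triangle rule anchored at the brighter histogram tail. The
  pixels below threshold are then background plus cell rims — one
  connected, border-touching region — so the contour count is zero.
  Ties are treated as negative defocus: the conservative branch, since
  a spurious zero is recoverable by moving the stage while spurious
  contours trigger penetrations.

Two implementation rules matter downstream:

* **Border rule.** Components touching the frame border are not
  counted. This is what maps "connected background" to NOCC = 0 on the
  negative side, and it mirrors the experimental practice of not
  counting cells cut by the frame edge.
* **Area filter.** Components below `min_area` = 30 px² are discarded
  (noise blobs; the smallest phantom is an order of magnitude larger).

The resulting NOCC curve over a stack is zero for Δf < 0 and unimodal
(plateau-topped) for Δf > 0 — the property that makes exhaustive argmax
z-positioning robust where Tenengrad/Energy/Brenner/Variance develop
local maxima on either side of focus. One caveat the acceptance test
documents: at near-zero defocus (|Δf| ≲ 1 noise SD of contrast) Otsu
thresholding of what is essentially pure noise can fabricate a blob, so
the curve may overshoot the phantom count by one at a single such
plane; unimodality and the negative-side zero are unaffected.

All thresholding, labelling (run-based two-pass union-find), contour
tracing (Moore neighbourhood with Jacob's stopping criterion) and
polygon simplification (Ramer–Douglas–Peucker, closed-curve variant)
are implemented in base R and each is tested against an independent
brute-force oracle (exhaustive between-class-variance search,
flood-fill component count, quadruple-loop NCC, point–line distance
scan).

## 3. Focus-curve quality metrics

`curve_quality()` min–max-normalizes a curve and reports:

* `range_um`: `minima_bracket` — z-distance between the local minima
  flanking the global maximum, curve ends counting as minima (the
  classical definition, right for NOCC); `maxima_bracket` — distance
  between the local maxima flanking the deepest *interior* local
  minimum (for classical measures, whose focal plane sits in a valley
  between two defocus peaks). Ends are not eligible as the focus-plane
  minimum; if the required extrema are missing the full span is
  returned with a `degenerate` attribute.
* `false_maxima`: strict interior local maxima excluding the global
  one, after collapsing plateaus (a run of equal values is one
  candidate at its centre) — essential for integer-valued NOCC curves.
* `noise_level`: Σ(second differences)², unit index step.
  `noise_level()` itself operates on whatever values it is given (so a
  linear curve gives exactly 0 and scaling by c scales it by c²);
  cross-metric comparisons go through the normalized curve via
  `curve_quality()`.

## 4. Tip rendering, detection and nonovershoot autofocus

The tip phantom is an opaque triangle (apex position, half-angle 22°,
length 120 px, opacity 120 gray levels under I₀ = 180). Defocus by
|z − z_focus| does two things: Gaussian blur with
σ = 0.5 + 0.04·|dz| px, and linear contrast attenuation reaching zero
at `detect_limit` = 110 µm. These three numbers are the simulator's
calibration: with them, the triangle-fitting detector succeeds through
100 µm of defocus and fails monotonically from 110 µm on, and the
template-matching similarity spans ≈ 0.9 → 1.0 over the last 100 µm of
descent so that thresholds between 0.90 and 0.98 produce distinct,
ordered stop heights. Note the attenuation alone is invisible to
zero-mean NCC (an affine intensity change); it is what ultimately kills
*detection*, while blur is what degrades *similarity*.

Detection chain: gamma transform (γ = 0.6; < 1 lifts the faint
silhouette), Otsu, closing (r = 1 — a larger disk eats the thin apex
and biases the vertex), inversion, longest contour, RDP with tolerance
0.03 of the perimeter. "Triangle-shaped" means exactly 3 vertices *and*
fitted-polygon/contour area ratio ≥ 0.8; the second condition is an
added robustness rule that rejects degenerate 3-vertex fits (e.g. an
inscribed triangle of a disk covers only ≈ 41 %, so circles are
rejected at any RDP tolerance). The apex is the vertex with the
smallest interior angle — the physically sharp end.

The descent controller renders the tip at the current stage height,
computes max S against a focused-tip template (cropped around the
apex), and steps down 5 µm while S < threshold. Because blur decreases
monotonically toward focus, S is monotone along the descent and the
stop height is monotone non-increasing in the threshold; any
sub-critical threshold (default 0.92) stops strictly above the focal
plane. A single coarse step size is used deliberately — the hardware
controller's fine-stage details are not part of this model.

## 5. Ion-current proximity detection

The approach curve is the standard pipette-occlusion model

$$ I(d) = \frac{I_\infty}{1 + c/d}, \qquad
   c = \tfrac{3}{2}\,\ln(r_o/r_i)\,\frac{r_i r_e}{h_p}, $$

implemented exactly (the applied potential U and resistances R_p, R_z
are represented informationally; only this approximation is computed).
Defaults r_i = 50 nm, r_o = 80 nm, r_e = 0.5 mm, h_p = 5 mm give
c ≈ 3.5 nm. The drop fraction p inverts analytically to
d* = c(1 − p)/p; p = 0.02 (the 2 % criterion, chosen over 0.25–1 % for
noise immunity) gives d* = 49c ≈ 0.17 µm — still non-contact.

`detect_surface()` estimates the baseline as the median of the first 20
samples, smooths with a width-5 moving median, and requires 3
consecutive smoothed samples at or below (1 − p)·baseline. On
noise-free traces it recovers d* to within one local schedule step;
on pure-noise traces (σ = I∞/200) the false-positive rate is below 1 %
over 1000 seeded trials (the 2 % threshold sits 4σ below baseline, and
the median-of-5 plus 3-sample confirmation suppresses excursions).
Approach schedules are log-spaced: the baseline needs samples several
decades beyond c while the stop criterion fires within tens of c, and a
linear schedule cannot serve both ends.

## 6. Orchestration

`run_experiment()` fixes the stage order: NOCC focus search over a
defocus series → cell detection at the winning plane → penetration-path
planning → tip autofocus → per-site approach with surface detection →
scoring against ground truth. The path planner defaults to
nearest-neighbour from the detected apex (2-opt refinement available);
length, not travel time, is the objective — the simplest defensible
reading of "optimized path". Penetration itself is an event in the log;
no cell-mechanics or electrochemical-signal model is attached. All
randomness derives from the single config seed, and reports serialize
to byte-identical JSON.

## 7. What the generator does and does not emulate

Emulated: linear defocus contrast of transparent thin objects with
seeded camera noise and 8-bit quantization; opaque-tip blur/attenuation
with a hard detectability limit; distance–current approach traces with
additive Gaussian noise; exact nucleus ground truth.

Not emulated: diffraction and partial coherence (no PSF beyond the
Gaussian terms), phase-contrast halos, uneven illumination, cell
overlap and motion, debris, focus drift, current drift/steps, cell
deformation during approach. A green suite therefore establishes
algorithmic correctness against the stated optical/electrical models
and exact analytic oracles — not performance on real micrographs. The
published benchmark rates are recomputed from their reported counts;
the synthetic end-to-end TPR/FPR (clean, well-separated phantoms) is a
stand-in at desk scale, and its 100 %/0 % outcome should be read as
"the pipeline is self-consistent", not as a claim about real cells.

## 8. Degenerate inputs and numerical choices

* Constant frames: Otsu and the triangle rule raise degenerate-histogram
  errors; `detect_cells()`/`locate_tip()` catch them and return an empty
  detection instead of failing the pipeline.
* Zero-variance NCC windows score 0 (a flat window cannot match a
  structured template); map values are clamped only by arithmetic, and
  |S| ≤ 1 + 1e−9 is asserted property-style.
* Ties: Otsu and histogram-peak ties resolve to the smallest gray
  level; `best_match` ties to the smallest row then column;
  `find_best_defocus` ties to the smallest |z| then z; longest-contour
  ties to the larger area; `T_otsu == T_peak` takes the triangle branch.
* Plateaus in curves collapse to their centre index before extremum
  analysis.
* Contours are pixel-centre polylines; polygon area is the shoelace
  value, component area the pixel count (used for ordering/filtering);
  centroids come from polygon area moments with a pixel-mask fallback
  for degenerate (zero-area) polygons.
* Coordinates are 0-based (row, col) with origin top-left throughout,
  including NCC offsets.

## 9. Known limitations

* Pure-noise frames can yield spurious detections through the Otsu
  branch (no cells to separate from background); a texture/contrast
  gate would be needed for unattended operation on empty dishes.
* The tip must be the longest dark contour in its frame; heavy debris
  would require the ROI mode (`locate_tip(roi = ...)`).
* The NCC search is exhaustive per frame (no pyramid); adequate at the
  simulator's 240² px scale.
* Hardware positioning error distributions (stage repeatability,
  backlash) are outside the model; the controller's micrometer-scale
  stop statistics under such errors are hardware results and are not
  reproduced here.
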