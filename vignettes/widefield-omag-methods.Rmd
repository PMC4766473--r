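---
title: "Wide-field OMAG processing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wide-field OMAG processing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omagr)
```

This vignette is the package's account of the science it implements: the
flow-contrast model and its assumptions, what the synthetic phantom does and
does not emulate, the tunable parameters with their defaults and units, the
numerical choices, and the design decisions that were genuinely open.

## The acquisition and flow model

A cluster-scan OMAG acquisition records, at each slow-axis position, N
repeated B-scans of complex OCT signal (amplitude and phase). The package's
default `scan_protocol()` models a 245 A-line × 245 position × 4 repeat
protocol at a 3.7 ms inter-B-scan interval — 270 frames/s and ≈3.6 s per
cube — with square cubes and 10 % montage overlap. Arrays are indexed
`[slow, depth, fast]`, 1-based, depth increasing into tissue; physical
positions are in mm and pixel pitches in µm.

Flow contrast is the mean absolute successive complex difference across
registered repeats (`omag_differentiate()`). The model assumptions are:

* static tissue returns an identical complex value each repeat, up to
  additive acquisition noise and bulk motion — so the differentiation
  signal of static tissue is zero after registration;
* flowing blood decorrelates the complex signal between repeats, and the
  differentiation signal grows monotonically with the decorrelation per
  inter-scan interval;
* bulk motion is a global per-B-scan displacement, recoverable by 2-D
  cross-correlation of the amplitude images.

Registration (`register_repeats()`) aligns each repeat to the first by the
argmax of the FFT-based circular cross-correlation of mean-subtracted
amplitude images; for full-frame circular shifts the correlation norm is
shift-invariant, so this argmax equals the normalized-correlation argmax.
Ties break toward the smallest displacement magnitude, then
lexicographically, which makes the estimate deterministic. Voxels that
leave the frame under the aligning shift are flagged invalid and excluded
from the flow average with renormalization — never zero-filled, which
would fabricate flow at the frame edges.

Two registration refinements are off by default and documented as options:

* **Subpixel mode** refines the integer peak by evaluating the cross-power
  spectrum on a 20× upsampled grid around it. Under fully developed
  speckle, amplitude images interpolate poorly (neighbouring resolution
  cells are independent), which biases a naive refinement; the cross-power
  spectrum is therefore weighted by a Gaussian low-pass (σ = 1 px,
  equivalent to blurring both amplitude images circularly) before the
  refinement. Integer-shift recovery is unaffected.
* **Global phase compensation** (`bulk_phase_compensate()`) removes the
  amplitude-weighted mean phase offset of each repeat relative to the
  first, `Arg(Σ Cᵣ·C̄₁)`. It is off by default because the modelled
  acquisition compensates displacement, not phase; the operation never
  increases the static-tissue differentiation signal, so enabling it is
  safe when the instrument has inter-B-scan phase drift.

An amplitude-only differentiation mode is exposed for comparison; the
complex form is the default since it uses both amplitude and phase.

## The phantom: what it emulates and what it does not

`phantom_spec()` + `simulate_cluster()` generate complex cluster volumes
with known ground truth. Each voxel receives a circular complex Gaussian
draw scaled by its layer's mean reflectivity, so amplitudes within a
homogeneous layer are Rayleigh — fully developed speckle. Static voxels
keep their complex value across repeats; a vessel voxel with decorrelation
rate d ∈ [0, 1] is re-mixed each interval as
`√(1−d)·previous + √d·fresh`, which preserves amplitude statistics while
making the complex-difference signal increase monotonically with d
(d = 0 reproduces static tissue exactly; d = 1 is full decorrelation).
Bulk motion is applied per (position, repeat) as a circular integer pixel
shift (default) or a Fourier-domain subpixel shift; additive complex
Gaussian noise models the acquisition noise floor.

The phantom deliberately does **not** model: the imaging optics (confocal
gating, depth roll-off, dispersion), spatially correlated speckle (the
simulated speckle is white voxel-to-voxel, which is *harder* for
segmentation and subpixel registration than PSF-correlated real speckle),
projection/decorrelation-tail artifacts beneath large vessels, pathology,
or the eye-tracker itself — tracking is represented only by the residual
inter-B-scan displacement it leaves behind. Passing tests on the phantom
therefore demonstrate the correctness and calibration behaviour of the
algorithms under the stated model, not clinical performance.

Default phantom conditions, chosen once as plausible for a tracked
clinical protocol and used by the presets: vessel decorrelation 0.8 per
3.7 ms interval for perfused vessels, acquisition noise at 10 % of the
superficial-layer amplitude (`vessel-grid` preset; 5 % for `normal`),
residual tracked motion of ±1 px between repeats (±3 px in
`motion-stress`). The default depth axis is 512 px at 3 µm pitch, so the
30 µm choriocapillaris slab is exactly 10 px; reduced-depth phantoms in the
tests scale the pitch (e.g. 128 px at 12 µm) so physical distances are
preserved. The montage phantom builds one wide-field anatomy (gently
curved surfaces, tube vessels of ≈2 px radius crossing the whole field in
the superficial and deep retinal bands) and samples each cube from it;
cube origins snap to the lateral pixel grid so overlap strips sample
identical anatomy, while speckle is drawn independently per cube exactly
as independently acquired cubes would be.

## Layer segmentation

`segment_layers()` tracks each boundary per B-scan as the minimum-cost
depth path through an axial step-detector image, by dynamic programming
with a bounded per-column depth step (`max_step`, default 2 px). The
"semi-automated" interaction model is: automatic tracking by default, with
optional sparse seed points as hard constraints (the path is forced
through them, and seeded values are re-imposed after smoothing — so a
manual correction is always honoured exactly).

Numerical choices, each driven by fully developed speckle:

* **Pre-smoothing** (`presmooth`, default 3 × 7 boxcar over slow × fast):
  single-look speckle has ≈52 % amplitude CV; averaging ~21 voxels brings
  the gradient SNR into a usable range. Repeat-averaging does not help
  here, because static speckle is identical across repeats by design.
* **Step detector** (`grad_window`, default 2): the cost at depth z
  compares the mean of the `grad_window` rows below z with the rows above,
  a matched filter for a reflectivity step. It discriminates the true edge
  from positions ≥2 px away much more reliably than a 1 px gradient.
* **Prominence-ordered banded search**: boundaries are found strongest
  first, not top-down. The lower edge of the bright RPE complex is the
  strongest bright-to-dark transition in the scan and anchors the search;
  the ELM is the strongest dark-to-bright edge within a bounded distance
  (150 µm) above it, the ILM the strongest one higher up, and the inner
  boundaries subdivide the remaining bands with their own µm-bounded
  priors (`near`/`band_um` in `boundary_targets()`). A greedy top-down
  search is fragile: with a weak boundary above a strong same-polarity
  one, speckle noise in the summed path cost can flip entire B-scans onto
  the wrong edge. The µm band priors are anatomical (layer thicknesses are
  bounded) and make each sub-search essentially unimodal.
* **Surface smoothing** (`smooth_window`, default 5 frames): a running
  median followed by a mean along the slow axis; the median pass rejects
  the occasional single-B-scan excursion that a plain mean would smear
  into its neighbours. Ordering is clamped afterwards so the model is
  always anatomically monotone.
* **Failure handling**: an infeasible band yields an `NA` surface for that
  B-scan plus a row in the model's `failed` table — a partial model, never
  a silently wrong one.

Slab masks are half-open in depth (`top ≤ z < bottom`) with µm offsets
converted by `round(offset / axial_pitch_um)`. The slab set follows the
clinical scheme: NFL, SRL (ganglion cell + inner plexiform), DRL (inner
nuclear + outer plexiform), ORL (outer nuclear to ELM), photoreceptors
(ELM to RPE), whole retina, choriocapillaris (30 µm beneath the RPE) and
deep choroid. Because the ORL ends at the ELM, the retina partition
property is: NFL ∪ SRL ∪ DRL ∪ ORL ∪ photoreceptors = whole retina,
pairwise disjoint. The deep-choroid bottom uses the choroid/sclera surface
when the model has one and otherwise falls back to a fixed 200 µm band —
bounded and explicit rather than an unbounded "to the sclera" on data that
lacks that boundary.

## En face projection and compositing

The flow volume is smoothed with a separable Gaussian truncated to a
3 × 3 × 3 support and renormalized to unit sum (σ = 0.8 px per axis by
default — the support alone does not determine a Gaussian, so σ is an
explicit, configurable parameter; 0.8 px fills the 3-tap support without
spilling significant weight outside it). Boundary handling is edge
replication, which preserves constants and total mass. The filter is
applied to the flow volume — the quantity being projected; structural en
face views use a mean projection, exposed separately, since maximum
projection of speckle amplitude is dominated by speckle tails.

Maximum amplitude projection takes the per-pixel maximum over the slab's
depths; pixels whose slab is empty are zero and flagged rather than
silently zero. The RGB composite maps SRL/DRL/ORL to red/green/blue, each
channel normalized by its own 99th percentile — display scaling only, the
quantitative images are never modified, and percentile normalization keeps
a few bright pixels from compressing the rest of the dynamic range.
Co-located superficial and deep flow renders yellow, which on real data is
largely a projection artifact; projection-artifact removal is out of scope
here.

## Montage geometry and stitching

n cubes of width w with fractional overlap f span
`w·(n − (n−1)·f)` (`montage_extent()`). With f = 0.10 and w calibrated so a
3-cube row spans 6.8 mm, rows of 4, 5 and 6 cubes span 9.0, 11.2 and
13.4 mm — the coverage figures of the modelled protocol; reported fields
of view are rounded to one decimal place in mm to match.

```{r extent}
w <- 6.8 / (3 - 2 * 0.10)
round(montage_extent(c(3, 4, 5, 6), w, 0.10), 1)
```

`stitch()` places tiles at their nominal grid positions, refines each
placement by the integer shift maximizing the normalized cross-correlation
against the already-assembled canvas within ±20 % of the overlap width,
and blends with linear feathering (per-tile weights ramp over the overlap
band and are renormalized to sum to one at every covered pixel, so
consistent overlapping data reproduce the source image exactly). The
refinement is translation-only: the acquisition is tracked and rigid, so
rotation and scale are out of scope. A correlation peak below 0.3 falls
back to nominal placement and flags the seam — a composite is always
produced, degraded gracefully rather than failing. The reported shift
convention is refined-minus-nominal: a tile whose content sits 3 px right
of its nominal origin reports `(0, +3)`.

## Pipeline, formats, determinism

`run_pipeline()` chains the stages per cube and stitches per slab,
writing quantitative 16-bit TIFFs (with a JSON sidecar recording the
scale) separately from display PNGs, and a JSON report with per-cube
registration shifts, seam scores, the field of view, timings, the seed and
a config hash. Cluster volumes round-trip through a directory container
(32-bit float real/imaginary TIFF stacks plus a YAML metadata file; values
are stored affinely mapped to [0, 1] with the scale recorded, exact to
float precision); a legacy two-TIFF reader covers inputs without a
metadata sidecar. All simulation randomness derives deterministically from
the configured seed (per-cube seeds are fixed integer functions of it), so
identical configuration and seed give identical image outputs byte for
byte; the report is excluded from that guarantee only because it records
wall-clock timings.

The test suite and the worked examples run at reduced problem sizes —
cubes of 48–64 A-lines × 10–64 positions × 96–256 depth px rather than
245 × 245 × 512 — chosen so every stage is exercised with meaningful
statistics (tens of speckle cells per smoothing window, several vessels
per cube) while a full run of the suite stays fast.

## Known limitations

* The flow value is a contrast, not a velocimetric quantity; it saturates
  once the inter-scan decorrelation is complete.
* Registration is rigid and per-B-scan; intra-B-scan (A-line level) motion
  is not modelled or corrected.
* The segmentation's band priors assume roughly normal layer thicknesses;
  grossly pathologic anatomy would need adjusted `boundary_targets()` or
  seed points — the intended use of the semi-automated interface.
* White-speckle phantoms underestimate the spatial correlation of real
  speckle; absolute accuracy figures on real data will differ.
* Projection artifacts are not removed from deeper slabs.
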