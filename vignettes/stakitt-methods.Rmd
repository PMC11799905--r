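---
title: "The stakitt MLC positional test: model, algorithm and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stakitt MLC positional test: model, algorithm and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the measurement model and
the design decisions behind it: what is measured, under which
assumptions, which knobs matter, and what the synthetic validation does
and does not demonstrate.

## The measurement model

A multileaf collimator consists of two opposed banks of tungsten leaves.
The stakitt test images six 2 cm wide MLC-defined sub-fields (center
spacing 4 cm, centers at ±100, ±60, ±20 mm) on the portal imager, plus
comb patterns of alternating protruding/retracted leaves at both image
edges, with a carriage shift between the two central sub-fields. Every
leaf tip appears twelve times per bank (6 stakitts × 2 banks per pair),
in broad-beam conditions, so each tip can be measured *individually* and
*absolutely*.

Absolute means: referenced to the projection of the collimator rotation
axis (CAX) onto the panel, not to other leaves. The CAX is the mean of
two 10 × 10 cm jaw-field centers imaged at collimator 90° and 270°; a
180° collimator rotation maps a jaw asymmetry $c$ to $-c$, so the mean
of the two field centers is invariant to jaw calibration errors. Each
field center is the midpoint of the two 50% penumbra crossings on
central crossplane/inplane profiles.

At gantry angles other than 0° the panel sags under gravity. A sag map
is built from cine frames of a stereotactic-cone field (cones are
essentially sag-free) over a full arc; per-frame cone centers, normalized
to the gantry-0 frame, give the angle-dependent CAX offset, linearly
interpolated (with 360° wrap) between tabulated angles — adequate for a
slow mechanical function sampled at least at the cardinal angles.

Leaf localization uses the comb patterns: a vertical sub-pixel profile at
the comb column on each side shows a trough at every protruding leaf and
a peak at every retracted one. Matched left/right centers define the
leaf's *trajectory*; measuring along trajectories removes
collimator-vs-panel rotation from the crossplane coordinates. The tip of
each leaf in each stakitt is the 50% crossing of the trajectory profile,
with the 50% level defined *locally* per edge: the maximum inside the
stakitt's open window and the minimum in the adjacent 8 mm shielded
window. The 2 cm stakitt width keeps both extrema stable. The measured
crossing is corrected by the per-bank radiation field offset (RFO) — the
systematic distance between the light-field edge (the planning
convention) and the 50% radiation edge caused by rounded leaf ends — and
expressed in mm from the CAX at the isocenter plane.

Sign conventions: deviations are positive when the leaf is retracted
away from the gap. Opposed deviations therefore add:
$\Delta\mathrm{gap} = d_A + d_B$, positive meaning a wider-than-planned
gap. Default action limits are ±0.5 mm at gantry 0 and ±1.0 mm at the
other cardinal angles, reflecting that leaf backlash under gravity makes
the tighter limit impractical laterally.

### Backlash and gravity

Mechanical play (backlash) of magnitude $b$ lets gravity displace a leaf
by $\pm b/2$ along its travel axis when the gantry is lateral: at
gantry 90° bank A retracts and bank B extends; at 270° the situation
mirrors; at 0°/180° gravity is perpendicular to travel and the
displacement is zero. The bank-mean difference between gantry 90 and 270
therefore equals the full backlash, while the *gap* is only translated,
not resized. Rotation-direction hysteresis at gantry 0 (a clockwise
history leaves the 270-like state imprinted) is real on hardware but not
modeled; the simulator's gantry-0 state is the neutral one.

## The simulator: what it emulates, and what it does not

Every acquisition the analysis consumes can be rendered synthetically
with exact ground truth (`render_stakitt_image`, `render_cax_pair`,
`render_cone_arc`). The model is deliberately minimal:

* **Edges** are 1-D error functions with `penumbra_sigma = 1.2` mm
  (typical of a 6 MV beam on an amorphous-silicon panel). The analysis
  uses only 50% crossings and local extrema, so a transport/scatter
  engine would add nothing the algorithm can see.
* **Noise** is additive Gaussian, `noise_sd = 0.5%` of the open-field
  signal — an integrated 480 MU image is low-noise — over a 5% baseline
  pedestal (a panel's dark level), which keeps shielded pixels positive.
* **Panel**: 1024 × 1024 at 0.39 mm/px at the isocenter plane, covering
  both common panel types without modeling either exactly. With
  SDD = SAD = 100 cm detector mm equal isocenter mm; the SAD/SDD scale
  factor is applied in general (the DICOM reader rescales detector pixel
  spacing by SAD/SID).
* **True tips** are the nominal light-field positions displaced by the
  introduced per-leaf error, the true RFO, and the gravity-projected
  half-backlash; a collimator-vs-panel rotation is applied about the
  true CAX; panel sag displaces the whole pattern.
* **Radiological width modulation**: Varian leaves have a thick and a
  thin section (tongue-and-groove); with beam divergence the section
  that collimates swaps sides across the field, so a leaf protruding
  beyond its neighbours appears to narrow (or widen, for alternate
  leaves) linearly along its travel. `narrowing_slope` (mm of apparent
  width per 100 mm of travel) reproduces this for error-carrying leaves
  by shifting their inplane boundaries — and their neighbours', so the
  bank still tiles. The analysis does *not* correct for it; the
  simulator exists to characterize the resulting sensitivity loss on
  narrow (2.5 mm) leaves, which is how the real effect manifests.

Not emulated: panel glare/ghosting, MU nonlinearity, dead pixels,
flood-field residuals, MLC repositioning scatter between deliveries.
Passing the closed-loop tests therefore demonstrates the *algorithm's*
accuracy under the declared image model, not the performance of any
physical linac; on hardware, the measured repeatability additionally
contains the MLC's own repositioning spread.

Comb geometry is not prescribed anywhere authoritative, so the package
declares its own: protruding tips at ±124 mm, retracted at ±154 mm, the
opposing bank parked at ±118 mm, measurement column at ±134 mm. The
8 mm clearance between the outermost stakitt edge (±110 mm) and the
parked bank matches the 8 mm shielded-window width, keeping the outer
local minima deep (a 5 mm clearance biases the outer 50% levels by ~2%,
i.e. ~0.06 mm of tip error, which is why the comb was pushed out).

## Numerical choices

* **Interpolation**: profiles are sampled at 0.01 mm steps with
  Catmull-Rom cubic convolution (the standard "cubic" image
  interpolant; exact at pixel centers, exact on linear ramps). Sub-pixel
  claims at the 0.01 mm level need nothing more elaborate.
* **Profile smoothing**: before inverse interpolation, leaf-travel and
  field-center profiles pass a Gaussian low-pass of σ = 0.3 mm. The
  kernel is symmetric, so the 50% crossing of an erf edge is *exactly*
  unshifted; only pixel noise is suppressed (measured repeatability
  0.03 mm at 3 SD under the default noise).
* **Comb sub-pixel refinement**: the comb extrema sit on leaf-width
  plateaus, so the extremum position itself is ill-conditioned under
  noise — and a trajectory tilted by comb jitter is amplified by the
  ~190 mm lever arm from the CAX to the outer leaves. The extremum is
  therefore only an existence check (`extremum_center`, parabolic
  refinement, used as specified for curved extrema); the leaf center is
  the midpoint of the leaf's two 50% inplane boundary crossings, with
  the level window re-centered iteratively so an edge shifted by
  rotation does not bias its own level estimate.
* **Tie-breaks and degeneracies**: when noise produces several 50%
  crossings in a ±3 mm tip search window, the crossing nearest nominal
  wins. A missing crossing flags `edge_not_found`; contrast below 10% of
  the local maximum flags `low_contrast`; deviations beyond a 5 mm
  sanity bound flag `out_of_range`. Flagged rows are excluded from
  statistics. Leaves whose inplane band leaves the panel (the two
  outermost Millennium120 pairs on the default panel) are excluded as
  not visible; more than 20% unlocated leaves aborts the analysis.
* **Determinism**: the analysis contains no randomness — five analyses
  of one image agree bitwise. All simulator randomness flows from an
  explicit seed, restored after use.

## Known limitations

* Cross-talk between neighbouring leaves through the inplane penumbra
  leaves ~3% of an introduced error unrecovered on 5 mm leaves
  (2·(1−Φ(2.5/1.2)) ≈ 3.7% of the trajectory signal belongs to the
  neighbours). This matches the few-hundredths-of-a-millimetre recovery
  offsets observed at ±1.5 mm and is inherent to measuring along a
  single trajectory; gap deviations are unaffected because paired
  offsets cancel.
* The RFO is a per-bank configuration scalar; the package does not
  measure it (an external commissioning method does).
* The radiological-narrowing sensitivity loss on 2.5 mm leaves is
  characterized, not corrected.
* Problem sizes used by the validation harnesses: five acquisitions for
  repeatability, five errored leaves (or adjacent pairs) × six stakitts
  per sensitivity magnitude, twelve cone-arc frames for the sag map —
  compact but sufficient for the sub-0.01 mm standard errors the
  comparisons need.
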