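---
title: "Defect characterization and fidelity assessment for OCT-monitored extrusion printing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defect characterization and fidelity assessment for OCT-monitored extrusion printing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioprintqc)
```

## The problem and the model

Extrusion (bio)printing deposits a continuous filament along a programmed
toolpath; an OCT probe mounted beside the nozzle can image the part
between printing rounds. `bioprintqc` treats quality control as an image
comparison: what *should* be there (a target model map, rasterized from
GCode and a filament-geometry calibration) versus what *is* there (a
reconstructed thickness map from OCT surface detection). Everything
downstream — the six-state defect map, the mean-SSIM fidelity score, and
the secondary-printing repair GCode — derives from those two per-pixel
fields.

The approach deliberately depends only on the deviation between design
and deposit, not on the printing technology or material: any process that
can state its target geometry per layer and measure a height map can be
analysed the same way.

### Target model maps

GCode motion lines are parsed into segments carrying modal state (Z, feed
rate, extrusion flag). Extrusion state comes either from E-word deltas (a
positive delta advances filament, a negative one retracts) or from paired
command codes (`M101`/`M103` by default) — both dialects occur on
laboratory extrusion printers, and the choice is a `gcode_dialect()`
setting. Feed rates are mm/min in GCode and converted to mm/s internally.
Print pressure is not a GCode word; it is a per-job configuration value
attached to each segment.

Each layer is rasterized on the imaging grid: segment endpoints map to
the nearest pixel center (ties toward +Inf, so the closed extent is
covered symmetrically), the Bresenham algorithm interpolates the
centerline, and every centerline pixel paints a disc of radius
`round(width / (2 pitch))` carrying the calibrated filament height. A
disc reproduces the round footprint of an extruded filament cross
section. Where deposits of different geometry overlap, the larger
width/height wins — a thicker deposit dominates what the probe will see.
Multi-layer composites colour layers in Z order, deep blue then green
first.

The map also keeps the *ordered* centerline with cumulative arc length
and a nearest-centerline (Voronoi) owner index for every path pixel.
This one structure drives three later steps: lateral propagation of
centerline classifications, arc-length measurement of defect runs, and
arc-interval defect injection in the simulator, and it guarantees the
three agree to within one pixel.

### Reconstruction from OCT volumes

For each lateral column the first-surface index is the shallowest axial
pixel whose (moving-average smoothed) intensity exceeds a threshold.
The instrument literature rarely states a specific detector; a
first-crossing detector after a short centred smoothing window (default
3 px) is robust for the high-contrast step between air and deposit, and
the threshold defaults to `mean + 2 sd` of the volume while accepting an
explicit value. Columns that never cross are marked invalid; invalid
columns inside the path count as zero thickness, which the classifier
reads as breakage — consistent with "no deposit detected".

Thickness then follows the base-referenced relation
`t = (Z_base + Z_descent − Z_surface) · ΔZ` with all Z in axial pixels.
Two notes on this expression:

* **Operator binding.** Read literally with `ΔZ` applied to the surface
  term only, the expression mixes pixel- and mm-valued terms. The
  package applies `ΔZ` to the whole pixel difference, which is the only
  dimensionally consistent reading; the property suite (base-unevenness
  cancellation, linearity in descent) pins this behaviour.
* **Axial orientation.** Depth-down indexing is the internal convention
  (taller deposit ⇒ smaller surface index); volumes acquired flipped are
  reversed on construction via the `depth_down` flag.

Negative thickness — surface below base plus descent — signals a
registration error; it is clipped to zero and counted in the result.

### Classification rules and their numerics

With target `T`, measured in-path thickness `t`, tolerance δ (default
0.05 mm):

| state | rule |
|---|---|
| normal | `T − δ ≤ t ≤ T + δ` (closed band) |
| under-extrusion | `0 < t < T − δ` |
| over-extrusion | `t > T + δ` |
| filament breakage | `t = 0` and `T ≠ 0` |

Numerical choices: the zero test is `t < ε` with ε defaulting to half
the axial resolution (an exact float zero would be fragile against
quantization), and the normal band is closed at both edges, matching the
inequalities as printed. Classification happens along the centerline —
print state is a property of the path — and each centerline label is
propagated across the local filament half-width for display via the
owner index. When crossing paths give a pixel two targets, it is
classified against the larger one, consistent with the max rule used in
rasterization.

Stringing is detected outside the path: binarize the reconstruction,
skeletonize, dilate back to filament width, intersect with the inverted
path mask, and clean with a 3 × 3 opening. EBImage supplies the
erosion/dilation/opening primitives; the skeleton itself is the
classical morphological (Lantuéjoul) skeleton built from iterated
erosions, since no installed package provides 2D thinning. The operator
sizes are not dictated by the method description, so they are
configurable with these defaults: dilation radius = filament half-width
in pixels, opening element 3 × 3. One cleanup rule is added: connected
components of the final mask that contain no actual off-path deposit are
discarded. Re-dilating the skeleton of the in-path deposit can poke a
few pixels past path corners and ends over empty background; real
stringing always contains its own material, so the filter removes only
artifacts (a perfect print yields an exactly empty stringing mask).

### Fidelity

Mean SSIM between the target map and the evaluation field (the
reconstruction masked to non-background defect-map labels, so deposit
both inside and outside the path is scored):

* window size: filament width / pixel pitch, forced odd (0.41 mm on the
  1024-grid → 43 px; on a 256-grid → 11 px) — the window is meant to see
  one filament across;
* `c1 = (0.01 L)²`, `c2 = (0.03 L)²` with `L = max(target)`: the
  conventional stability constants, since the method description leaves
  them open;
* uniform (box) window statistics with symmetric border padding,
  computed via summed-area tables;
* the mean is taken over the full grid by default (both compared fields
  live on the whole grid); a support mask can restrict it.

Because the constants, weighting and window are conventions rather than
published values, fidelities on real instrument data are comparable
within a configuration, not bit-reproducible across implementations.

Per-layer values are summarised as mean ± standard error of the mean
(`glance()` on a `fidelity_series`); a single layer reports zero spread
by convention.

### Repair

Breakage and under-extrusion runs of length ≥ 1.5 mm (inclusive — runs
that *reach* the threshold qualify) become secondary-printing moves: a
travel move to the run start, extrusion on, linear moves along the run's
centerline polyline (collinear points merged, so a straight run is one
move), extrusion off, at the layer's Z. Under-extrusion re-prints at
nominal parameters unless a calibration table allows choosing a speed
whose deposited height matches the deficit. An optional endpoint overlap
(default 0 mm, i.e. off) can pre-compensate start/stop under-deposition;
no published value exists for it, so it ships disabled. Repair length
measurement uses centerline step lengths (pitch per axis step,
pitch·√2 per diagonal), and generated moves never extend beyond the run
endpoints by more than one pixel pitch.

Note that an under-extrusion stretch of 2 mm legitimately qualifies for
repair under the 1.5 mm rule, just as a long breakage does; counting
"one repair" in validation is therefore done per class.

## What the simulator emulates — and what it does not

`render_heightmap()` renders the filament as the target footprint at
uniform target height (flat-topped cross-section: OCT surface maps are
effectively top-surface heights), then injects defects:

* breakage/under/over as arc intervals along the centerline — a pixel
  covers ± half a pitch of arc, so interval selection uses that margin
  and the induced run length matches the injected length to one pixel;
* accumulation blobs as radially tapered extra height, restricted to the
  path mask (accumulation is on-path material excess; letting the skirt
  spill off-path would make the ground truth ambiguous between
  over-extrusion and stringing);
* stringing threads as thin off-path polylines.

`render_volume()` inverts the thickness relation (surface index =
`round(base + descent − h/ΔZ)`), fills columns with high intensity below
the surface, and optionally applies multiplicative gamma speckle
(mean 1, configurable shape) — the standard first-order model for OCT
intensity noise. The base profile may be tilted or uneven to exercise
base cancellation. All generators are deterministic under a fixed seed.

Not emulated: extrusion physics and rheology (defects are injected, not
emergent), partial signal penetration, shadowing and refraction at
filament edges, speckle correlation, and stage-registration drift
between rounds. Passing tests therefore demonstrate the correctness of
the *analysis* given surface data of stated quality, not robustness to
every instrument artifact.

Scenario fixtures carry the validated print configurations: HAP-like
gradient serpentine (0.41 mm nozzle, 0.18 MPa, 0.25 mm layers, 10 mm/s
straight / 12 mm/s at turnarounds, 9 × 9 mm), a nose-like silicone
contour (0.21 mm, 0.15 MPa, 0.18 mm, 10 mm/s) and ear-like PCL patches
with 90° vs 60° infill (0.15 mm, 0.55 MPa, 0.18 mm, 2 mm/s, 130 °C).

## Problem sizes and performance

The test-suite and acceptance computations run the full pipeline at
256 × 256 (pitch 0.039 mm) with axial stacks of ~90 pixels at
ΔZ = 0.01 mm — small enough for a laptop CPU in seconds while keeping
every geometric quantity (filament width 11 px, SSIM window 11 px,
3.6 mm gap ≈ 92 px) well resolved; unit tests use 48–128 px grids. The
full 1024 × 1024 instrument grid is the default for real data and runs
in a few seconds per round.

## Known limitations

* Stringing thresholds beyond "out-of-path thickness > 0" are not
  modelled; faint smears below the binarization ε are invisible.
* Internal defects (air bubbles) are out of scope; only the top surface
  is analysed.
* Lateral stitching of multiple fields of view is not implemented; one
  acquisition field is processed at a time, with simple per-round
  accumulation for cumulative height.
* The repair planner emits open-loop GCode; it does not decide whether a
  print should be aborted, and over-extrusion cannot be repaired by
  adding material.
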