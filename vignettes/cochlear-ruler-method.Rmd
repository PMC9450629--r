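---
title: "Measuring cochlear canal length with quantized chord rulers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cochlear canal length with quantized chord rulers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleaR)
```

## The measurement model

The spiral canal of the cochlea is a tapering helical tube roughly 30–37 mm
long by direct 3D morphometry. On clinical 3D reconstructions its length is
estimated by a *quantized chord walk*: a protocol of predefined digitized
rulers laid end-to-end along the canal, starting at the point closest to the
vestibule and advancing towards the apex. Each ruler is a straight chord; the
protocol fixes six mandatory 2.0 mm chords (R1–R6) and then, for every later
ruler, the largest of {2.0, 1.5, 1.0} mm that still "fits" the curving canal.
The reported canal length is the exact sum of the placed nominal lengths.

Two properties follow from plane geometry and drive everything in this
package:

* **Chord inequality.** A chord of length $L$ spans an arc
  $a \ge L$; on a circle of radius $R$, $a = 2R\,\mathrm{asin}(L/2R)$.
  Summed chords therefore *underestimate* arc length, worst where curvature
  is highest (the apical turns).
* **Termination remainder.** When no allowed ruler fits before the apex the
  walk stops, leaving an unmeasured remainder arc. The reference tables mark
  such unfilled ruler positions "DNM"; this package records the remainder
  explicitly instead of dropping it.

`chord_bias()` reports both terms: `1 - chord_total / total_arc` splits into
within-chord shortening plus the terminal remainder.

## How a chord is placed

`place_chord()` starts at arc position $s$ and finds the *first* position
$e > s$ with $\lVert C(e) - C(s)\rVert = L$ — first-crossing semantics,
because a physical ruler laid forward along the canal meets it at the first
crossing. On the piecewise-linear centerline the squared distance to $C(s)$
is an exact quadratic on every segment, so the crossing is found by a
closed-form quadratic root per segment rather than iterative bisection; the
placed chord satisfies $\lVert E - S\rVert = L$ to full floating-point
precision.

The protocol's historical description never states how the operator chose
1.5 vs 1.0 mm near the apex. This package's reconstruction is a *greedy
deviation-bounded* rule: a candidate chord is accepted only if the maximum
perpendicular distance between the chord and the sub-curve it spans is at
most `deviation_tol` (default 0.5 mm, about the apical canal radius — a
chord deviating more than the canal's own half-width would visibly leave the
canal on screen). The maximum over the spanned polyline is attained at a
vertex because distance to a segment is convex, so vertices are checked
exactly. This rule is deterministic and reproduces the qualitative pattern
of the reference tables (2.0 mm chords basally, smaller apically); it is a
stated reconstruction, not a claim about any operator's actual behavior.

Deliberate consequences of the defaults:

* The six-chord 2.0 mm prefix is mandatory; a canal whose chord walk cannot
  absorb it raises a `prefix-infeasible` error rather than silently
  shortening the protocol.
* Prefix chords are *not* deviation-checked (the protocol fixes them);
  deviation control applies from R7 on.
* Totals are sums of nominal lengths — all multiples of 0.5 mm — so they are
  exact, never accumulated floating point.

## The phantom: a stated world

No imaging data ships with cadaver measurements, and a cadaver gives no
ground-truth arc length at all. The phantom substitutes a parametric
helico-spiral — the standard cochlear morphometry shape — with a known
length:

$$C(\theta) = \bigl(r(\theta)\cos\theta,\ r(\theta)\sin\theta,\
h\,\theta / (2\pi T)\bigr), \qquad r(\theta) = R_0\,e^{-b\theta}.$$

Defaults (all in mm unless noted): basal spiral radius $R_0 = 4.0$; taper
$b = \log(4)/(5\pi)$ per radian so the apical spiral radius is 1.0 at
$T = 2.5$ turns; axial rise $h = 5.0$; canal tube radius 0.9 (basal) to 0.5
(apical), interpolated linearly in $\theta$; voxel spacing 0.2 isotropic;
margin 1.5. These were chosen once, before any test was run, on three
grounds: (i) they are adult-cochlea-sized; (ii) the true arc length
($\approx 34.5$ mm, by adaptive quadrature of the closed-form speed) falls
between typical in-vivo ruler-protocol totals (17–26.5 mm) and direct 3D
morphometry values (33–36 mm), so underestimation experiments are
meaningful; and (iii) successive turns of the *tube* keep $\approx 0.9$ mm
clearance, so rasterization cannot merge adjacent turns at any tested voxel
spacing — a merged mask would let the skeleton short-circuit across turns
and invalidate length recovery for reasons unrelated to the method.

Rasterization marks voxel centers within the local tube radius of the
centerline (foreground 1, background 0), then optionally applies isotropic
Gaussian blur in world mm (partial-volume emulation) and seeded additive
Gaussian noise. With zero noise the output is bit-identical across runs.
What the phantom does *not* emulate: MRI physics (no pulse-sequence or coil
model), the scala compartments, ossification or fibrosis, intensity
inhomogeneity, or anatomical variability beyond the spiral parameters. A
green phantom test therefore establishes correctness of the *geometry
pipeline*, not clinical performance on real scans.

## Centerline extraction

`extract_path()` automates the manual "trace the canal on the best view"
step: threshold segmentation (fixed value or Otsu's 256-bin between-class
criterion), 3D thinning to a unit-width skeleton, spur pruning, then the
minimal-cost 26-connected path between the voxels nearest the user's
vestibule and apex seeds (Euclidean edge weights in world mm). Thinning
deletes only *simple* border points — exactly one 26-connected foreground
component in the punctured 26-neighbourhood and exactly one 6-connected
background component in the 18-neighbourhood — with endpoints preserved, in
six directional subiterations with sequential re-checking; this is
deterministic and topology-preserving. Seeds snap within 2.0 mm by default;
disconnected seeds raise a connectivity error, the software analogue of an
obstructed canal.

Numerical choices that matter:

* **Spur pruning** (default 5 voxels): leaf chains shorter than the
  threshold that end at a junction are removed; a chain running endpoint to
  endpoint (the main canal curve) is never pruned.
* **Smoothing window 5 points, then resampling at one max-voxel-spacing arc
  step.** The raw voxel path overestimates length by 9–13% (digital
  zigzag). A 3-point moving average leaves the zigzag overestimate and the
  smoothing corner-cut in near-cancellation, which makes the signed error
  cross zero as resolution changes — the recovery error was measured
  non-monotone in voxel size. The 5-point default keeps the estimate
  consistently on the short side, with magnitude shrinking as voxels
  shrink, which is the behaviour a resolution study needs. Both parameters
  are exposed.
* **Planar-projection mode** (`project = TRUE`, off by default): points are
  projected onto the best-fit (principal-component) plane before
  measurement, emulating protocols that measure on a single projected 2D
  view. Projection can only shorten a non-planar curve; whether a
  historical measurement was made in 3D or on a projection is unknowable,
  so both modes exist and neither is asserted as "the" protocol.

## Degenerate inputs and tie-breaks

A curve needs at least two distinct points; consecutive duplicate points are
rejected at construction. `resample_curve()` preserves endpoints exactly;
uniform re-interpolation cannot lengthen a polyline but does shorten it
marginally at corners (measured ~3e-6 relative on the default phantom), so
"length preservation" is guaranteed one-sided only. Chord placement at a
touch point (distance reaching $L$ exactly at a tangency) counts as a
crossing; this is a measure-zero configuration. When several allowed ruler
lengths fit, the largest wins (greedy); when none fits, the walk terminates
— there is no backtracking, which keeps the walk deterministic and
$O(n)$ per ruler.

## Known limitations

* The deviation-tolerance reconstruction of ruler-size selection is one
  defensible rule among several; per-segment agreement with any particular
  operator's table is not claimed (and the per-case fixtures are carried as
  data, not regenerated).
* Skeleton-based centerlines are biased towards the medial axis of the
  *binary* mask; at 0.4 mm voxels with a 0.5 mm apical tube radius the
  recovered length is several percent short. The acceptance suite pins the
  error envelope at 10%/7%/5% for 0.4/0.2/0.1 mm.
* MetaImage is the only volume format (no NIfTI reader exists in the
  supported dependency set); headers are plain text, data uncompressed.
* The fixtures' vestibule-side starting landmark is defined operationally
  ("closest point to the vestibule"); its exact anatomical location (round
  vs oval window side) is not modelled — the phantom simply starts at the
  basal end of the spiral.
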