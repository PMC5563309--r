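---
title: "Cone-of-uncertainty streamline tracking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cone-of-uncertainty streamline tracking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the propagation model, how the uncertainty angles are measured, what the
synthetic phantoms do and do not emulate, and the places where the design
was genuinely open and a choice had to be made.

## The propagation model

A streamline is grown from a seed in fixed steps (default 0.5 mm). At each
step the tracker holds a position and an incoming unit direction
$V_{n-1}$. The voxel at the current position (nearest-voxel lookup; voxel
centres sit at integer 0-based indices) supplies up to five fODF peaks.
Peaks are *axes*, not vectors — the fODF is antipodally symmetric — so both
signs of every peak are considered and the sign-resolved direction with the
largest dot product against $V_{n-1}$ is selected as $V_n$. If even the
best candidate exceeds the maximum turning angle (default 50°), tracking
stops. The deterministic update is then

$$V_{n+1} = \mathrm{normalize}\big(f\,V_n + (1-f)\,((1-g)\,V_{n-1} + g\,V_n)\big),$$

with $f$ the local scalar-map value (FA/GFA; clipped to $[0,1]$ so the
update stays a convex blend even for maps that exceed 1) and $g$ the
*puncture* (default 0.2), which weighs the incoming against the newly
selected direction.

The probabilistic variant replaces $V_n$ with one draw
$W = \theta(V_n, \alpha)$, uniform on the spherical cap of half-angle
$\alpha$ about $V_n$. $W$ is drawn **once** per step and reused in both
terms: the two occurrences of $V_n$ in the update are the same quantity, and
sampling twice would decorrelate them. With $\alpha = 0$ the draw returns
$V_n$ exactly (the uniform height variable degenerates to 1), so the
probabilistic tracker at fraction $k = 1$ is bitwise identical to the
deterministic one under a shared seed schedule — a limit the test suite
asserts on all three phantoms.

### Stopping, lengths and the angular gate

A half-track stops when (a) the mask value at the current voxel falls below
the threshold (default 0.1), (b) no peak passes the angular gate, (c) the
length budget is exhausted, (d) the position leaves the volume, or (e) the
blend cancels to the zero vector (exact antiparallel geometry). Streamlines
are grown in both senses from the seed (the initial peak is chosen
uniformly at random among the voxel's peaks, then followed as $+p$ and
$-p$); the two half-tracks share the seed point. The paper-style length
window (default 10–200 mm) is enforced asymmetrically: the maximum by
stopping before the overrunning step (the streamline is kept), the minimum
by rejecting the finished streamline. The forward half-track spends the
length budget first and the backward half receives the remainder; only the
total is bounded, and on the phantoms used here the budget never binds.

In probabilistic mode the angular gate is applied to the cone-perturbed
direction $W$ as well as to the selected peak. This choice (the most
conservative reading of "the maximum angle a new direction can have with
the previous one") has a useful consequence: the final blend is a convex
combination of $W$ and $V_{n-1}$, so the realised turn can never exceed the
gated angle, and the per-step curvature bound holds *post hoc* on every
emitted streamline rather than only in expectation.

### Random numbers

One master seed spawns one L'Ecuyer-CMRG substream per streamline index
(stream 0 is reserved for seed placement). Each streamline consumes
uniforms only from its own pre-drawn substream, so results are independent
of evaluation order, identical between single-streamline and bundle calls,
and bitwise reproducible.

## Measuring the uncertainty angle

The fODF (real, symmetric, even-degree spherical harmonics; 45 coefficients
at order 8) is evaluated on a subdivided icosahedron. Level 3 (642
vertices, maximum edge ≈ 9.4°) is the default: comparable in angular
resolution to the 724-vertex symmetric spheres conventionally used for this
purpose, and antipodally symmetric by construction since the icosahedron's
vertex set is closed under negation and midpoint subdivision preserves
that.

For each peak vertex, the vertices within 90° are visited in increasing
angular distance (on a sphere this set is a spherical cap, so distance
ordering coincides with a breadth-first expansion from the peak), and
$\alpha$ is the angle to the first vertex whose value falls strictly below
$k$ times the peak value. Two boundary rules:

* if no vertex within 90° falls below the fraction (a plateau or
  near-isotropic lobe), $\alpha$ is capped at $\pi/2$, so the sampling cone
  degrades gracefully to a hemisphere rather than being undefined;
* $\alpha$ is a **half-angle** (peak axis to cap boundary), matching the
  geometry of the sampling cone.

$\alpha$ is stored in radians on disk (the fourth component of each peak's
slot in the 20-component peaks layout); the command line reports degrees.
Discretisation limits accuracy to roughly one mesh edge: on the Gaussian
test profile with σ = 20° the recovered angles match
$\sigma\sqrt{2\ln(1/k)}$ to within the 9.4° edge length across
$k \in \{0.95, 0.75, 0.5, 0.35, 0.15\}$, with errors typically under 2°.

### Peak finding and one deliberate relaxation

A peak is a vertex no neighbour of which has a larger value and at least
one neighbour of which has a strictly smaller one; candidates below half
the global maximum (configurable) are dropped, and surviving maxima are
greedily suppressed to a minimum axial separation (default 25°), which also
collapses each antipodal pair to its stronger member. The initial design
required *strictly* larger than all neighbours, but that rule fails in an
instructive way: when a lobe's axis lies exactly on a symmetry plane of the
mesh, the two straddling vertices carry bitwise-equal values and neither is
strictly maximal, so a clean single-fiber voxel yields no peak at all (this
occurs on the curved phantom, whose tangents sweep the xy-plane). The
relaxed rule keeps exact ties while still returning nothing on constant
(isotropic) functions. Extended flat plateaus below the global scale remain
peak-free, which is the intended behaviour for near-isotropic voxels —
those are the mask threshold's job.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `step_size` | 0.5 | mm | distance per propagation step |
| `max_angle` | 50 | deg | per-step turning gate |
| `mask_threshold` | 0.1 | mask units | stop when the scalar map drops below |
| `puncture` (g) | 0.2 | — | weight of the new peak vs the incoming direction |
| `min_length`, `max_length` | 10, 200 | mm | validity window for emitted streamlines |
| `seeds_per_axis` | 10 | — | a bundle run draws 10³ = 1000 random seeds |
| `fwhm_fraction` (k) | 0.35 | — | fraction of the peak at which α is measured |
| `relative_threshold` | 0.5 | — | peak-extraction floor vs the global max |
| `min_separation_angle` | 25 | deg | minimum axial separation between peaks |

The tracking defaults are the demonstrated operating point of the method
this package implements; 35% is the fraction reported to balance
probabilistic spread against bundle quality, and the peak-extraction
thresholds are conventional values (the source method does not state its
own). The fraction behaves as expected at its limits: $k = 1$ reproduces
deterministic tracking exactly, and lowering $k$ through
$\{1, 0.5, 0.35, 0.15\}$ monotonically increases the mean per-step turning
angle on the straight phantom (the "jaggier streamlines" trend).

## Synthetic phantoms and what passing tests mean

`make_phantom()` builds three geometries on a 40³ grid at 1.72 mm (the
spacing of the evaluation data the method family is usually demonstrated
on): a straight cylinder along x, a quarter-arc tube (radius 20 mm), and a
90° planar crossing of two cylinders (tube radius 6 mm; FA 0.8 inside,
0.02 outside). Each voxel's fODF is a sum over its fibers of the
antipodally symmetrised Gaussian-in-angle kernel
$\exp(-\theta^2/2\sigma^2)$, σ = 20°, fitted to order-8 SH by least
squares; the peak field stores the analytic tangents with
$\alpha = \sigma\sqrt{2\ln(1/k)}$. The Gaussian kernel was chosen *because*
its fraction-crossing angle has that closed form, giving every α test an
analytic oracle; any smooth unimodal kernel would track the same but lose
the oracle. In the crossing region the two kernels are summed without
renormalisation, so peak heights differ from single-fiber voxels and the
relative threshold is genuinely exercised.

What the phantoms do **not** emulate: measurement noise on the SH
coefficients, partial-volume fading at bundle edges, dispersion or fanning
within a bundle, curving crossings, and realistic brain geometry. Passing
tests therefore demonstrate that the algorithms are implemented correctly
and behave as specified under clean conditions — not that the tracker's
output on real data is anatomically faithful, which for this family of
methods is established by comparison against offline trackers on real
acquisitions.

Problem sizes in the test suite and acceptance script were chosen to keep
runs at the seconds-to-minutes scale while still exercising the claimed
scales: 1000-seed bundles per phantom, 20 seeded repeats of the
deterministic-vs-probabilistic overlap, a 25,000-streamline tractogram
(500,000 points) for the octree oracle, and 10⁵ cone draws for the
sampling-law checks.

## Numerical choices and degenerate inputs

* **Voxel convention**: 0-based indices, voxel centre at integer
  coordinates, nearest-voxel via rounding — a point at a voxel centre
  unambiguously belongs to it. No interpolation of `f` or the mask
  (nearest-voxel lookup is the literal reading of the method); trilinear
  sampling is a known limitation, not an option.
* **Peaks on read** are renormalised when their magnitude deviates from 1
  by more than 10⁻³ (files in the wild carry magnitudes); all-zero slots
  are preserved as absent. Peak axes are expressed in world (RAS)
  coordinates — fixed and documented here rather than inferred.
* **TrackVis round-trip** stores 32-bit floats in voxel-mm with the
  half-voxel corner offset; coordinates survive to within 10⁻⁴ mm, counts
  exactly, and the resolved parameter record rides in the header's
  reserved field so a run can be recreated from its output.
* **Ties** in peak selection during tracking go to the lowest peak slot;
  exact antiparallel blends return the zero vector and terminate the
  half-track; `weighted_dice` of two empty maps is defined as 0 with a
  warning.
* **Density maps** walk streamline points, counting each streamline at most
  once per voxel; this is exact while the step size does not exceed the
  voxel size (true at the defaults) and a guard warns otherwise.
* **Octree**: closed-box containment (boundary points are inside), static
  one-pass build (point positions are known up front), leaf capacity 64,
  depth cap 8; queries are verified against a linear scan.

## Known limitations

* Nearest-voxel sampling makes streamlines sensitive to voxel-boundary
  effects; on the curved phantom the per-step turn concentrates at voxel
  crossings.
* α is quantised by the mesh (≈ one edge length); very tight cones
  (k → 1) are indistinguishable from deterministic tracking below that
  resolution, which is why the package states its accuracy claims in
  mesh-edge units.
* The tracker is single-threaded, pure R, vectorised across streamlines;
  1000-seed bundles on the phantoms take on the order of a second, but
  whole-brain scales are out of scope.
* Only NIfTI and TrackVis are read or written; no compressed streamline
  formats, no DICOM, and no rendering.
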