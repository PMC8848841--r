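---
title: "Estimating the dynamic rotation axis of the ulnohumeral joint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the dynamic rotation axis of the ulnohumeral joint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elbowaxis)
```

## The problem

During elbow flexion the ulna rotates on the humeral trochlea about an axis
that is classically approximated by the transcondylar line — the line
joining the centers of the medial and lateral epicondylar faces ("aspects")
of the distal humerus. Collateral-ligament reconstructions aim their humeral
tunnels at the point where that axis pierces the epicondyle, on the theory
that an attachment on the rotation axis stays isometric through flexion. If
the true axis migrates with flexion angle, a single isometric point does not
exist, and the surgically relevant question becomes *where on the
epicondylar face the axis pierces, and how that point travels with flexion*.

`elbowaxis` implements the full measurement chain for posed surface models
of the joint (e.g. reconstructed from time-resolved CT): estimate the
instantaneous rotation axis of each frame from the greater sigmoid notch of
the ulna, express where that axis pierces the medial and lateral aspects in
an anatomical coordinate system, normalize by the aspect radii, and test how
the pierce points migrate with flexion.

## The axis construction

The greater sigmoid (trochlear) notch of the ulna is nearly cylindrical, and
its cylinder axis coincides with the momentary hinge axis of the joint. The
estimator mirrors a manual reverse-engineering workflow:

1. **Landmark plane.** Three points registered in the deepest part of the
   notch define a cross-sectional plane (`plane_from_landmarks`). Because
   the landmarks sit in one notch cross-section, the plane's normal is the
   mediolateral direction.
2. **Offset sections.** The plane is offset along its own normal in 1 mm
   steps into 11 parallel planes, centered on the landmark plane
   (`offset_planes`). Both spacing and count are configurable; the defaults
   are the conventional ones.
3. **Section curves.** Each plane is intersected with the ulna surface
   (`section_curve`). A plane through a bone crosses several cortices, so
   among the connected intersection polylines the one nearest the landmark
   centroid is selected, and it is trimmed to the contiguous portion
   consistent with the circle seeded by the three landmarks. This automates
   the curve selection an operator performs by eye.
4. **Circle fits.** Each section curve gets a least-squares circle
   (`fit_circle`): a Kåsa algebraic fit followed by one geometric
   Gauss–Newton step. The fit is then iterated with a radial-deviation trim
   (`k = 3` standard deviations, floored at 0.5 % of the radius) so stray
   points adjacent to the articular arc — cortical side walls, noise — do
   not bias the center. Arcs subtending less than 60° as seen from the
   algebraic center are rejected as ill-conditioned rather than silently
   fitted.
5. **Axis.** The 11 circle centers are fitted with a total-least-squares
   line (`fit_axis`): the first principal axis of their centered
   covariance, with the centroid as the axis point and the rms
   perpendicular distance as the residual. Centers spreading less than
   1 mm along the principal direction are rejected. The direction sign is
   fixed toward lateral (+X) so downstream angles are comparable across
   frames.

As an independent cross-check, `helical_axis_oracle` computes the finite
helical (screw displacement) axis between two vertex-corresponding poses by
closed-form least-squares registration. On a fixed-axis motion the
notch-derived per-frame axes and the between-frame helical axes must agree;
this dual route is exercised by the test suite. Rotations under 1° leave
the helical direction ill-determined and are flagged unreliable.

## The anatomical frame and the intersection map

The landmark coordinate system of the distal humerus (`build_frame`) is
constructed from the two aspect circles (fitted to operator- or
generator-supplied rim points by a total-least-squares plane plus the same
circle engine), the humeral shaft direction, and a posterior hint:

* **X** — from the medial to the lateral aspect center (the transcondylar
  axis), mirrored for left elbows;
* **Z** — the component of `X × shaft` oriented posteriorly, hence exactly
  perpendicular to both X and the shaft;
* **Y** — `Z × X`, oriented superiorly.

When the shaft is not exactly perpendicular to X, the conventions
"Y parallel to the shaft" and "Y perpendicular to X and Z" conflict
slightly; the constructive order above resolves it by making Z exact and
letting Y be only approximately the shaft. The origin is the medial aspect
center projected along −X onto the humerus surface by ray casting (the
projection direction is otherwise under-determined); without a mesh the
medial center itself is used.

Each frame's axis is intersected with the aspect *planes*
(`intersect_axis_with_aspect`): the aspects are near-planar faces and the
summary figures live on a 2-D disk, so the plane — not the triangulated
surface — is the canonical target. Pierce points are expressed in frame
coordinates, and Y and Z are divided by the aspect radius
(`normalize_intersection`, in percent). The medial side is referenced to
the frame origin; the lateral side to the lateral aspect center expressed
on the same axes — the only reading under which a ±100 % disk is meaningful
on both sides, kept switchable via `lateral_origin`. Quadrants
(anterior/posterior × superior/inferior) follow the coordinate signs, with
exact zeros assigned to the positive class and flagged as ties so the
classification is deterministic.

Axis orientation is summarized by the angles between the axis and X after
projection into the coronal (XY) and horizontal (XZ) planes
(`axis_angles`), reported unsigned in [0°, 90°] with signed values retained
for trend directionality. The flexion angle of each frame is the dihedral
angle between the ulnar and humeral coronal planes, disambiguated by the
rotation sense about X (`flexion_angle`), with 0° at maximum extension.

`isometric_window` selects the frames whose normalized intersection stays
within ±20 % (configurable) of the aspect center on Y and Z simultaneously
on *both* sides — the frames for which a central tunnel is nearly on the
axis.

## Statistics

`linear_trend` is ordinary least squares from the normal equations with a
two-sided t-test on the slope (exact t distribution with n − 2 degrees of
freedom — frame counts per sequence are ~30, so the normal approximation is
avoided). Regressions pool frames by default; per-group use is up to the
caller. `sample_size_two_means` is the two-group normal-approximation
formula `n = ceil(2 (z_{1-α/2} + z_{power})² sd² / Δ²)` — with α = 0.05,
power = 0.8, means 2.6° and 5.7°, SD 2.2° it returns 8 per group, which is
the only standard reading of a "multi-sample mean comparison" reproducing
that published design. `angle_summary` reports mean, sample SD and range,
treating angles linearly (all quantities here stay below 90°, so no
wraparound handling is needed).

## The synthetic elbow

No participant imaging is distributed, so validation rests on a parametric
generator with exactly known kinematics:

* the **distal humerus** is a frustum whose end faces are the planar
  medial/lateral aspect disks (default radii 10 and 8 mm, 50 mm apart) —
  the generator returns the exact aspect circles;
* the **proximal ulna** is a curved shell whose concave inner surface is an
  exact cylinder arc (default radius 12 mm, width 18 mm, arc 170°) standing
  in for the greater sigmoid notch, with three registration landmarks
  emitted on the mid-width cross-section;
* `pose_sequence` carries the ulna rigidly onto a prescribed per-frame axis
  (direction given by coronal/horizontal tilt functions relative to the
  transcondylar line, point by an offset function) and rotates it by the
  flexion angle, storing the per-frame truth. By construction the posed
  notch cylinder axis *is* the stored axis, so the estimator is testable by
  parameter recovery in every frame.

Default sequences use 30 evenly spaced frames over a 106.5° range of
motion — a realistic dynamic-CT frame count and the reported mean range for
active flexion. The `drifting_axis` preset sweeps the unsigned horizontal
angle from 0° to 47° (cubically, so low flexion stays near the
transcondylar line), and raises the axis point by up to 5.7 mm superiorly;
that reproduces the qualitative published behaviour: medial intersections
migrate anterior-inferior → posterior-superior, lateral ones
posterior-inferior → anterior-superior, and only the frames below ~30°
flexion pass the ±20 % window on both sides. Vertex noise is i.i.d.
Gaussian per coordinate (seeded, caller's RNG untouched); its displacement
magnitude is chi(3)-distributed with mean σ√(8/π), which the tests verify.

What the generator does *not* emulate: realistic trochlear ridge geometry
(the notch is a clean cylinder arc), cartilage, soft tissue, CT intensity
formation, or inter-subject shape variation. Passing recovery tests
therefore demonstrates correctness of the geometry processing under known
kinematics — not clinical accuracy on real anatomy.

## Segmentation

`threshold_segment` applies the single-threshold rule (`intensity ≥ t`).
`mask_to_mesh` extracts the bone surface by naive surface nets (dual
contouring): one vertex per boundary cell at the centroid of that cell's
edge-midpoint crossings, one quad per sign-crossing voxel edge. The result
is closed and consistently wound by construction, and on binary masks it is
substantially more accurate than midpoint marching cubes (sphere-area error
≈ 2 % at 1 mm voxels vs ≈ 8 %), because the dual vertex averages away the
staircase. The largest connected component is returned (separating bones
that both exceed the threshold) with the component count attached. The
iso-level is the segmentation threshold itself; no smoothing is applied.
A single positive voxel yields a closed cube of side spacing/3 (volume
spacing³/27) — the expected behaviour of a midpoint dual method, worth
knowing when meshing very thin structures. No HU threshold default is
shipped: thresholds are scanner- and protocol-specific and must be
supplied.

## Numerical choices and edge cases

* Vertices exactly on a section plane are nudged by 10⁻¹² mm so crossing
  detection stays well-defined; the induced error is far below all stated
  tolerances.
* The axis estimator is rigid-equivariant: transforming mesh and landmarks
  transforms the axis. Exactness is limited by curve re-selection — a rigid
  transform can flip individual boundary points in or out of a trimmed
  section curve; the measured effect is ~10⁻⁴ mm and the property test
  bounds it at 10⁻³.
* Reversing the offset direction reproduces the same set of section planes
  (offsets are symmetric about the landmark plane), hence the same axis up
  to direction sign.
* Degenerate inputs fail loudly with specific messages: collinear
  landmarks, arcs under 60°, coincident circle centers, shaft within 5° of
  the transcondylar axis, axes parallel to an aspect plane, empty masks.
* All randomized code paths take explicit seeds; fixtures and pipeline
  outputs are byte-reproducible for a fixed seed and configuration.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they
measure: unit tests run on a coarsened mesh (1.2 mm vertex spacing,
5-frame sequences); the study-level checks use the full default geometry
(0.75 mm spacing, 30 frames, 11 sections per frame), 0.2 mm vertex noise
for the robustness condition, and 1000 null simulations for the type-I
check of the trend test. These sizes were chosen as the smallest at which
the checked quantities are stable across seeds.

## Known limitations

* The ±20 % window and all intersection coordinates inherit the aspect
  circle fits; badly jittered rim points propagate directly into the
  normalization.
* The estimator assumes the notch region is visible to every offset plane;
  narrow notches with wide offsets (count × spacing exceeding the notch
  width) will fail per-section with an informative error rather than
  extrapolate.
* Ligament length change along the reconstruction is out of scope — the
  pierce-point migration is a geometric proxy for isometry, not a strain
  measurement.
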