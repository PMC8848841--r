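# elbowaxis

Estimation of the dynamic rotation axis of the ulnohumeral (elbow) joint
from posed bone surface models, and mapping of where that axis pierces the
medial and lateral epicondylar faces of the distal humerus.

## Why

Elbow collateral-ligament reconstructions (MCL, LUCL) aim their humeral
tunnels at the presumed rotation axis of the joint — classically the
transcondylar line joining the centers of the medial and lateral aspects of
the distal humerus. If the instantaneous axis migrates with flexion, no
fixed attachment point is isometric, and the clinically useful output is a
map of the axis pierce points on each epicondylar face across flexion.
`elbowaxis` is for biomechanics researchers analyzing sequences of posed
bone meshes (e.g. from time-resolved CT): it turns per-frame ulna surfaces
plus a few registered landmarks into per-frame axes, normalized
intersection coordinates, quadrant labels, axis angles and trend tests.

## Method at a glance

Per frame, the instantaneous axis is recovered from the greater sigmoid
notch of the ulna, whose articular surface is nearly cylindrical:

1. a plane through 3 registered notch landmarks (normal = mediolateral);
2. 11 parallel section planes at 1 mm offsets, centered on it;
3. per plane, the intersection polyline with the ulna surface nearest the
   landmarks, trimmed to the arc consistent with the landmark circle;
4. per curve, a least-squares circle *C_k* (Kåsa seed + one Gauss–Newton
   step, radial-deviation trimmed);
5. the axis is the total-least-squares line through the centers of
   *C_1 … C_11* (first principal axis of their covariance).

In the humeral landmark frame (X transcondylar toward lateral, Y superior,
Z posterior, origin at the projected medial aspect center), each axis is
intersected with the aspect planes and normalized by the aspect radius
*r*: `y% = 100 · y / r`, `z% = 100 · z / r`. Axis orientation is
summarized by the angles between the axis and X after projection into the
coronal (XY) and horizontal (XZ) planes. An independent finite helical
(screw displacement) axis from vertex-correspondence registration serves as
a cross-check, and `sample_size_two_means` implements
`n = ceil(2 (z_{1−α/2} + z_{power})² σ² / Δ²)`.

Because no participant imaging is public, the package ships a synthetic
elbow generator with exactly known per-frame axes (`make_fixture`); every
stage is validated by parameter recovery against that ground truth.

## Worked example

Generate a 30-frame synthetic sequence whose axis tilts in the horizontal
plane with flexion (up to 47°) and climbs superiorly, then run the full
pipeline:

```r
library(elbowaxis)

fx <- file.path(tempdir(), "elbow_demo")
make_fixture("drifting_axis", fx, seed = 1)
res <- run_pipeline(list(input_dir = fx))
res
#> elbow axis pipeline: 30 frames analyzed, 0 failed
#>   coronal angle  0.0 (SD 0.0) deg
#>   horizontal angle 12.2 (SD 14.2) deg
#>   isometric window frames: 1 2 3 4 5 6 7 8 9
```

The per-frame axes tilt away from the transcondylar line as flexion grows —
frame 15 (flexion ≈ 51°) already points 5.3° off in the horizontal plane:

```r
res$axes[[15]]
#> rotation axis: point (25.00, 2.75, 0.00) mm, direction (0.9957, -0.0000, -0.0922), rms 6.84e-05 mm
```

The medial pierce point moves posteriorly and superiorly with flexion
(positive slope of `z%` on flexion, ~2 % of the aspect radius per degree),
and the ±20 % isometric window contains exactly the frames below ~30°
flexion:

```r
res$trends$medial_z_vs_flexion
#> linear trend: slope 2.047 (t = 9.3, p = 4.7e-10, n = 30)

res$window$selected_frames
#> [1] 1 2 3 4 5 6 7 8 9
max(res$frames$flexion_deg[res$window$selected_frames])
#> [1] 29.38294
```

So on this synthetic motion there is no fixed isometric point: a
near-central tunnel position is only justified while the elbow stays below
about 30° of flexion — which is precisely the kind of statement the
pipeline is designed to make quantitative on real data.

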