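---
title: "Methods: contour-based segmentation and 3D morphometry of tubular organs"
author: "cardiomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contour-based segmentation and 3D morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`cardiomorph` quantifies the morphology of two-layered tubular organs —
the motivating system is the embryonic zebrafish heart, with a muscular
outer layer (myocardium), an endothelial inner layer (endocardium), a
blood-filled lumen, and an acellular extracellular-matrix (ECM)
compartment between the two layers. The input is a two-channel
fluorescence z-stack in which each tissue layer carries its own label;
the ECM carries no label and is recovered purely by set algebra on the
segmented layers.

The processing chain is:

1. **Per-slice contouring.** Each z-slice of each channel is thresholded
   (per-slice Otsu by default) and the 0.5 iso-contours of the binary
   foreground are traced as closed polygons. Every polygon gets a
   containment depth; even depth means it outlines the external border of
   the tissue, odd depth means it outlines a lumen. The filled external
   mask is the union of filled even-depth polygons, the filled internal
   mask the union of filled odd-depth polygons, and the tissue mask is
   their exclusive disjunction (XOR) — an identity that holds bit-exactly
   by construction. The stack of per-slice contours and masks is the
   *contour library*, the substrate for everything downstream.
2. **Negative-space (ECM) extraction.** With `A` the filled internal
   contour of the outer layer (the outer layer's lumen) and `B` the
   filled external contour of the inner layer, the ECM is
   `A XOR (A AND B)`, i.e. `A AND NOT B`. Inner-layer voxels protruding
   outside `A` — segmentation noise in real data — are clipped and
   reported as a leak count rather than silently creating negative
   compartments. With that clipping, myocardial tissue, endocardial
   tissue, lumen and ECM tile the filled external volume of the outer
   layer exactly, so their percentage shares sum to 100.
3. **Meshing.** Binary masks become watertight triangle meshes in
   physical micrometre coordinates via marching tetrahedra at the 0.5
   level of the binary field (6-tetrahedron cube split sharing the main
   diagonal; one-voxel zero padding closes foreground touching the array
   border), followed by shrink-free Taubin smoothing. Volumes come from
   the divergence theorem and are validated against voxel counts.
4. **Centreline.** The lumen midline between the user-supplied venous and
   arterial pole anchors realizes the classical maximal-inscribed-sphere
   definition discretely: the Euclidean distance transform gives every
   lumen voxel its clearance, and Dijkstra's algorithm on the
   26-connected voxel graph with edge cost
   `step length / (eps + mean clearance)` finds the path that stays as
   deep in the lumen as possible. The grid path is Gaussian-smoothed
   along arclength (mirror padding keeps the anchors in place) and
   resampled uniformly. The looping ratio is centreline arclength divided
   by the straight pole-to-pole distance; 1 for a straight tube, rising
   as the organ loops.
5. **Partitions.** A user-defined finite disc (centre, normal, radius)
   splits masks or meshes into atrium and ventricle by the sign of the
   projection onto the disc normal; left/right splitting classifies each
   voxel by the sign of the triple product of its offset from the nearest
   centreline point with the local tangent and the dorsal reference.
   Chamber orientation angles project each chamber's pole-to-apex axis
   into the ventral or lateral view plane and measure the signed angle to
   a reference vector.
6. **Morphometry fields.** Chamber geometry is summarized by the
   axis-aligned bounding ellipsoid (semi-axes = half extents along the
   scene triad) and its asphericity; *ballooning* maps the distance from
   the centreline to each surface vertex; *thickness* maps the exact
   point-to-triangle distance from each carrier vertex to the opposing
   surface (an AABB tree makes the exact minimum fast).
7. **Unrolling.** Planes normal to the (pole-extended) centreline cut the
   heatmapped mesh at uniformly spaced stations; each intersection loop is
   parameterized by the signed circumferential angle about the station,
   with the ventral direction (the negated dorsal reference projected
   into the plane) at 0° and the dorsal-most point at ±180°. Scalars are
   averaged per angle bin into a (station × angle) matrix. Cells the mesh
   does not reach stay missing; they are never interpolated, and
   cross-specimen averaging is per-cell over contributors only, with the
   contributor count and the sample (n−1) standard deviation reported.
8. **Cell analysis.** Nuclei centroids from an external spot detector are
   assigned to chambers by the same disc rule (on-plane nuclei go to the
   ventricle), to quadrant regions (dorsal / ventral / outer / inner
   curvature, 90° sectors about the centreline frame), and every nucleus
   acts as the seed of a cluster of its k nearest same-chamber
   neighbours; the mean seed-to-neighbour distance is the internuclear
   distance (IND), a proxy for cell size.

# Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| threshold policy | per-slice Otsu | – | global fixed level available; the threshold rule is not prescribed by the workflow this reimplements |
| `minArea` | 4 | px | suppresses speck contours before classification |
| smoothing iterations (mesh) | 10 | – | Taubin λ = 0.5, μ = −0.53; volume change ≤ 2% |
| `eps` (centreline cost) | 0.1 × min spacing | µm | keeps edge costs finite at zero clearance |
| resampling step | min spacing | µm | centreline point spacing |
| smoothing σ (centreline) | half the mean inscribed radius | µm | tube-scale: removes grid jaggedness without shortcutting bends |
| pole extension | 5% of arclength per end | µm | so end stations still cut the mesh transversely |
| `nPlanes` × `nAngleBins` | 100 × 72 | – | 5° bins; the number of planes is a free choice of the method |
| `k` neighbours (IND) | 4 | – | cluster size of seed + 4 neighbours |
| tie-breaks | ventricle / right / CCW-next | – | disc plane, tangent–dorsal plane, 45° sector boundary |

# The phantom generator

All validation runs on synthetic phantoms with closed-form truth:
straight, bent (circular-arc), nested and bulged tubes, concentric
spherical shells, a two-chamber ellipsoid pair with a 90° inter-axis
angle, and a cubic nuclei lattice. Voxelization is by centre sampling — a
voxel is foreground iff its centre lies inside the analytic solid — so
rasterization error is bounded by surface area × voxel size and every
tolerance in the test suite is derivable. Optional salt-and-pepper or
Gaussian noise exercises the despeckle/threshold path; noise never
alters the stored truth record, and generation is seed-deterministic.

The phantoms emulate the geometry and the two-channel labelling of real
stacks, with the default spacing (0.5, 0.25, 0.25) µm mimicking the
anisotropic sampling of lightsheet acquisitions. They deliberately do not
emulate a point-spread function, depth attenuation, intensity
inhomogeneity, or contact between layers; passing tests therefore
demonstrate the correctness of the geometry pipeline, not robustness to
every imaging artifact of live microscopy — the per-slice manual override
hook exists precisely for slices where automatic contouring fails on
real data.

The test suite runs the phantoms at 0.5–1 µm isotropic grids (arrays of
roughly 10⁵–10⁷ voxels, meshes of 10⁴–10⁵ faces), chosen so the whole
suite completes in a few minutes while keeping every feature ≥ 5 voxels
across, the regime in which the stated tolerances hold.

# Numerical choices and degenerate inputs

* **Iso-surfacing.** The 6-tetrahedron split's face diagonals are
  translation invariant, so adjacent cubes tile consistently and the
  surface is watertight with a consistent outward orientation (enforced
  to positive signed volume). Vertices are deduplicated by voxel pair,
  making meshing bit-deterministic. An isolated voxel reconstructs to a
  closed polyhedron of exactly half a voxel volume — sub-voxel solids
  are at the resolution limit by construction.
* **Thickness/ballooning.** Distance queries are pure minima (AABB-tree
  branch and bound for triangles, segment-wise scan for polylines) and
  independent of traversal order.
* **Contour fill.** Even-odd scanline filling at pixel centres; pixel
  centres lying exactly on a polygon edge are filled, so integer-valued
  manual override polygons include their boundary. Contours touching the
  image border are closed along it (cropped organs commonly touch the
  crop box).
* **On-plane ties.** Voxels exactly on a cutting plane go to the
  ventricle (disc) or the right side (left/right split); nuclei on a 45°
  sector boundary join the counter-clockwise-next sector. All three are
  arbitrary but deterministic; note that a label swap under normal
  flipping is exact only off the tie set.
* **Empty foreground** is a valid contouring result (empty list, empty
  masks), not an error; empty masks are rejected only where geometry is
  required (meshing).
* **Centreline ends.** Near capped tube ends the inscribed radius is
  bounded by the cap distance, not the lateral wall; clearance
  guarantees are therefore stated away from the poles. Pole anchors are
  snapped to the nearest lumen voxel within ~2 voxels; anchors farther
  out are rejected.
* **Cylinder caps in thickness maps.** When two nested solids share
  end caps, cap vertices see the opposing cap rather than the lateral
  wall, so cap scalars deviate from the lateral gap; lateral assertions
  exclude the caps.

# Design decisions that were genuinely open

* *Semi-automatic contour selection* is realized reproducibly as
  automatic parity classification + a minimum-area filter + an explicit
  per-slice override file; there is no interactive step, so a run is a
  pure function of its inputs.
* *Asphericity* is the coefficient-of-variation form
  `sqrt(sum((s_i - mean(s))^2)) / mean(s)` over the semi-axes: 0 exactly
  for a sphere, monotone in axis disparity, dimensionless. The bounding
  (extent-based) ellipsoid is used rather than a least-squares fit, to
  match the projection-onto-reference-faces construction it mirrors.
* *Looping ratio orientation*: looped/linear (≥ 1) rather than its
  inverse, so the ratio increases as looping proceeds.
* *Unrolling* bins by circumferential angle (anchored ventrally) rather
  than by normalized loop perimeter, which keeps the 0°/±180° anchoring
  exact on every station; when a plane cuts several loops (both chambers
  of a looped organ), the loop whose centroid is nearest the station is
  kept and the number of discarded loops is logged.
* *All-seeds IND*: every nucleus serves as a seed, so clusters overlap;
  this is deterministic, unbiased by any seed-selection rule, and makes
  the per-chamber mean IND exactly the count-weighted mean of the region
  INDs.
* The 270° bent-tube looping truth is the arc/chord closed form
  `phi / (2 sin(phi/2))` ≈ 3.332 (chord `sqrt(2) R`, arc `3 pi R / 2`).

# Known limitations

* Layers are assumed strictly nested per slice; contact or crossing
  between layers is clipped into the leak diagnostic rather than
  resolved.
* Centreline extraction requires a connected lumen between the poles and
  does not handle branching vessels.
* Unrolled heatmaps of strongly looped organs legitimately contain gaps
  near the inner curvature; downstream averaging reports fewer
  contributors there rather than imputing.
* Sub-voxel walls (< 2 voxels) are rejected by the phantom generator and
  are below the method's resolution on real data too.
* The bounding ellipsoid is axis-tagged by the scene triad; if the organ
  is strongly oblique to the triad the width/length/depth naming (not the
  asphericity) loses anatomical meaning.
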