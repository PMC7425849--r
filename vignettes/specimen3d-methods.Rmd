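---
title: "Methods: how specimen3d processes a turntable capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how specimen3d processes a turntable capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`specimen3d` covers the post-reconstruction half of turntable photogrammetry
for natural-history specimens: standardized images in, a measured, textured,
measurement-ready 3D model out. This vignette is the package's own account of
the methods, the tunables, and the choices made where the design was open.

## The capture model

A turntable session is modeled as a pinhole camera orbiting a static
specimen: `round(360/step_deg)` azimuths per rotation at each elevation
(defaults 3.75° and −45°/0°/+45°, i.e. 96 × 3 = 288 frames). Poses are exact
world-to-camera transforms (`x_cam = R x + t`, `u = fx·x/z + cx`); the
fixture renderer stores them losslessly, emulating a reconstruction whose
alignment succeeded perfectly. Scene bookkeeping outside the images is kept
in *model units* — an arbitrary global scale, as photogrammetric
reconstructions have — and only the scale-calibration stage converts to
millimeters.

Lighting is two softboxes that ride with the camera (as on a physical rig,
where the specimen rotates and the lights do not), with Lambertian shading
`ambient + diffuse · mean(max(0, n·l))`. The constants (0.7208, 0.34) are
calibrated so a camera-facing surface reproduces its albedo exactly — the
synthetic analogue of an exposure-standardized studio capture. There is no
specular term: the physical workflow removes highlights with polarizers, so
the fixtures emulate the already-unpolarized image.

### What the fixtures emulate, and what they do not

`generate_specimen()` builds a closed surface of revolution — ellipsoidal
body, conical bill, flattened tail fin — whose landmark separations are
exact by construction (the bill tip and the bill-base ring vertex are placed
so their chord is `bill_length_mm` to machine precision). Seeded variation
perturbs body proportions and adds smooth radial bumps, windowed so the
landmark construction is untouched. `inject_defects()` reproduces the
defects real scans show: open holes, floating debris shells under 1% of the
surface area, a stand tube penetrating the underside, optionally non-manifold
fin faces.

The fixtures deliberately do **not** simulate feather microstructure, fine
surface texture, reconstruction noise correlated along the surface,
misestimated poses, lens distortion, or specular residue. Passing tests
therefore demonstrate that the *processing chain* is correct and
shape-preserving under known conditions; they do not bound the errors a real
camera, a real alignment, or loose plumage would add.

## Image preparation

Exposure and white balance are standardized against the chart's 75% neutral
chip: per-channel gains `g_c = reference_c / observed_c` computed from
linear-light values and applied in linear RGB (inverse sRGB companding,
gain, re-encode). Linear light is a deliberate choice — the photographic
tooling this replaces does not document its working space, and gain
correction is only radiometrically meaningful on linear intensities. The
operation is idempotent and leaves the chip within 1/255 of its reference.

Masking measures each pixel's CIELAB distance to the nominal backdrop color;
pixels with ΔE above `threshold × 100` (default threshold 0.12, i.e. ΔE 12)
are foreground. A morphological closing with a 2 px disc bridges pixel noise,
then the largest component plus anything touching it is kept. The default
tolerates mild shading on a matte backdrop while rejecting chart and ruler,
which appear as separate components.

## Scale calibration

Ruler markers clicked in a few photos are triangulated by linear least
squares over back-projected rays (`Σ (I − dᵢdᵢᵀ) x = Σ (I − dᵢdᵢᵀ) cᵢ`);
bundles whose normal-equation condition number exceeds 1e8 are rejected as
near-parallel. The photo choice mimics an operator: candidates are ranked by
the projected ruler length (how clearly the ruler is seen) and picked
greedily subject to a ≥ 60° azimuth spacing, which keeps triangulation
baselines wide; 4 views is the default, matching the 3–5 used in practice.
Under 0.5 px Gaussian click noise the median recovered factor is within
0.5% of truth (the per-trial distribution has a tail, which is why the
median is the stated statistic).

## The mesh chain

**Voxel remesh.** The surface is re-sampled through a voxel grid: an x-ray
parity fill classifies interior nodes, a conservative half-voxel unsigned
band keeps sub-voxel-thin features (a bill tip, a fin edge) alive as a
one-cell shell, and naive surface nets extract one vertex per mixed cell
with quads across sign-changing edges. Every new vertex is then projected
onto the nearest point of the input surface, so nothing is displaced by more
than the voxel quantization. The output is watertight for closed input with
edge-length CV well under 0.5. Grid nodes carry a fixed sub-voxel offset so
they cannot land exactly on mesh vertices or edges. The default
`voxel_size = 0.5` mm is roughly one fifth of the smallest feature the
fixtures carry (the ~2.5 mm bill base), the usual sampling margin for
preserving a feature through a grid.

**Quality heatmap.** The decimation prior is discrete mean curvature
(cotangent Laplacian with barycentric areas — correct on the anisotropic
ring meshes the fixtures produce), normalized robustly by its 95th
percentile and clamped to [0, 1]; boundary vertices are excluded because the
cotangent sum is meaningless there. Painted regions (spheres, boxes or
explicit vertex sets) override to 1.

**Decimation.** Quadric-error-metric edge collapse with area-weighted plane
quadrics, boundary constraint planes, the link-condition test (no new
non-manifold edges), a normal-flip rejection, and the quality multiplier
`1 + k·max(q_endpoints)` on each collapse cost; `k = 9` makes a fully
painted vertex ten times more expensive to remove. Collapse order is a
strict priority queue with (cost, lower index, higher index) ordering, so
results are bit-reproducible.

**Cleanup.** `clean()` removes components below 1% of total area, deletes
faces on non-manifold edges, repairs collapsed-shell slivers by vertex
welding and shortest-edge collapse (never by deleting faces from a closed
surface), and fills boundary loops up to 10% of the bounding-box diagonal in
perimeter by centroid fans; larger holes are reported, not filled. The
operation is idempotent.

**Smoothing.** Taubin's λ|μ pair (defaults 0.5 / −0.53, 10 iterations) on
the uniform Laplacian. The defining property — closed-mesh volume within 2%
where an equal-iteration pure Laplacian loses over 10% — is asserted on a
~1500-face fixture, coarse enough that Laplacian shrinkage is blatant. One
honest caveat: white vertex noise is attenuated about 2.6×, not more, at
these classic settings — the filter's pass band necessarily keeps the
low-frequency share of the noise — and the tests state that measured figure.

**Alignment.** Principal axes of the vertex cloud map to x/y/z in descending
variance with a rigid (det +1) rotation; axis signs follow the third moment
(bill-ward positive skew toward +x), with a deterministic vertex-index
tie-break and an `ambiguous` flag for near-isotropic shapes. Alignment is
applied after baking (it changes vertex coordinates, not UVs, so the baked
texture remains valid) and measurement results are invariant to it.

**UV atlas.** Faces go to whichever of 8 bounding-box-corner directions
maximizes `|n·d|` (a 6-axis preset exists); connected runs of same-direction
faces become sub-charts; each is flattened by planar projection plus a
conformal relaxation pass (per-face isometric embeddings fitted by
similarity transforms and averaged), scaled to true 3D area, and shelf-packed
with a gutter (default 4 texels). With the corner preset the worst
projection obliquity is `1/cos ≈ 1.73`, which is why ≥ 95% of faces land in
the [0.5, 2] normalized area-distortion band.

## Texture baking

Each covered texel maps through the atlas to a surface point. For each view,
the mesh's own depth buffer provides the occlusion test; unmasked, unoccluded,
camera-facing samples contribute their bilinear image color in linear light
with weight cos² of the view angle. The cos² favoritism toward frontal views
is a recorded substitution — the commercial texturing step this replaces does
not document its blend. Unseen texels and the inter-chart gutter are
in-painted by iterative nearest-neighbor dilation (4 gutter passes), which
prevents seam bleed in mip-less viewers. Baking is deterministic and
invariant to image order.

## Phenomics

`measure()` is the caliper analogue: landmarks snap to the nearest surface
point (rejected beyond 1 mm — if a feature eroded that far the measurement
would be meaningless) and the chord distance is reported; an edge-graph
geodesic is available for surface-bound traits. `compare_measurements()`
reports the mean absolute difference, mean relative error, the naive
repeatability `1 − mean|d−r| / mean(r)` *and* ICC(A,1) — both are given,
clearly labeled, because informal repeatability figures in collections
practice rarely state a formula. Color clouds weight every sampled texel by
the 3D area it represents (face area / sampled texels on that face), so
weight fractions are invariant to UV stretch — the defense against
flattening bias — and sum exactly to the covered surface area.

## Problem sizes and determinism

The shipped tests run the chain at desk scale: fixture meshes of roughly
2–6 k faces (subdivision 3–4), remeshed to ~80 k at 0.5 mm voxels and
decimated to 10%; captures of 12–36 frames at 256 px for interactive stages,
with the full 288-frame schedule exercised for the capture-count law and the
constant-albedo bake check (at 512² texels); batch accuracy is measured on
10–20 seeded specimens. Production polycounts in the millions differ only in
constants: every threshold in the chain is scale-free or expressed in
physical units. All randomness flows through per-call seeded generators that
save and restore the global RNG state, so identical seeds give bit-identical
meshes, captures and textures.

## Known limitations

* Reconstruction itself (alignment, dense matching) is out of scope; the
  package starts from posed images and a mesh.
* The unsigned-shell fallback for open input meshes is a degraded path:
  it doubles thin regions and relies on `clean()` to absorb the collapse.
* Quad retopology is not offered; output stays triangulated.
* Color clouds inherit whatever shading residue baking leaves; with the
  fixture lighting that residue is a few ΔE at grazing angles, but real
  captures with harsher lighting would need flat-field correction first.
* The repeatability fraction is descriptive, not a substitute for a designed
  repeatability study with repeated digitizations.
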