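---
title: "Virtual osteotomy planning and 3D morphometry for bipolar hip allografting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual osteotomy planning and 3D morphometry for bipolar hip allografting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxaplan)
```

## The problem

Bipolar osteochondral allograft transplantation of the hip replaces both
articular surfaces of the joint — the femoral head and the acetabulum —
with size-matched donor grafts.  Two things decide whether the
reconstruction can work: how faithfully the executed osteotomies reproduce
the virtual surgical plan (femoral neck version, inclination and length
drive hip stability), and how intimately the donor graft apposes the
recipient bed (osseous integration proceeds by creeping substitution across
the interface, so dead space is the enemy).  `coxaplan` implements the
computational side of this workflow: planning biplanar osteotomies from
anatomic landmarks, virtually executing and checking them on bone surface
meshes, measuring postoperative alignment from CT, quantifying the
donor–recipient interface gap, and comparing guided against freehand
execution statistically.

Because no imaging data accompany the motivating experiment, the package
carries a first-class synthetic-data module.  Every measurement the
pipeline makes can therefore be checked against known ground truth, from
single geometric fits up to the full CT round trip.

## Geometry and measurement conventions

All computation happens in a right-handed physical frame in millimetres;
angles are reported in degrees.  CT volumes are mapped to physical space at
load time (voxel index through spacing/origin/direction), so downstream
code never sees voxel indices.

The femoral measurements follow the standard CT morphometry chain:

1. a least-squares sphere is fitted to the femoral-head surface region
   (algebraic linear fit for initialization, then Gauss–Newton refinement of
   the orthogonal distances; 100-iteration cap, 1e-10 parameter tolerance —
   both criteria are available, orthogonal-distance is the default and the
   reported one);
2. the diaphyseal axis is the refined central axis of the shaft region
   (principal direction through the centroid, then minimization of the
   radial-distance variance over direction and transverse offset);
3. the neck axis runs from the fitted head centre through the centroid of
   the neck surface region, directed at the head;
4. the anatomic frame is built from the diaphyseal axis and the
   transcondylar axis: the mediolateral axis is the transcondylar direction
   orthogonalized against the shaft, the craniocaudal axis completes the
   right-handed triad and is flipped for left femora so "cranial" is
   side-consistent.

**Inclination** is the unsigned angle between the frontal-plane projection
of the neck direction and the *distally* pointing diaphyseal direction
(about 135 degrees in a normal canine femur).  **Version** is the signed
angle between the transverse-plane projections of the neck direction and
the mediolateral axis, with a cranially directed neck (anteversion)
positive on both sides.  **Neck length** is the distance from the head
centre to the point where the neck axis meets the diaphyseal axis; since
two measured 3D axes are generically skew, the closest-approach point on
the neck axis is used, which coincides with the intersection whenever the
axes are coplanar.  These conventions are deliberate choices, documented
rather than inferred: the source workflow's CAD environment snapped axes
interactively and did not state a sign convention.  Defining both
measurement planes from the femoral frame rather than the scanner axes
makes every measurement invariant under rigid repositioning of the limb,
which the test suite asserts to 1e-6.

## Chevron osteotomy planning

The osteotomy plan derives from four landmarks on the physeal scar:
craniomedial, craniolateral, caudomedial, caudolateral.  Two planes are
built — one through the craniomedial/caudomedial/craniolateral triple, one
through the caudomedial/caudolateral/craniolateral triple.  The two
landmarks shared by both triples (caudomedial, craniolateral) necessarily
lie on both planes, so the chevron ridge is the line through them; the
implementation asserts this as an invariant rather than constructing it
independently.  Plane normals are oriented so the femoral-head side is
positive, resolved against the head-region centroid.  The dihedral angle of
the chevron is an emergent property of the landmarks; no default is
imposed.

Virtual osteotomy clips a watertight surface mesh with both planes.
Crossing triangles are split with intersection points computed once per
mesh edge (so shared edges stay exactly shared), and each cut cross-section
loop is closed by deterministic ear clipping; a multiply-connected
cross-section (a shell cut into an annulus) is capped loop-by-loop with the
orientation induced by the cut boundary, which keeps both the enclosed
volume and ray parity exact.  Graft plus remainder volumes reproduce the
input volume to 0.1% over random poses.  Graft thickness is measured by
casting rays from articular vertices along inward normals onto the cut
faces; the 8 mm bound reflects the working band for osteochondral grafts
(3–8 mm: thick enough for structural integrity, thin enough to limit the
transplanted marrow and the recipient's immune response to it).

## Segmentation and gap volumetry

Bone is segmented by inclusive HU thresholding (default 300 HU, ordinary
bone-window practice; the source protocol names only the scanner's bone
reconstruction algorithm).  Surfaces are extracted at the 0.5 level of the
binarized field by marching tetrahedra on the Freudenthal six-tetrahedron
cube decomposition.  That decomposition is translation-consistent across
cube faces, which makes watertightness a structural property instead of a
table-correctness property — the reason it was chosen over classic
256-case marching cubes, which it matches in contract (vertices at voxel
edge midpoints).

The donor–recipient gap is segmented inside a region of interest with an
inclusive upper bound of 250 HU.  The source workflow outlined the region
and cleaned the threshold result manually; the package replaces both steps
reproducibly: the region of interest is the intersection of the two bone
masks' 2 mm Euclidean dilations minus the bones, and candidate voxels are
kept only if their 26-connected component touches both bone surfaces.
Volumes are voxel counts times voxel volume — no subvoxel estimation, so
accuracy statements are tied to the stated voxel size (at 0.25 mm the
hemispherical-shell benchmark is recovered well within 10%; halving the
voxel size roughly halves the error).

## The synthetic data module

`generate_femur()` builds a parametric canine proximal femur: head sphere,
neck cylinder, diaphysis with condylar prominences, optional marrow
interior.  The components are individually watertight and overlap; the
rasterizer fills their union by parity counting along voxel columns and
paints nested interiors innermost-first (mesh booleans are out of scope and
nothing downstream needs them: surface regions come from exact parametric
samples, volumes from the rasterized union).  The neck direction is
constructed so that the requested inclination and version are exactly what
the measurement definitions above return — for inclination $\iota$ and
version $v$ the unnormalized direction is $(\sin\iota,\ \sin\iota\tan v,\
-\cos\iota)$ in the (medial, cranial, proximal) frame — which makes
parameter recovery a genuine end-to-end identity check, not a fit to the
generator's internals.

Defaults describe a medium adult dog: head radius 10 mm, neck radius 5 mm,
neck length 35 mm, inclination 135°, anteversion 20°, shaft radius 8 mm.
The physeal landmarks sit on the head–neck junction ring at the
cranial/caudal-by-medial/lateral diagonal positions, offset axially
(craniolateral most proximal, caudolateral most distal, ±2.5 mm; medial
points ±1 mm) to encode the scar's oblique course — without those offsets
the four points would be concyclic and the chevron would degenerate to a
single plane.  Rasterization HU values are plausible constants, not a
scanner model: cortical/subchondral bone 1200, marrow 200, soft tissue 40,
air −1000.  Marrow (200 HU) is deliberately placed between the gap bound
(250, above it) and the bone bound (300, below it) so both thresholds do
discriminative work in the round trip.  Gaussian vertex noise (default off;
0.2 mm in the stressed tests) emulates segmentation surface jitter.

The graft-bed scene mimics the reamed acetabulum: a solid spherical cap
(donor) concentric with a socket surface (recipient) on a base plate, the
radial separation being the controlled gap width.  The plate closes the
construct so the enclosed low-density space is exactly the spherical shell
between the two surfaces, whose closed-form volume (difference of two
plane-cut spherical caps; $(2/3)\pi(r_b^3-r_g^3)$ for the hemisphere) is
recorded as ground truth.

What the generator does *not* emulate — and what green tests therefore do
not certify for clinical data — includes real anatomic shape variation
(no statistical shape model), partial-volume blur and scanner noise,
osteophytes or dysplastic remodelling, and metal artefact from fixation
wires.

## The synthetic paired study

`run_pipeline()` simulates the comparative experiment at its published
scale: five paired subjects; per subject a virtual plan from the guide-side
femur, mirrored across the sagittal plane to provide contralateral targets
(mirroring is an involutive isometry, so inclination, neck length and
|version| carry over exactly); each arm's postoperative outcome is produced
by re-generating the femur with arm-specific execution errors and
re-measuring it through the full mesh pipeline.  The error models are
half-normal with the observed arm statistics: guide version error
|N(0, 1°)| (mean ≈ 0.8°), freehand |N(7°, 4°)| (mean ≈ 7°); inclination
|N(0, 5°)| vs |N(8°, 6°)|; neck length |N(0, 1.25 mm)| vs |N(3, 2 mm)|.
Deviations from plan are compared with one-tailed paired t-tests
(direction supplied explicitly: guided deviates less), with Shapiro–Wilk
normality reported on the paired differences — the quantity that actually
enters the t statistic.  No multiple-testing correction is applied,
matching the source analysis.  Donor–recipient matching maximizes the
number of pairs satisfying the 1–4 mm acetabular-diameter window and then
centres the differences at 2.5 mm — an explicit, reproducible objective
standing in for pairing by eye; it is solved exactly by dynamic programming
over donor subsets (the study scale is five dogs; the implementation is
exact to 16 donors).

## Numerical choices and degenerate inputs

* Collinearity and coplanarity are tested against scale-relative
  tolerances (1e-8 of the configuration size), not absolute ones.
* Sphere fitting rejects fewer than four or coplanar points; axis fitting
  rejects clouds whose first principal extent is less than twice the
  second.
* Axis direction signs are deterministic: toward an anatomic hint when one
  is supplied, otherwise positive dot with +z, ties toward +x then +y.
* On-plane vertices in mesh clipping are classified with a tolerance of
  1e-9 of the bounding-box diagonal; faces lying entirely in the plane
  belong to the positive side only, which makes repeated clipping with the
  same plane idempotent and keeps the two sides disjoint.
* Landmark superimposition refuses an optimal transform with a negative
  determinant instead of silently reflecting — opposite-handed landmark
  sets almost always mean mislabelled correspondence.
* Rigid-transform validation requires orthogonality to 1e-6 and a positive
  determinant.

Problem sizes in the shipped tests are chosen for single-CPU runs: the
recovery grid uses the default tessellation (about 3,500 vertices per
femur), the CT round trip and the gap benchmark rasterize at 0.25 mm over
a roughly 30 mm construct, and the study simulation runs five subjects.
All statements about accuracy above are computed by the test suite or the
acceptance script, not quoted.

## Known limitations

* Volume I/O is NIfTI-only; meshes move as STL/PLY.  DICOM series must be
  converted upstream.
* The exact matching solver is exponential in donors beyond its DP window
  (16) and refuses larger instances rather than approximating.
* Gap volumetry reports voxel-counted volume; at coarse spacing a
  zero-width interface can report a small positive volume where the two
  tessellated surfaces leave sub-voxel slivers.
* Region labels (head/neck/diaphysis/articular) are inputs — from the
  generator, a label file, or the nearest-primitive classifier for
  re-extracted synthetic surfaces.  No automatic anatomic parcellation of
  real bones is attempted, and acetabular cup orientation is not measured.
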