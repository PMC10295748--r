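---
title: "Serial-grinding reconstruction and stent lumen morphometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial-grinding reconstruction and stent lumen morphometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentmorph)
```

## The measurement problem

Stent prototypes for the Eustachian tube (ET) are evaluated ex vivo by
implanting them in the cartilaginous ET of body donors, embedding the
harvested specimen in a cylindrical epoxy block, and grinding the block away
in fine steps (nominally 0.2 mm per plane once the stent is reached), with
each freshly exposed plane photographed under a stitching microscope. The
stack of section images is the only record of the specimen; everything
quantitative — how wide the stent lumen stayed open, where the stent sat
between the isthmus and the pharyngeal ostium, how the lumen cross-section
was squeezed by the tubal cartilage, and how its long axis rotated along the
tube — must be reconstructed from it.

Three systematic effects stand between the raw images and those numbers:

1. **In-plane misalignment.** Each photograph has its own arbitrary
   translation and rotation. The embedding mold casts two non-congruent
   grooves into the block rim; because the grooves are distinguishable (one
   wide, one narrow, at an angular offset different from 180°), they
   determine the rigid pose of every section uniquely, including flips.
2. **Grinding-depth error.** The machine does not remove exactly the
   nominal depth per plane. Comparing the reconstructed volume with a
   trusted-geometry reference scan (cone beam CT of the intact block)
   exposes the average per-plane excess, which is then applied uniformly —
   one value for all planes and samples, mirroring how such corrections are
   applied in practice.
3. **Block-vs-stent axis tilt.** The stent is not parallel to the block
   axis, so grinding planes cut it obliquely and inflate its apparent
   diameter by `1/cos(tilt)`. All measurements are therefore taken in
   virtual planes perpendicular to the stent's own fitted axis.

Per cross-section the package measures the longest diameter `dL` (a
Feret-type, ruler-style chord), the perpendicular short diameter `dS`
through the midpoint of `dL`, split by that midpoint into a cartilage-facing
part `D1` and an opposite part `D2` (`D1 + D2 = dS` by construction), the
elliptical area `pi/4 dL dS`, the pixel-counted area where available, and
the orientation of the long axis relative to the first stent section. The
elliptical approximation is validated against the pixel-counted area in the
grinding planes; on elliptical lumens the deviation stays below 5%.

## The phantom: what it emulates and what it does not

Because no specimen images are distributed, the package ships a first-class
synthetic phantom (`phantom_spec()`, `build_phantom()`) that emulates the
embedded specimen: the epoxy disk with both rim grooves, soft tissue with a
cartilage band on one side, a tubal lumen that is collapsed (a dark cleft)
outside the stent, and a stented lumen segment whose long/short diameters,
D1/D2 split, and long-axis orientation follow prescribed analytic profiles.
The geometry is generated at a *true* plane spacing while the stack declares
the *nominal* spacing, so grinding-depth error is injected exactly as it
occurs; per-slice rigid misalignment and Gaussian intensity noise are drawn
from a seeded generator, and an unperturbed reference volume on true spacing
stands in for the reference scan.

Default study conditions: nominal spacing 0.2 mm; block diameter 35 mm
(the casting mold) at 0.02 mm/px; stent profiles tapering about threefold
in area toward the isthmus with `D1_frac < 0.5` (cartilage-side compression)
and a twist of order 20° over the stent, within the observed 6-32° range; a
stent-axis tilt of 8°; misalignment uniform in ±10 px and ±5°; noise
sigma 5 on the 0-255 intensity scale. Tests and the acceptance script run
the same model desk-scale (block 10-12 mm, 0.04-0.05 mm/px, 30-76 planes)
so a full pipeline completes in seconds to a couple of minutes on one CPU;
these sizes are stated here as the package's chosen problem sizes.

The intensity model is deliberately minimal — five flat gray levels plus
noise. It makes threshold segmentation nontrivial but does not model
histology texture, grinding scratches, partial-volume mixtures at
boundaries, or CT physics. Passing tests therefore demonstrate the
correctness of the geometry processing chain, not robustness to real
histologic appearance; on real data the segmentation threshold and polarity
are exposed (`segment_lumen(threshold=, polarity=)`) precisely because
automatic contrasting is the step most sensitive to appearance.

The tilt is realized as a linear in-plane drift (shear) of the lumen centre
rather than a full 3-D rotation of the lumen ellipse. A sheared cylinder's
axis-perpendicular section compresses the drift-direction diameter by
`cos(tilt)` — below 1% at the 8° default and at most 6% at 20° — which is
why the perpendicular-vs-grinding-plane contrast tests use an analytically
voxelized, truly tilted cylinder instead of the phantom.

## Algorithmic and numerical choices

**Fiducial detection** (`detect_fiducials()`). The block is separated from
the background by a threshold anchored a quarter of the way from the border
(background) intensity to the 99.9th percentile; the largest component is
kept and holes filled. Groove candidates are connected components of
(analytic disk minus observed disk), clipped 2 px below the rim and required
to cut at least 0.2 mm radially into it — thin crescents left by resampling
smoothing fail that depth test. The circle is then re-estimated on the
notch-filled disk (centroid and area radius are unbiased there), and each
groove is reported as its notch centroid projected radially onto the rim
circle: the projection cancels the radial bias of thresholding, leaving the
angular coordinate, which thousands of notch pixels determine to well below
a pixel. Identity (wide vs narrow) follows from notch area.

**Rigid registration** (`align_stack()`). Two identified points determine
the rotation from the inter-groove vector and the translation as the
least-squares residual over both points. The model is rotation +
translation only — documentation magnification is fixed, so scale is
constant. Each section is resampled once, bilinearly (nearest-neighbour for
label images), into the frame of the middle plane by default (smallest
maximum resampling path; configurable). On seeded phantoms the composed
(recovered after injected) transform deviates from the reference pose by
under 0.5 px and 0.5°.

**Spacing correction** (`estimate_plane_excess()`). Both volumes are
reduced to their axial lumen-area profiles (open area per plane), a
quantity invariant to in-plane pose, so no 3-D pre-registration is needed
beyond the area-weighted centroid alignment along z. The per-plane excess
delta is found by golden-section search (tolerance 1 µm) minimizing the sum
of squared differences between the stack profile laid out at
`nominal + delta` per plane and the linearly interpolated reference
profile. Raw endpoint extents are quantized at one plane spacing
(±0.28 mm here), too coarse for a ±5% band on an 84 µm effect; the profile
shape constrains the scaling far more tightly, which is why profile
superposition rather than endpoint matching is used. The correction is a
single uniform value; `apply_spacing_correction()` rejects corrections that
would make the spacing non-positive. Whether the excess is additive to the
nominal spacing or replaces it is exposed by keeping the two numbers
separate.

**Segmentation** (`segment_lumen()`). "Automatic contrasting" is
implemented as the k-class generalization of Otsu's threshold (1-D k-means
on the intensity distribution, deterministic quantile initialization;
`k = 2` is classic Otsu), thresholding midway between the two brightest
class centres. With the phantom's five levels a binary Otsu split lands
between background and epoxy, not at the lumen, hence the multi-level form;
`k`, polarity and a manual threshold are exposed. The largest 6-connected
3-D component is kept.

**Axis and cross-sections** (`fit_axis()`, `extract_cross_sections()`).
The axis is the first principal direction of the *per-plane lumen
centroids*, not of the voxel mask: the strong calibre variation along a
tapered stent would bias a mask PCA toward the wide end, while centroids
weight every plane equally. The direction sign is chosen so s increases
toward the pharynx (landmark hint); s = 0 sits at the middle-ear-facing
stent end. Sections are sampled at 0.2 mm steps (the fine grinding
increment) by interpolating a signed Euclidean distance field of the mask —
computed slice-wise in-plane and interpolated trilinearly across planes —
and thresholding at zero, which avoids the stair-casing of
nearest-neighbour lookups on oblique planes; slice-wise rather than full
3-D distances are exact in-plane and adequate through-plane for tilts up to
about 20°. Sections within `2 r sin(tilt)` of the axial ends can cross the
lumen's cut faces and are trimmed (`r` is the section's own in-plane
radius); on an untilted lumen nothing is trimmed and the section count is
`floor(L / step) + 1`.

**Chord morphometry** (`long_diameter()`, `short_diameter()`). `dL` is the
exact point-set diameter of the mask, computed on the convex hull; the
chord may cross background in concave lumens, consistent with ruler-style
measurement in a viewer. Because a single extremal pixel pair leaves the
chord *orientation* noisy on blunt-ended lumens (many near-diameter pairs
within half a pixel), the orientation of clearly elongated masks
(eigenvalue ratio at least 1.05) is refined from the second central
moments, which are exact for elliptical lumens including unequal D1/D2
halves. The chord line's across-chord position is de-biased with a
closed-form apex estimate from the extreme-strip extents (clamped to 1.5 px
around the maximal pair's midpoint so non-elliptical shapes cannot drag
it). D1 and D2 are ray-cast extents from the chord midpoint — distance to
the last foreground crossing, with sub-pixel interpolation of the boundary
— matching the geometry in which the two parts of the short diameter meet
the lumen boundary; if the midpoint falls outside a concave mask, rays are
cast from the nearest in-mask chord point and the row is flagged.

**Rotation tracking** (`rotation_profile()`). Orientations live on a 180°
circle; successive differences are wrapped into (-90°, 90°] and
accumulated from the first stent section. A step within 15° of 90°
*combined with* an exchange of the long and short diameters (each within
20% of the other's predecessor) is flagged as an axis swap — a
near-circular lumen handing the "longest" role to the other axis, not a
physical rotation — and a discrete 90° correction is applied in the
corrected series while the uncorrected series is kept alongside. A 90° step
without the diameter exchange is treated as real rotation.

**Landmark metrics** (`stent_span()`, `coverage_overlap()`,
`summarize_cohort()`). Positions are referenced to the isthmus (x = 0,
positive toward the pharynx). Signed distances follow the convention that
negative values mean the stent passes through the isthmus or protrudes
into the pharyngeal space, and the identity
`dist_isthmus + stent_length + dist_pharynx = cartilaginous_length` holds
exactly in that frame. The cross-stent comparison preset looks up the
profile row nearest 6 mm from the isthmus, a position covered by all
stents. All reported lengths and areas are rounded half-up to one decimal
place (`round_report()`); internal computation keeps full precision,
because the plane-spacing uncertainty makes further decimals meaningless.

## Degenerate inputs and tie-breaks

Empty masks, single-plane lumens, missing fiducials, non-positive corrected
spacings, and landmark files with the pharynx on the wrong side of the
isthmus all raise errors naming the offending plane or field. Ties in the
point-set diameter resolve toward the smaller orientation angle. The
orientation of a near-circular mask is arbitrary by nature; the swap logic
is what keeps the accumulated rotation meaningful through such sections.

## Known limitations

* The stent axis is modelled as a straight line; a curved centerline is out
  of scope, as is nonrigid registration and stitching of microscope tiles.
* The spacing correction is a single average value; per-plane depth
  estimation is deliberately not attempted.
* Landmarks are taken from an annotation file; there is no automatic
  anatomical landmark detection.
* The phantom validates geometry processing, not appearance robustness (see
  above); strut/metal segmentation is out of scope — the open lumen is the
  measured object.
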