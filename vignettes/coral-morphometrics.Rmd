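---
title: "Mesh-based coral morphometrics: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-based coral morphometrics: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralmesh)
```

`coralmesh` measures triangulated 3D models of coral colonies as produced by
structure-from-motion photogrammetry, and derives the difference and error
statistics used to compare underwater colony models with dry-imaged samples.
This vignette is the package's own account of the methods: the geometric
model, the measurement conventions, the synthetic validation bodies, and the
numerical choices made where more than one convention was defensible.

## The geometric model

A colony model is an indexed triangle mesh: an `n × 3` vertex matrix and an
`m × 3` matrix of vertex-index triples, optionally with per-vertex texture
coordinates. Polygonal faces in OBJ input are fan-triangulated on read.
Structural invariants are enforced at construction: indices in range, no
face referencing a vertex twice, finite coordinates.

**Surface area** is the sum of half cross-product magnitudes per face. It is
well defined for any triangle soup; degenerate (zero-area) slivers — routine
in photogrammetric exports — contribute nothing and are tallied in a
warning rather than treated as fatal.

**Enclosed volume** uses the divergence theorem: the absolute value of
`Σ det(v₁, v₂, v₃)/6` over faces. This is exact for watertight, consistently
wound surfaces and independent of the coordinate origin, which the test
suite checks to 1 part in 10⁹ under translation, rotation and the `s²`/`s³`
scaling laws. Two preconditions are enforced rather than assumed:

- *Watertightness.* A mesh with boundary edges has no enclosed volume. The
  package refuses (a typed `coralmesh_open_mesh` condition) instead of
  guessing; callers close break surfaces explicitly with the hole-repair
  step if that is scientifically appropriate. This mirrors field reality:
  some growth forms (thin tabular plates, foliose fronds) never yield
  coherent solid models, and their volume is reported as absent, not zero.
- *Orientation.* Face windings are made consistent by flood fill across
  shared edges, seeded per connected component from its largest face; a
  genuinely non-orientable surface is an error. The absolute value then
  removes the global sign.

**Boundary loops and hole repair.** Boundary edges (bordering exactly one
face) are chained into closed loops; an edge on three or more faces is a
structural error listing the offending edges. Each loop is closed by a fan
of triangles from the loop's vertex centroid. For the near-planar break
surfaces left by sampling a colony this is exactly the "flat" patch a mesh
editor produces; for non-planar loops it remains well defined, which is why
the centroid fan is used unconditionally rather than keeping a separate
ear-clipping path for pathological loops. Repair is idempotent, never
touches existing faces, and reports the added face indices so they can be
labelled as non-living contact surface — an artificial patch is not coral
tissue. Whether total surface area should include such patches is a
convention, not a fact; here TSA includes them and ESA excludes them, and
both are always computable so either convention can be recovered.

**Segmentation.** Faces carry one of three labels — `living`,
`nonliving_contact`, `background` — and every measurement can be restricted
to a label set. Total surface area (TSA) uses the colony classes (living +
non-living contact); effective surface area (ESA) uses `living` only.
Submesh extraction drops unreferenced vertices and compacts indices; an
empty selection is an error, distinct from a zero-area warning.

## Calibration and alignment

Photogrammetric models come out in arbitrary model units. The scale factor
to centimetres is fitted from landmark pairs digitised on an imaged
reference object (a folding ruler or colour-checker card of known
dimensions): the factor is the *mean of per-pair ratios*
`known length / model distance`. A total-least-squares fit was considered
and rejected: with the 1–15 roughly equal-length landmark pairs typical of
field protocols the mean ratio is equivalent in precision, simpler to
reason about, and pairs with gross landmarking errors are surfaced by the
accompanying coefficient of variation rather than silently down-weighted.
A CV above 5 % (default) warns; it is a data-quality flag, not an error.

Sampled and unsampled models of one colony are reconstructed independently
and land in different poses, so segmentation transfer needs rigid
alignment. The package uses point-to-point iterative closest point with a
closed-form orthogonal-Procrustes (SVD) update per iteration, on
*deterministic stride subsamples* of the vertex sets (default ≤ 1500 moving
and ≤ 6000 fixed points) — determinism in the core path was preferred over
random subsampling so reruns are byte-identical without seed plumbing. When
no initial transform is given, centroids are aligned and a principal-axes
rotation is chosen among the four sign-resolved eigenvector combinations by
lowest starting RMS. This initialisation is intended for the near-aligned
pairs of a single colony; ICP is a local method and arbitrary pose recovery
is out of scope. Iteration stops when the RMS residual improves by less
than `tol` (default 10⁻⁷ cm) or at `max_iter` (50); hitting the cap above a
configurable RMS ceiling flags the result as unconverged instead of
raising.

## The derived-metric suite

All derived quantities are simple arithmetic on the raw per-colony
measurements, but the sign and denominator conventions matter and were
fixed once, verified numerically against the ten-colony reference table
shipped with the package:

| Quantity | Definition | Convention notes |
|---|---|---|
| ThSA | `unsampled_sa − esa_sampled` | signed; negative values are retained as reconstruction-error diagnostics |
| ThV | `unsampled_v − tv_sampled` | signed |
| Biosurface | `tsa_tissue − tsa_skeleton` | signed (mucus can inflate the skeleton model) |
| Biomass | `tv_tissue − tv_skeleton` | signed |
| % Scale (SA) | `100 · esa_tissue / unsampled_sa` | denominator is the underwater unsampled quantity |
| % Scale (V) | `100 · tv_tissue / unsampled_v` | absent when no closed underwater model exists |
| Theoretical Error (SA) | `100 · abs(ThSA − esa_tissue) / esa_tissue` | reference (denominator) is the dry tissue measurement |
| Theoretical Error (V) | `100 · abs(ThV − tv_tissue) / tv_tissue` | as above |
| Error TVW | `100 · abs(tv_skeleton − tv_water) / tv_water` | denominator is the water-displacement volume |

Absent raw values propagate as absent (`NA`), never as zero: a colony whose
underwater model never closed has no ThV, no % Scale V and no volume
theoretical error, and the serialized table shows empty cells. All
arithmetic is done at full precision; rounding to two decimals happens only
at serialization. The reference table is reproduced cell by cell within
`max(0.02, 0.1 %)` — the slack absorbs the two-decimal rounding of
intermediates in the printed source values (e.g. a printed biomass of 3.39
against 3.40 recomputed from the printed, already-rounded inputs); the
package does not "correct" printed values.

## Synthetic colonies and what they do (and do not) show

The generators build colony scenes with analytic ground truth, one per
growth form, each above a `background` seafloor plane with the basal
contact labelled `nonliving_contact`:

- **massive** — hemisphere (radius `size_cm`) on a base disc; SA `3πr²`,
  volume `⅔πr³`;
- **branched** — a tapered trunk frustum plus five tapered branch frusta
  with seeded placement jitter. The assembly is deliberately overlap-free
  (branches are disjoint closed solids), so closed-form sums of frustum
  areas and volumes are exact; realism is secondary to an exact oracle;
- **tabular** — a thin plate box over a stalk box, again disjoint and
  exactly summable;
- **foliose** — an open hemispherical shell with no base: intentionally
  non-watertight, to exercise the volume-refusal and hole-repair paths.

Default study conditions: `size_cm = 5` (a decimetre-class colony),
`resolution = 3` (64 azimuthal segments, giving discretized areas within
about 0.2 % of the closed forms), `sample_patch_fraction = 0.05` (the small
hammer-and-chisel sample of a field campaign), `tissue_thickness_cm = 0.1`
(a millimetre-scale tissue layer). Tests use these values; the parameters
exist so users can explore, not so the defaults can drift.

**Sampling** grows a connected patch of living faces breadth-first from the
topmost living face until the requested area fraction is reached, detaches
it, and closes the matching break surfaces on colony and fragment with the
same flat patch — so the living area splits exactly and the two closed
volumes sum exactly to the original, which the tests verify. **Bleaching**
erodes every living-surface vertex inward along its area-weighted,
living-faces-only vertex normal by the tissue thickness; vertices on
contact surfaces stay put. On the hemisphere this recovers the analytic
shell volume `⅔π(r³ − (r−t)³)` within the discretization error of the
normal field (tested at 5 %); thickness 0 is the exact identity, and
thicknesses beyond a quarter of the smallest bounding-box extent are
clamped with a warning since such offsets would fold the surface through
itself.

In the synthetic end-to-end study the "unsampled" surface area is taken as
the living (effective) area of the segmented colony, and the unsampled
volume as its closed-model volume — i.e. segmentation is assumed perfect.
That is the point of the exercise: with segmentation and scale error
removed, ThSA and ThV must recover the detached patch area and fragment
volume almost exactly, isolating the measurement chain itself. What passing
these tests does *not* show: robustness to reconstruction noise, occlusion
artefacts, texture-dependent point-density variation, segmentation
disagreement between observers, or scale error from refraction — real
photogrammetric data carry all of these, and the reference-table error
statistics (theoretical errors of tens to thousands of percent) show how
large they can be in practice.

An independent brute-force oracle guards the volume implementation: column
(pencil) integration on an xy grid, pairing sorted z-crossings per column.
It shares no code with the divergence-theorem path and agrees within
`3·h·SA` for grid spacing `h` on every closed synthetic form.

## Frame selection

Reconstruction services cap the number of input images (70 per model for
the service targeted here), while a one-minute video yields thousands of
frames. Frames are scored by the variance of a 5-point Laplacian of the
grayscale image — the standard focus measure; the acquisition protocol's
"well-defined" criterion is subjective, and variance-of-Laplacian is
declared as this package's operationalisation of it, not claimed as the
original authors'. Selection is greedy: frames in decreasing sharpness,
ties broken toward lower frame ordinals, accepted while at least
`min_spacing` ordinals from every accepted frame and under the cap. The
greedy pass is deterministic and enforces the constraints exactly; it does
not guarantee a maximum-cardinality selection for adversarial sharpness
profiles, which is acceptable for its role of thinning near-duplicate video
frames. JPEG decoding is not built in (frames are expected as PNG/TIFF
extracted by the video tooling); EXIF metadata, lost when extracting stills
from video, is likewise not synthesised — its absence is a known accuracy
cost of video-based acquisition.

## Numerical choices and degenerate inputs

- OBJ indices are 1-based on disk and 1-based internally (the natural R
  convention); negative (relative) OBJ indices are resolved; material and
  normal records are ignored without error. Face-label CSVs use 0-based
  face indices on disk, matching the external mesh tools that produce
  them, and are converted on read.
- Mesh writing uses fixed `%.8f` formatting and deterministic record
  ordering, so identical meshes serialize byte-identically — reruns of any
  command on identical inputs are byte-identical, and provenance headers
  deliberately contain no timestamps.
- Equality tolerances in the invariance tests are relative 10⁻⁹; geometric
  recovery tolerances (0.5 % for discretized closed forms, 2 % for patch
  recovery, 5 % for shell recovery) reflect discretization, not
  implementation slack.
- Degenerate faces: zero area, warned, never fatal. Empty label
  selections: error. Zero-distance landmark pairs: error. Non-watertight
  volume: typed refusal. Unreadable frames: skipped with a warning and
  recorded in the manifest.

## Known limitations

Reconstruction itself (structure from motion), texture handling, colour
calibration and non-rigid registration are out of scope. The ICP is
point-to-point and local; models must be roughly pre-aligned, which
reconstruction pipelines provide. The hole filler produces flat patches
only — correct for break surfaces, wrong for large organic holes. The
synthetic growth forms are geometric idealisations; they validate the
measurement chain, not the photogrammetry. Encrusting/crustose morphology
has no dedicated generator (its measurement path is the same as the
massive form's). Water-displacement volume is a physical input and is only
ever consumed, never computed.
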