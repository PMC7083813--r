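---
title: "Mapping cortical lesions onto an unfolded mouse cortex template"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cortical lesions onto an unfolded mouse cortex template}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionmap)
```

## The problem

Experimental traumatic brain injury in mice (for example the lateral
fluid-percussion model) produces cortical lesions whose location on the
cortical mantle predicts the behavioural outcome.  To compare lesions
across animals and time points, the curved cortical sheet is *unfolded*:
each coronal section's cortical surface becomes a horizontal line, the
lines are stacked along the anteroposterior (AP) axis, and the boundaries
of the cytoarchitectonic regions (S1, S1BF, M1, ...) are drawn on the
resulting flat map.  A lesion measured slice by slice can then be placed
on this map and intersected with each region to quantify damage in mm²
and as a percentage of each region.

Doing this by hand (transferring distances into a drawing program,
outlining, measuring) is slow and operator-dependent.  `lesionmap`
automates it: the same measurements always produce the same map.

## Input measurements

For every coronal histological section or MRI slice the researcher
records four numbers, in millimetres, along the cortical surface:

* **MB** — the slice's bregma-relative AP coordinate (anterior positive);
* **M1** — medial reference point (midline/corpus-callosum intersection)
  to the medial lesion edge;
* **M2** — medial lesion edge to lateral lesion edge;
* **M3** — lateral lesion edge to the rhinal fissure.

When the lesion extends *lateral* to the rhinal fissure, the convention
changes: M2 is measured from the medial lesion edge to the fissure, and
M3 from the fissure to the lateral lesion edge **with a negative sign**.
Measurement files are CSV or Excel with the columns in the order MB, M1,
M2, M3 (an optional header row is auto-detected).  Lesion edges are
conventionally read in cortical layer V.

For MRI data the recorded slice coordinate refers to a slab of thickness
equal to the AP voxel size, so the coordinates are shifted by half a
voxel (`apply_mri_shift()`).  The anatomical direction of this shift is
not fixed by the measurement convention itself; the package defaults to
anterior (`+slice_depth/2`) and exposes the sign as an argument, because
either choice is defensible depending on how slice positions were read
off the scanner.  The shift is recorded in the set's metadata and a
second application is refused.

## The template

The unfolded map template is a plain SVG file plus a JSON table of atlas
reference lengths:

* each region is a unique **closed** path labelled `A_<id>` (label = SVG
  `id`, falling back to `inkscape:label`; "labelled" is otherwise
  ambiguous in plain SVG);
* `ap_zero` (the bregma ordinate) and `units_per_mm` (the template-unit
  per millimetre constant *r*) are attributes of the root `svg` element,
  or alternatively rectangles with those labels (y-position and width
  respectively).  When both forms are present the **attribute wins**;
* the rhinal fissure is a path labelled `rhinal_fissure`;
* anything else (labels, axis lines) is kept for rendering but ignored
  by every computation.

The JSON is an array of plates
`{"ap": <mm>, "medial_to_rhinal": <mm>, "medial_to_lateral": <mm>}`,
strictly monotone in `ap`.  The published table's exact layout is not
standardised; `read_atlas_lengths()` accepts a `loader` hook mapping any
other layout onto these three columns.

Cubic Bezier path segments are flattened by de Casteljau midpoint
subdivision before any geometry is computed.  The flatness criterion is
the maximum distance of the two inner control points from the chord; the
default tolerance of 0.01 template units is well below 0.01 mm at the
usual *r* = 10, matching the AP placement precision the mapping itself
guarantees.  SVG transforms are composed down the ancestor chain and
applied to control points *before* flattening, so the tolerance is
honoured in final template coordinates.

Axis conventions, used consistently everywhere: x increases medially to
laterally, y increases posteriorly (screen-style, anterior at the top),
so a slice at coordinate MB sits at `y = ap_zero − r·MB`.

### The synthetic template

`generate_synthetic_template()` emits a fully self-consistent template:
a grid of rectangular regions spanning the published template extent
(+3.20 to −4.96 mm AP, 40 coronal plates) with a straight vertical
rhinal fissure and constant atlas lengths, plus the matching JSON, and a
bookkeeping table of exact region areas.  It exists so that every test
and example can run without the published atlas-derived template, and it
round-trips bit-exactly through `parse_template()`.

What it deliberately does **not** emulate: curved region boundaries,
AP-varying surface lengths, plates with missing corpus callosum, or any
real cytoarchitectonic layout.  Tests passing on it therefore validate
the *mapping machinery* (normalization, placement, clipping,
bookkeeping), not the anatomical fidelity of any particular template —
that fidelity lives in the template file a user supplies.

## The mapping algorithm

Mapping runs in four steps.

**1. Normalization** (per slice).  The measured inter-reference distance
is

$$D = \begin{cases} M_1 + M_2 + M_3 & M_3 \ge 0\\
M_1 + M_2 & M_3 < 0 \end{cases}$$

(when the lesion crosses the fissure, M1 + M2 already spans medial
reference → fissure).  With $L(\mathrm{MB})$ the atlas medial-to-rhinal
surface length at the slice's AP level, the scale ratio is $\rho = L/D$,
and the adjusted distances are $M_2' = \rho M_2$, $M_3' = \rho M_3$.
This removes brain-size differences and histological shrinkage: scaling
all of one slice's measurements by any $k > 0$ leaves the mapped contour
unchanged.  M1 is not carried further — the fissure-anchored placement
below only needs $M_2'$ and $M_3'$.  Ratios outside $[0.25, 4]$ trigger
a warning as biologically implausible.  $L$ is taken from the plate
whose `ap` is **nearest** to MB, ties resolving to the anterior plate;
this mirrors the manual practice of assigning a section to its closest
atlas plate (plates are ~0.2 mm apart, so interpolating between plates
would change lengths by less than typical measurement error).

**2. Translation.**  For each slice, $y = \mathrm{ap\_zero} - r\,
\mathrm{MB}$; the lateral lesion edge is anchored at the rhinal fissure:
$x_{lat} = x_{rh}(y) - r M_3'$ (beyond the fissure when $M_3 < 0$), and
the medial edge at $x_{med} = x_{rh}(y) - r\,(M_2' + \max(M_3', 0))$.
A medial edge that would fall medial to the cortex boundary is clipped
to it with a warning.  This *fissure-anchored* placement is the only
reading consistent with using the rhinal fissure as the lateral
reference point and with M1 being dropped during normalization; an
alternative midline-anchored placement ($x_{med}$ at $r M_1$ from the
medial cortex border) is available via `translate_slices(anchor =
"midline")` for comparison, but is not the default.

**3. Interpolation.**  The medial and lateral edge polylines (one vertex
per slice, ascending MB) are densified either linearly (vertices kept
as-is) or with an alpha-parameterised Catmull-Rom spline, and closed
into a single polygon: medial edge in ascending MB order, then the
lateral edge descending — an anticlockwise contour (positive signed area
under the y-down axes).  Design choices, where the underlying
convention is genuinely open:

* the two edges are splined **separately** and then joined, rather than
  splining the closed contour through the corners; this keeps the
  first/last slices as hard corners of the lesion, which is what the
  measurements actually assert;
* spline ends are clamped by duplicating the terminal control points;
* `alpha = 0.5` (centripetal) is the default — it is the standard choice
  that cannot produce cusps or local self-intersections within a
  segment; `alpha` and the per-gap point count `n_insert` are exposed;
* if spline overshoot still makes the closed polygon self-intersect, the
  offending edge(s) fall back to linear densification with a warning.

`n_insert = 0` makes the spline identical to the linear contour, and the
spline converges to the linear contour as slice spacing shrinks; both
properties are asserted in the tests.

**4. Quantification.**  The contour is intersected with every region
polygon (Boolean polygon intersection); for region $R$ the damage is
$A_R = |C \cap R| / r^2$ mm² and $100\,A_R/|R|$ percent.  The total
cortical damage percentage uses the sum of all region areas as the
denominator.  Because the regions partition the template, the summed
per-region intersection areas equal the lesion-within-cortex area; the
tests enforce this conservation to 1e-6 relative over random lesions.

Boolean operations are delegated to the Clipper library (R package
`polyclip`), which snaps coordinates to an integer micro-grid
internally; that snapping bounds the achievable agreement of areas at
roughly 1e-9 relative, far below measurement precision.
Self-intersecting input polygons are interpreted under the even-odd fill
rule with a warning.  Degenerate inputs quantify to zero: a single-slice
set produces a flagged degenerate contour and a warning rather than an
error, since batch runs should not abort on a sparse animal.

## Time series

Measurement sets from several days (unique positive day numbers) are
mapped independently against the same template and collected with
`lesion_series()`; `series_table()` emits the long-format per-day table
behind the chart and CSV exports.  For visualising the transition
between two days the contours must have equal vertex counts:
`align_contours()` inserts *dummy points* on the contour with fewer
vertices — evenly spaced in arc length along each edge, medial edge
matched with medial and lateral with lateral — and flags them so they
can be removed afterwards (`drop_dummy_points()`).  Because dummies are
inserted *on* existing edges they are collinear and the polygon's area
is unchanged.  The even-by-arc-length placement is this package's own
rule; the original behaviour behind the idea is unspecified, and any
placement that preserves originals and monotone ordering would be
equally defensible.  `interpolate_transition()` is then a vertex-wise
convex combination, exact at both endpoints.  Video encoding is out of
scope; `render_series_frames()` writes a numbered PNG frame sequence
instead.

## Export

`results_csv()` writes `day,region,area_mm2,percent` rows plus a `TOTAL`
row per day (area plus percentage of the whole cortex), RFC-4180, LF
endings, two decimals (full precision is retained in the R objects).
`render_map()` draws *every* template SVG object — including decorative
ones — plus the lesion overlays (colours, solid/dashed/dotted border,
fill opacity, dpi all settable via `contour_style()`), and writes an
uncompressed RGB TIFF, a vector PDF of the same scene, and a ZIP bundle
of the two.  Raster pixel dimensions follow from the template's physical
size (template units divided by *r*) times the dpi.

## Command line

`run_cli()` (wrapped by the `inst/cli/lesionmap` Rscript) processes a
single file or a whole folder, with custom templates
(`--template`/`--atlas-lengths`), MRI mode (`--mode mri --slice-depth`),
interpolation and style flags, and writes one output subfolder per input
containing `results.csv`, `map.tiff`, `map.pdf` and `bundle.zip`.  In
batch mode, files named `<stem>_day<k>.<ext>` are grouped into a time
series per stem, producing `series.csv`, a chart and transition frames.
Exit codes: 0 success, 1 processing error (in batch mode, readable files
are still processed and failures are summarised), 2 usage error.

## Numerical choices and problem sizes

* Bezier flatness tolerance: 0.01 template units; recursion capped at
  depth 32.
* Clipper vertex snapping: `polyclip` defaults (relative resolution
  ~1e-9); area conservation asserted at 1e-6 relative.
* Nearest-plate AP lookup; ties anterior; querying outside the plate
  range ± half a plate spacing is a hard error.
* Duplicate MB values within one measurement set are rejected at import
  (the contour construction needs one edge pair per AP level).
* The test suite and the acceptance script exercise the pipeline on the
  synthetic template at its published extent (16 regions, 40 plates)
  with elliptical ground-truth lesions (AP half-width 1.8 mm,
  mediolateral half-width 1.2 mm, centred 2 mm medial of the fissure at
  MB −1) sampled every 0.2 mm — 18 slices, the typical section count of
  a histological series — with a smooth per-slice shrinkage field that
  normalization must undo.  Geometry oracles use Monte-Carlo rejection
  sampling and fine-grid rasterization at sizes that keep the whole
  suite around half a minute.

## Known limitations

* Elliptical SVG arc segments (`A`/`a`) are not parsed; templates using
  arcs must be exported with arcs converted to cubics.
* Legacy binary `.xls` files are read through the same reader as
  `.xlsx`, but only `.xlsx` fixtures are generated in the tests.
* The mapping faithfully reproduces *measured* edges; it cannot correct
  mis-identified lesion boundaries, and per-slice normalization assumes
  shrinkage is uniform along the surface within a slice.
* A single-slice set has no AP extent and quantifies to zero by design.
* Lesions extending beyond the template's AP span are a hard error, not
  a clipped warning: measurements outside the atlas range have no
  reference length.
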