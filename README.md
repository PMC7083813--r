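# lesionmap

Quantification of cortical lesions on a 2D unfolded template of the
mouse cerebral cortex.

In mouse models of traumatic brain injury (e.g. lateral fluid-percussion
injury), the location of the cortical lesion on the cortical mantle
predicts behavioural outcome. The standard way to compare lesions across
animals and time points is the *unfolded map*: every coronal section's
cortical surface becomes a horizontal line, the lines are stacked along
the anteroposterior (AP) axis, and cytoarchitectonic region boundaries
are drawn on the resulting flat sheet. `lesionmap` takes the slice-wise
measurements a researcher records from histological sections or MRI
(bregma-relative AP coordinate **MB** and the along-surface distances
**M1**, **M2**, **M3**; M3 negative when the lesion extends lateral to
the rhinal fissure), places the lesion on the template, and reports the
damaged area per region in mm² and percent. It is aimed at experimental
TBI / lesion-mapping labs and at pipeline use (batch CLI).

## The algorithm

Mapping runs in four steps, per measurement set:

1. **Normalization** — per slice, the measured medial-reference-to-fissure
   distance `D = M1 + M2 + M3` (or `M1 + M2` when `M3 < 0`) is compared
   with the atlas surface length `L(MB)` of the nearest coronal plate;
   `M2` and `M3` are scaled by `ρ = L / D`, removing brain-size and
   shrinkage differences.
2. **Translation** — with the template constant `r` (units per mm), each
   slice maps to ordinate `y = ap_zero − r·MB`; the lateral lesion edge
   anchors at the rhinal fissure, `x_lat = x_rh(y) − r·M3′`, and the
   medial edge at `x_rh(y) − r·(M2′ + max(M3′, 0))`.
3. **Interpolation** — the medial and lateral edge polylines are
   densified (linear, or centripetal Catmull-Rom spline with chosen
   `alpha` and per-gap resolution) and closed into one anticlockwise
   lesion polygon.
4. **Quantification** — Boolean polygon intersection of the contour with
   every region: `area(C ∩ R)/r²` mm² and `100·area(C ∩ R)/area(R)`
   percent, plus cortex-wide totals.

Templates are plain SVG (regions as closed `A_`-prefixed paths, Beziers
flattened by de Casteljau subdivision, `ap_zero`/`units_per_mm` as root
attributes or labelled rectangles — attributes take precedence — and a
`rhinal_fissure` path) plus a JSON array of atlas plate lengths. A
synthetic template generator ships with the package, so nothing needs to
be downloaded to use or test it. Multi-day measurement sets produce
per-day tables and smooth contour transitions for lesion-evolution
animation. See `vignettes/lesion-mapping.Rmd` for the full model
description and design decisions.

## Worked example

```r
library(lesionmap)

## build a template (synthetic here; supply your own SVG + JSON instead)
syn <- generate_synthetic_template()
template <- parse_template(syn$svg, syn$atlas_json)
template
#> Unfolded cortex template
#>   regions: 16 (total cortex area 66.59 mm^2)
#>   units per mm: 10; ap_zero (bregma ordinate): 42
#>   atlas plates: 40, AP +3.20 to -4.96 mm

## measurements: 18 slices of an elliptical test lesion, 0.2 mm apart
truth <- synthetic_lesion_truth(syn)
ms <- synthetic_lesion_measurements(truth, spacing = 0.2)
head(ms$slices, 3)
#>     mb       m1        m2       m3
#> 1 -2.7 5.765595 0.7888106 1.605595
#> 2 -2.5 5.496675 1.3266499 1.336675
#> 3 -2.3 5.330007 1.6599866 1.170007

## map and quantify
contour <- map_lesion(ms, template, method = "spline", n_insert = 10)
result <- quantify(contour, template)
result
#> Lesion quantification (day 1)
#>  region area_mm2 percent
#>     R07     1.46   35.12
#>     R08     1.59   38.15
#>     R11     1.74   41.80
#>     R12     1.89   45.30
#> TOTAL: 6.67 mm^2 = 10.02% of the cortex (66.59 mm^2)
```

The per-region rows say how many mm² of each region the lesion covers
and what fraction of that region is damaged; the `TOTAL` row reports the
whole lesion area and its share of the entire cortex. The mapped total
(6.67 mm²) recovers the analytic area of the painted test lesion
(π·1.8·1.2 ≈ 6.79 mm²) from 18 discrete slices. Export with
`results_csv(result, "results.csv")` and `render_map(template,
list(contour), contour_style(), out_dir = "out")`.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/lesionmap --input case01.csv --out-dir out        # single file
Rscript inst/cli/lesionmap --input-dir measurements/ --out-dir out # batch
```

with `--template`/`--atlas-lengths` for custom templates, `--mode mri
--slice-depth 0.2` for MRI data (half-voxel AP shift), and
interpolation/style flags (`--interp spline --alpha 0.5 --resolution
10`, `--fill-color`, `--dpi`, ...). Files named `<stem>_day<k>.csv` in a
batch folder are combined into a time series with a per-day table,
chart, and PNG transition frames.

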