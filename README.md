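# isletscope

Quality control of pancreatic-islet segmentation by a panel of experts.

Isolated islet grafts are dosed in **islet equivalents (IE)** — the volume of
a sphere 150 µm in diameter. An islet's IE volume is derived from its 2-D
micrograph area *A* (in µm²) via the spherical model:

```
d = 2 * sqrt(A / pi)          equivalent-circle diameter (µm)
V = (d / 150)^3               volume in IE
```

with islets conventionally sorted into 50 µm diameter bins (50–100,
100–150, …). Automated segmentation of dithizone-stained micrographs needs
consensus ground-truth contours, and building that consensus requires
collecting, scoring and aggregating expert opinions on drawn contours.
`isletscope` implements the computational side of that workflow for
islet-isolation labs and image-analysis groups:

- **Mask handling** — class-coded grayscale masks (islet / exocrine /
  background), per-image pixel-size tables, connected-component islet
  labeling (4/8-connectivity).
- **Contours** — inner-boundary extraction, colored overlays, arrow-marked
  review images, per-islet crops.
- **Morphometry** — equivalent diameters, 50 µm size categories, IE volumes
  (continuous spherical model, plus the classical stepwise per-category
  factors as an alternative mode).
- **Selection engine** — seeded random image draws and size-stratified
  random islet draws above an adjustable threshold (validation scenario),
  or manual picks (inquiry scenario), with per-set numbering and
  bit-reproducible manifests.
- **Agreement metrics** — polyline rasterization, trimming to the
  ground-truth islet, symmetric average line distance with the < 2 px
  accuracy rule, contour-derived volumes, relative error
  `RE = |V_expert − V_template| / V_template`, and replicate coefficient of
  variation (triplicates with a zero volume are excluded).
- **Opinions** — image quality classes (good / borderline / unacceptable),
  islet verdicts (true / false / skip) with graphical edits (separation
  lines, redraws, non-islet calls, …), validation, tallies and anonymized
  consensus reports.
- **SUS** — System Usability Scale scoring with the Sauro–Lewis curved
  grading scale (A+ … F).
- **Synthetic scenes** — blob islets of known diameter with matching masks,
  simulated expert tracings with controlled perpendicular jitter, and
  simulated opinion sets, so the whole pipeline is testable without
  microscopy data.

## Worked example

```r
library(isletscope)

dir <- file.path(tempdir(), "demo")
make_fixture_bundle(dir, n_images = 19, seed = 11,
                    height_px = 300, width_px = 300)

man <- build_validation_set(dir, n_images = 8, threshold_um = 50,
                            quota_per_image = 7, seed = 12,
                            out_dir = file.path(dir, "set"))
man
#> <selection_manifest> 'validation' (VALIDATION): 8 image(s), 47 marked islet(s)
head(man$entries, 4)
#>   image set_image_no islet_label set_islet_no centroid_row centroid_col size_category
#> 1 img02            1           6            1     205.5495     59.72410            50
#> 2 img02            1           8            2     258.8336    137.65065           100
#> 3 img02            1           5            3     188.1462    181.27172           150
#> 4 img02            1           1            4      89.8555     64.22942           200
```

Eight of the 19 bundle images were drawn; within each image, islets at or
above the 50 µm threshold were drawn round-robin across the occupied 50 µm
size categories (note the first four marked islets span categories
50–200), up to 7 per image. `out_dir` receives `manifest.csv` and
arrow-marked PNGs. Simulated experts then review the set:

```r
profiles <- lapply(1:8, function(k)
  expert_profile(sprintf("expert%d", k), jitter_sigma_px = 0.5 + 0.25 * k,
                 p_false_call = 0.3))
ops <- simulate_opinions(man, profiles, dir, seed = 13)
tal <- tally_islet_opinions(Filter(\(o) inherits(o, "islet_opinion"), ops))
tal$totals
#> $n_graphical_opinions       123
#> $n_disputed_islets           46
#> $n_identity_disputed_islets   0
summ <- consensus_report(man, ops, dir, file.path(dir, "report"))
#> 46 anonymized crops + consensus.csv written
```

Each of the 8 experts judged every marked islet; with a 0.3 dispute
probability, 123 of the 376 verdicts carried a graphical redraw, touching
46 islets — each gets a cropped image with the ground-truth boundary in
blue and the (anonymized `e1`…`e8`) expert redraws in white. Usability
scoring of a cohort CSV:

```r
sus <- sus_cohort_summary(read_sus_responses(
  system.file("extdata", "sus_scores.csv", package = "isletscope")))
sus$mean_score; sus$overall_mark
#> 86.1
#> "A+"
```

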