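---
title: "Models and methods behind isletscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind isletscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletscope)
```

`isletscope` quantifies pancreatic islets on segmentation masks and scores
how well a panel of experts agrees on islet contours. This vignette is the
package's own account of the models it implements, the parameters that
matter, and the design choices made where more than one reasonable option
existed.

## The spherical volume model

Islet grafts are dosed in islet equivalents (IE): one IE is the volume of a
sphere 150 µm in diameter. From a 2-D mask, an islet of pixel area
$A_{px}$ at pixel size $s$ (µm/px) gets

$$A = A_{px}\,s^2, \qquad d = 2\sqrt{A/\pi}, \qquad V = (d/150)^3 \;\mathrm{IE}.$$

The equivalent-circle diameter is used as the size proxy because the
upstream measurement is an area; `size_category()` bins $d$ into the
conventional 50 µm-wide half-open bins, closed at the lower edge, so a
50.0 µm islet belongs to category 50 and a 400 µm islet is representable
(`[400, 450)`). The continuous cube-law volume is the default because it
makes volume comparisons between two drawn contours well-defined at any
diameter; the classical stepwise per-category factor table
(`islet_volume_ie(d, "ricordi")`) is kept as an alternative mode for
emulating manual counts, where every islet in a bin contributes that bin's
fixed factor. Size thresholding is a *selection* rule only: islets below
the threshold are never excluded from morphometry summaries, only from
marking for review.

## Masks, labeling and boundaries

Masks are single-channel 8-bit PNGs with a three-level encoding (default
0 = background, 128 = exocrine, 255 = islet — an artifact convention, since
only the class semantics are fixed by the data; any level mapping can be
passed). A gray level not covered by the encoding is a hard error: stray
levels almost always mean an anti-aliased or re-saved mask whose areas
would be silently wrong.

Islets are individuated as connected components of islet-class pixels,
8-connectivity by default (diagonally touching blob fragments are one
object; 4-connectivity is available). The labeler is a run-based union-find
pass, checked in the test suite against an independent stack-based flood
fill on random masks.

A component's boundary is its *inner* boundary: pixels of the object with
at least one 4-neighbor (or the image edge) outside the component. This
yields the closed 1-px edge drawn on the object that contour overlays
display; whether an outer boundary would match the original displays
cannot be determined, and the inner convention keeps every boundary pixel
a pixel of the islet itself.

All coordinates in the package are 1-based `(row, col)` with the origin at
the top-left and rows increasing downward — R's native matrix indexing.
Using the host language's convention end to end avoids an off-by-one
adjustment at every matrix access and keeps user code idiomatic.

## The selection engine

A review set is reproducible from a bundle (`images/`, `masks/`,
`pixel_sizes.csv`) and a single integer seed: one generator drives the
image draw, then the per-image islet draws in image order. Image selection
is uniform without replacement. Islet selection is *stratified by size
category*: among islets at or above the size threshold (default 50 µm),
one islet is drawn uniformly from each occupied 50 µm category in
ascending order, round-robin, until the per-image quota (default 7) is
filled. Round-robin is the simplest rule with the property that whenever
the quota is at least the number of occupied categories, every occupied
category is represented — the point of stratifying, since islet isolates
are heavily skewed toward small islets and an unstratified draw would
rarely show a reviewer a large one. The quota is per image, matching
engines that mark a handful of islets on each selected image.

## Scoring expert drawings

**Rasterization.** Polylines become 8-connected 1-px Bresenham chains;
closed contours also connect last to first vertex.

**Trimming.** Separation lines are only meaningful inside the islet mass
they split, so both the expert's and the template line are trimmed to the
pixels belonging to the ground-truth component before comparison. Closed
contours are not trimmed; they are compared through their enclosed
volumes.

**Average line distance.** The accuracy measure is the symmetric mean
nearest-neighbor distance: the mean Euclidean distance from each pixel of
one line to the nearest pixel of the other, averaged over both directions.
"Corresponding points" between two free-hand lines have no canonical
definition; the symmetric form is zero exactly on identical lines, has no
direction bias, and is checked in the tests against a brute-force
all-pairs oracle. The one-directional variant is available
(`directed = TRUE`). A drawing is judged `GOOD` when the average distance
is strictly below 2 px — the boundary value 2.0 itself is `POOR`. An
expert line whose trim is empty (drawn entirely off the islet) scores an
infinite distance, is flagged, and is `POOR`.

**Template length** is reported as the trimmed pixel count (not arc
length): it is the denominator actually entering the mean and needs no
sub-pixel convention.

**Contour volumes.** A closed contour is converted to a filled binary mask
(pixel centers inside the polygon, even-odd rule) and the pixel count goes
through the spherical model — the same path a mask-based analysis takes —
rather than the shoelace formula, which the tests use as an independent
cross-check (the two agree to rasterization error, about 1% for a
radius-75 px disc and below 1% beyond radius 150 px). Self-intersecting
contours are not rejected; the even-odd rule is applied as-is, which is
the conservative choice when an expert's stroke loops on itself.
Agreement between an expert and a template volume is summarized by the
relative error $RE = |V_e - V_t|/V_t$ and the normalized volume $V_e/V_t$.

**Repeatability.** An expert's consistency over repeated tracings of one
islet is the coefficient of variation of the replicate volumes, using the
sample ($n-1$) standard deviation since triplicates are a small sample (a
population-SD mode exists for exact comparability with tools that use
$n$). A replicate set containing a zero volume is excluded from the CV —
a ratio to a mean dragged toward zero by a failed tracing does not measure
repeatability — and flagged instead.

## Opinion aggregation

A *graphical opinion* is an islet opinion whose edit list is nonempty; a
`NOT_AN_ISLET` call counts as graphical even though it carries no
geometry, because it is a drawing-screen act that disputes the annotation.
Edits carry their geometric contract in the type: separation lines are
open, full redraws and missing contours are closed. Validation enforces
reference integrity against the manifest, one submission per (expert,
target), and the verdict/edit consistency rules (`FALSE_CONTOUR` iff edits
present). Consensus reports anonymize experts through a stable bijection
(`e1`…`eN`, sorted by id) so no identity leaves the report, overlay the
ground-truth boundary in blue and expert edits in white (both
configurable), and emit crops only for islets that actually received
edits.

## SUS scoring

The 10-item System Usability Scale is scored the standard way: odd
(positively-toned) items contribute $item - 1$, even (negatively-toned)
items $5 - item$, and the sum is scaled by 2.5 onto 0–100. Marks come from
the Sauro–Lewis curved grading scale, whose bin edges (A+ at 84.1 and up,
F below 51.7, nine bins between) were calibrated on the empirical
distribution of SUS scores across hundreds of product studies; the bins
partition [0, 100] exactly, which the tests sweep. Cohort means are
reported to one decimal, the precision at which such scores are
conventionally tabulated.

## The synthetic-scene generator

The generator exists so that every stage — masks, labeling, morphometry,
selection, tracing metrics, opinion aggregation — can be exercised with
known ground truth and no imaging data.

*Scenes.* Islets are discs or star-shaped blobs: a disc of the nominal
equivalent radius perturbed by low-order radial harmonics
($k = 2\ldots4$, relative amplitude = the `irregularity` parameter,
default 0.12). Low-order harmonics give islet-like lobed outlines whose
area stays within a few percent of the nominal diameter (the tests hold
discs to 2% and blobs to 10%). Embedded islets are wrapped in an exocrine
annulus (1.3× the islet radius), emulating the ambiguous-boundary case;
exocrine-only distractor blobs can be added. The RGB rendering (reddish
islets on a light field with Gaussian brightness jitter) is cosmetic — the
mask is the ground truth.

*Bundles.* `make_fixture_bundle()` emulates a multi-center upload: 19
images by default, pixel sizes uniform on 1.41–3.77 µm/px, 4–10 islets per
image with diameters spanning 50–400 µm skewed toward small islets
(Beta(1, 2.5) on the log scale, matching the small-islet-heavy size
distributions of real isolates), about one islet in five embedded.
Diameter draws are capped at what fits the scene at the drawn pixel size,
and placement is rejection-sampled to keep non-embedded islets disjoint; a
crowded scene places fewer islets rather than failing.

*Simulated tracing.* An expert line displaces each template vertex along
the local normal by Gaussian noise of marginal SD $\sigma$ px. The
per-vertex draws are smoothed along the curve with a Gaussian kernel
(correlation length ~8 vertices, circular on closed contours) and then
rescaled back to marginal SD $\sigma$. Both halves of that choice are
deliberate: a tracing hand drifts smoothly off the target line rather than
oscillating pixel by pixel, and without the rescaling the smoothing would
silently shrink the realized jitter below the nominal $\sigma$, making the
noise parameter an upper bound instead of the truth. With it, the measured
mean line distance tracks the folded-normal mean
$E|N(0,\sigma)| = \sigma\sqrt{2/\pi}$ closely for $\sigma \ge 1$ px, which
the tests verify along with strict monotonicity in $\sigma$.

*What the generator does not emulate* — and therefore what passing tests
do **not** show: staining variability and color texture, out-of-focus or
uneven illumination, genuinely ambiguous islet boundaries (the synthetic
ground truth is exact by construction), intentional expert disagreement
(simulated disputes are random, not opinionated), and fragmented or
overlapping touching islets beyond the embedded-annulus case. Results on
synthetic data validate the algorithms and their contracts, not human
expert performance.

## Numerical and scale choices

- Contour templates trace a component's boundary by angular ordering
  around the centroid, valid because generated blobs are star-shaped; for
  arbitrary (non-star-shaped) components a boundary-following tracer would
  be needed. Separation-line templates are centroid chords extended past
  the component so that trimming is exercised.
- Nearest-neighbor distances are computed from the exact all-pairs
  Euclidean matrix in row blocks (capped around 4·10⁶ entries per block),
  exact to machine precision; no spatial index is used because review-set
  lines are a few hundred pixels.
- Test and acceptance problem sizes — 300 px scenes, 19-image bundles,
  9 × 15 and 9 × 3 experiments, 100-mask and 200-pair oracle sweeps — were
  chosen so the full suite exercises every contract in well under a
  minute while keeping rasterization error comfortably inside the stated
  tolerances (e.g. disc diameters recover within 2% at these scales).
- Determinism: every stochastic entry point takes a seed; internal seeded
  evaluation saves and restores the caller's RNG state, so package calls
  never perturb a user's own simulation stream. Manifest CSVs round-trip
  bit-exactly and repeated runs with equal seeds are byte-identical.

## Known limitations

- The labeler and boundary extractor operate on matrices in memory;
  images far larger than typical micrographs (thousands of pixels per
  side) are fine, but tiled processing of slide scans is out of scope.
- Volume comparison assumes the template volume is positive; scoring a
  contour against an empty template is a caller error by design.
- The even-odd fill assigns self-intersecting expert contours a
  well-defined but possibly surprising area; such contours are not
  detected or flagged.
- Anonymization is per report: the same expert maps to the same `eN`
  within one report, but labels are not stable across reports.
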