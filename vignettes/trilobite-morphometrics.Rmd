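---
title: "Landmark morphometrics and disparity for trilobite cephala and pygidia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark morphometrics and disparity for trilobite cephala and pygidia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trilodisp)
```

## The problem

Occurrence databases measure taxonomic diversity; they say nothing about
how much *morphology* a fauna spans. For trilobites — with an excellent
Palaeozoic record and over 20,000 described species — morphological
disparity computed from landmark data is the natural complement to
richness curves, and a community landmarking standard makes data digitised
by many contributors comparable. `trilodisp` implements that workflow end
to end: reading and validating 2D shape files against fixed
cephalon/pygidium templates, arc-length resampling of semilandmark curves,
generalised Procrustes superimposition, covariance-PCA morphospaces,
disparity metrics binned over geological stages, and a measurement-error
validation protocol — plus a seeded synthetic-data generator so the whole
chain is testable offline.

## The landmark standard

Two structures are digitised, always on the right half in dorsal view
(specimens better preserved on the left are mirrored first,
`mirror_configuration()`):

* **cephalon** — 16 fixed landmarks and 4 semilandmark curves: glabellar
  outline (LM2–LM7), facial suture (LM10–LM12), anterior margin
  (LM13–LM15), posterior margin (LM4–LM15);
* **pygidium** — 7 landmarks and 3 curves: axis (LM1–LM2), border furrow
  (LM3–LM6), margin (LM4–LM5).

Every curve is bound at both ends to a fixed landmark. The eye landmarks
(LM8, LM9, LM14) may legitimately be absent in blind taxa; the validator
tolerates exactly these under `allow_absent = TRUE`, driven by the
`morphology.eyes` metadata flag. Spine landmarks (LM13, LM16, pygidial
LM4) are positional variants, not absences. For marginal facial sutures,
LM10 coincides with LM1; the validator notes this without flagging an
error. Cranidium-only specimens are handled as cephala with the
librigenal landmarks absent — the validator reports the absences and the
user decides between the two removal policies below; no reduced template
is defined.

```{r}
structure_template("cephalon")
```

## File dialects and validation

Shape files come one per specimen per structure, named `<ID>_C` /
`<ID>_P` (case-insensitive, last underscore token). Two dialects are
read and written:

* **tps** (`read_tps()`/`write_tps()`): `LM=`, coordinate lines,
  `CURVES=`/`POINTS=`, `IMAGE=`, `ID=`, `SCALE=`. Coordinates are stored
  in physical units (the scale is applied at read time); files without a
  scale are kept but flagged `unscaled` — superimposition removes size
  anyway, only centroid-size reports need the flag. The encoding of
  missing landmarks in tps files is not standardised; the reader's
  default (`missing_as_negative = TRUE`) treats a landmark whose two raw
  coordinates are both negative as missing, which matches common
  digitiser practice, and the toggle covers files that use no such
  convention.
* **StereoMorph-style text** (`read_stereomorph()`): named blocks
  (`landmarks.pixel`, `curves.pixel`, `scaling` or
  `ruler.pixel`/`ruler.interval`). Landmarks are matched by *name* and
  reordered to the template order, so file order is irrelevant; absent
  names become missing landmarks.

`validate_configuration()` is the homogeneity check run before any
analysis: landmark count, curve count and length (minimum 3 points — a
2-point curve carries no shape beyond its endpoints and breaks
interpolation edge cases), scale presence, missing landmarks. Metadata
(`read_metadata()`, YAML, one entry per specimen) is validated for the
mandatory fields, coordinate ranges and ontogeny levels; violations are
*reported, never repaired*.

## Resampling and assembly

`resample_curve()` places `k` points at equal arc-length steps on the
piecewise-linear interpolant of a digitised polyline. Piecewise-linear
rather than spline interpolation is deliberate: it is deterministic and
cannot overshoot sparsely digitised curves. `fix_shapes()` then stacks
conforming specimens into the standard `p × 2 × n` array under one of two
policies: `drop_specimen` (default — specimens failing validation are
excluded and listed) or `drop_trait` (landmarks missing in *any* specimen
are removed from *all*, together with every curve bound to a removed
landmark — the recommended treatment for traits absent in some taxa).

Because both curve endpoints are template-bound fixed landmarks, each
resampled curve contributes only its `k − 2` interior points (endpoint
deduplication); otherwise the shared points would be counted twice and
silently up-weight curve junctions in the superimposition. With the
reference cephalic counts `c(12, 20, 20, 20)` this yields
`16 + 10 + 18 + 18 + 18 = 80` points per specimen. The original tools do
not document their handling of the duplicate endpoints; deduplication is
this package's declared convention.

## Superimposition

`gpa()` is a from-first-principles generalised Procrustes analysis:
configurations are centred and scaled to unit centroid size (full
Procrustes; `scale = FALSE` preserves sizes), rotated onto the consensus
by the SVD solution of the two-shape problem (`opa()`), and the consensus
is recomputed as the renormalised mean until its change drops below `tol`
(default 1e-8, `max_iter = 100`; hitting the cap flags non-convergence
with a warning rather than failing).

Numerical and design choices:

* Reflections are disallowed (`det R = +1`, enforced through the singular
  value sign) because the protocol pre-mirrors specimens to the right
  side; `allow_reflection = TRUE` exists for QC.
* The consensus is initialised from the lexically first specimen id, so
  the result cannot depend on input order.
* The OPA residual is evaluated directly as ‖Â − B̂R‖ rather than via the
  algebraically equivalent √(2 − 2Σσᵢ): the closed form loses half its
  significant digits to cancellation near identity and cannot meet the
  1e-9 invariance tolerances the tests impose.
* Downstream statistics use Euclidean (tangent-space) distances between
  aligned pre-shapes (`pairwise_distances()`); exact full Procrustes
  distances remain available via `procrustes_distance()`.
* **No semilandmark sliding.** The upstream workflow calls a GPA routine
  that *can* slide semilandmarks but does not state whether it did;
  sliding is deliberately excluded here, and semilandmarks are fixed
  points after resampling. Comparisons with slid analyses will differ,
  most visibly along curve-tangent directions.

## Morphospace

`shape_pca()` performs covariance-based (not correlation-based) PCA of
the flattened aligned coordinates, denominator `n − 1`. Components with
eigenvalue below 1e-12 of the leading one are dropped as noise axes.
Eigenvector signs are fixed by making each column's largest-magnitude
entry positive — scores and virtual shapes are then reproducible across
platforms. `reconstruct_shape()` maps any score vector back to a
configuration (zero gives the consensus), which is how virtual shapes
annotating a morphospace are produced; `occupancy_grid()` builds the
per-interval presence/absence table behind through-time morphospace
plots.

## Disparity through time

Three metrics on morphospace scores: **SoV** (sum of per-axis sample
variances — dispersion about the centroid, the headline metric), **SoR**
(sum of ranges — extent, outlier-sensitive), **NND** (mean nearest
neighbour distance — packing). SoV and NND are rotation-invariant in the
full space; SoR is only stable under axis permutations, which is one
reason it is reported alongside rather than instead of SoV.
`disparity_through_time()` defaults to **all** retained PCs (the source
workflow does not state a truncation; `n_axes` exposes one).

Specimens are assigned to geological stages by age-range overlap
(`assign_bins()`, `min_age`/`max_age` stage names against a contiguous
stage table; a Devonian table with ICS ages ships as both
`devonian_stages()` and a CSV). Richness standardisation uses
**range-through** counting (`richness_range_through()`): a taxon is
present in every stage between its first and last occurrence.

Uncertainty is a percentile bootstrap over specimens within bin
(resampling with replacement, seed mandatory). One caveat is documented
rather than hidden: for SoR the upper percentile cannot exceed the point
estimate — a resample never widens a range — so the interval brackets the
point estimate for variance-type metrics but is a downward-biased band
for ranges. Bins with fewer than two specimens report `NA` metrics, not
zeros.

## Measurement-error validation

The data-quality protocol compares three scales of variation after a
*joint* GPA: within-observer (replicate digitisations by one person),
among-observer (one digitisation each by several people), and among-genus
(the natural variation yardstick). `error_report()` reports mean
within-group pairwise tangent distances and their ratios to the genus
group, a Kruskal-Wallis rank test (own implementation, tie-corrected,
verified against the reference implementation), and a PERMDISP-style
homogeneity-of-dispersions test: distances to the *mean* group centroid
(not the spatial median — the workflow pairs the test with a classic
Tukey HSD on fitted distances, which assumes the mean-based
construction), an ANOVA F with parametric and permutation p values
(add-one correction, default 9,999 permutations, seeded), and the Tukey
table at family-wise 95%.

The misplaced-landmark scenario deserves a note. In the replicated
experiment one observer displaces LM15 — a landmark that terminates two
marginal curves — while the digitised curves still trace the true
outline; the displaced point therefore weighs 1/16 of a landmark-only
configuration but only 1/80 of the full one, and landmark-only
among-observer variability rises above the full configuration's. Had the
simulator regenerated curves from the displaced landmark the contrast
would invert; the chosen semantics match how an observer actually
digitises an image.

## The synthetic world

`simulate_dataset()` states its world once: genus mean shapes are the
idealised base configuration plus isotropic Gaussian landmark
displacements (`sigma_between`, default 0.1 on a shape of extent ≈ 1 —
clearly separated genera), specimens add `sigma_within` (default 0.01 —
an order of magnitude below genus spread, the regime the error
experiments assume), and each specimen receives a nuisance similarity
transform (rotation ±180°, translation ±1, scale 0.5–2) that GPA must
remove. Curve interiors inherit a linear blend of their endpoint
displacements along normalised arc length, keeping bindings exact;
isotropic landmark noise without correlated deformation fields is enough
for the ordering/recovery tests the generator exists for, and keeps the
truth table exact. Files are written half as tps, half as
StereoMorph-style text, with image-like positive coordinates (digitisers
emit pixel coordinates, and the tps missing-landmark convention would
otherwise corrupt negative ones). Defects are injected with stated
probabilities and recorded in the truth table: missing landmarks, missing
scales, blind genera (eye landmarks absent, `morphology.eyes: false`).

`simulate_error_experiment()` mirrors the replicate-digitisation design:
defaults `sigma_within = 0.01`, `sigma_among = 0.02` (observer bias, 2×),
`sigma_between = 0.2` (genus spread, 20×), 10 replicates, 8 observers,
two within-observer sets, 20 reference genera.

What a green test does **not** establish: the generator has no correlated
deformation, no allometry, no preservation-dependent landmark loss, no
digitiser-specific bias structure — so passing recovery tests demonstrate
the *pipeline's* correctness, not that real trilobite data meet the
generator's assumptions.

## Known limitations

* 2D only; no missing-data imputation during alignment (specimens or
  traits are dropped instead, explicitly).
* No semilandmark sliding (above).
* Stage assignment needs stage *names* resolvable in the supplied table;
  numeric ages are not interpolated.
* The chi-squared reference for the Kruskal-Wallis statistic and the F
  reference for the parametric dispersion p are asymptotic; for the small
  groups typical of error experiments the permutation p is the one to
  report.
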