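---
title: "Morphological portraits of stem-cell colonies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological portraits of stem-cell colonies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonymorph)
```

## The problem

Human pluripotent stem cells (hPSCs) grow in vitro as monolayer colonies, and
an experienced culturist judges colony quality by eye: a healthy
undifferentiated ("good") colony is round-ish with a well-defined edge and
tightly packed small cells (10–16 µm); a colony showing differentiation signs
("bad") has loosely packed, often elongated cells with phase-bright gaps and a
spiky, irregular edge. `colonymorph` turns that judgement into numbers. From a
labeled segmentation raster (a cell label mask plus a colony footprint mask)
it computes seven shape descriptors per cell and per colony, analyzes their
variance across lines, growth times and phenotypes, quantifies how informative
each descriptor is for phenotype classification, and relates phenotype and
clonality groups to relative pluripotency-gene expression measured by qPCR.

The seven descriptors are:

| descriptor     | definition                                                     | units  |
|----------------|----------------------------------------------------------------|--------|
| `area`         | pixel count × pixel size²                                       | µm²    |
| `perimeter`    | boundary length (estimators below)                              | µm     |
| `minor_axis`   | minor axis of the area-matched moment ellipse                   | µm     |
| `feret_d`      | maximal caliper (largest boundary point distance)               | µm     |
| `min_feret_d`  | minimal caliper width                                           | µm     |
| `shape_factor` | isoperimetric quotient 4π·area/perimeter²                       | —      |
| `ais`          | area of intercellular space: footprint − Σ cell areas (colonies)| µm²    |

## Raster conventions and numerical choices

Regions are sets of unit square pixels, 4-connected, with label 0 reserved for
background; the pixel in matrix row *r*, column *c* occupies the unit square
with corners at integer coordinates. All lengths scale linearly and areas
quadratically with `pixel_size`, exactly.

**Perimeter.** No single local estimator is simultaneously exact on
axis-aligned rectangles and convergent on smooth curves, so
`region_perimeter()` exposes three:

* `"weighted"` (default) — the 8-connected boundary chain with Kulpa weights
  (0.948 per straight step, 1.340 per diagonal step). On a rasterized disk of
  radius 200 px it is within about 0.3 % of 2πr; the classical Freeman chain
  (`"chain"`, weights 1 and √2) is asymptotically ~5.5 % high on smooth
  boundaries.
* `"corner"` — the axis-aligned pixel-corner (crack) polygon. Exact for
  rectangles (a 10×10 px square has perimeter 40) and for a single pixel (4),
  but ~27 % high on disks. This is the polygon a wand-type particle tracer
  follows.
* `"chain"` — the Freeman chain length, kept for comparability.

Regions too small to trace fall back to the corner polygon. The shape factor
is *not* clamped at 1: on near-circular fine rasters the weighted estimator
can land slightly below the true perimeter, giving values just above 1 (the
disk example above yields ≈ 1.006); tests and analyses use tolerances rather
than clamping.

**Feret diameters.** Measured on the convex hull of the corner points of
boundary pixels: the maximal Feret by rotating-calipers antipodal search
(verified in the tests against an exhaustive pairwise-distance oracle), the
minimal Feret as the minimum over hull-edge-aligned projection widths, which
is exact for convex polygons. A w×h rectangle therefore reports
feret = √(w²+h²) and min-feret = min(w, h), and a single pixel reports √2.

**Moment ellipse.** Axes come from the eigenvalues of the second central
moments of pixel centres, then both axes are rescaled so that
π/4·major·minor equals the region area exactly (the particle-analyzer
convention); degenerate collinear regions report `minor = 0` with a warning.

**AIS.** Defined by subtraction — footprint pixels minus the union of cell
pixels — so holes in the footprint interior count as intercellular space,
while holes inside an individual cell are filled before that cell is
measured.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without any
external download; its defaults define the simulated study conditions the
analysis assumes.

**Images** (`generate_colony_image()`). The footprint is a disk whose area
follows the line's monotone growth curve over 24–120 h, perturbed radially by
a low-order Fourier series (amplitude = `boundary_irregularity`) plus, for
the bad preset, a handful of narrow spikes. Cells are an anisotropically
weighted Voronoi tessellation of dart-thrown seeds: each seed gets a random
orientation, a diameter drawn from N(13, 1.5²) µm, and an elongation around
the preset target (with a 10 % doubled-elongation outlier fraction in the bad
preset). Intercellular space is carved along the near-bisector channels where
the first- and second-nearest seed distances are close; the channel width is
tuned by a short deterministic bisection until the realized gap fraction is
within ±0.005 of the target (the contract is ±0.03). `gap_fraction = 0`
skips carving entirely, so the tessellation is exact and the AIS is exactly
zero. Every cell is reduced to its largest 4-connected component, labels are
contiguous, and the whole construction is a pure function of
(line, phenotype, time, seed).

Default presets: good = gap 0.04, elongation 1.15, smooth edge; bad = gap
0.14, elongation 1.6, irregular spiky edge. Pixel size defaults to 1 µm/px on
a ≥512² raster.

What the images do *not* emulate: phase-contrast optics, segmentation errors,
colony merging/fragmentation, or growth mechanics. Passing the round-trip
tests shows the measurement chain is correct on clean labeled rasters, not
that segmentation of real images would be.

**Feature tables** (`generate_feature_table()`). Records are multivariate
normal draws per (line, phenotype) group. The default group means put the
good/bad separation mostly into AIS and shape factor with smaller
size-descriptor shifts (opposite in sign for the ES-like line, mirroring
line-dependent phenotype effects), at an overall Mahalanobis separation of
roughly 1.4 — a two-class Bayes accuracy near 75 %, the regime in which
expert phenotype calls are predictable but not trivially so. The magnitudes
of real phenotype differences are not published, so these effect sizes are
calibration choices fixed once; the clonality label is generated
independently of the descriptors (it carries expression effects only).
Samples are clipped to the record invariants (shape factor in (0, 1], AIS
below area, calipers bounding the minor axis), so tests that need exactly
independent columns place group means away from those bounds.

**Ct panels** (`generate_ct_panel()`). A planted fold change f for gene g in
group j lowers that gene's expected Ct by log2 f cycles; measurement noise is
i.i.d. Gaussian per well; the reference gene carries noise but no group
effect. Three technical replicates × three biological repeats is the default
design.

## Statistics

Dynamics are summarized as mean ± SEM per (line, time bin, descriptor) with
bins 24 h, 48 h and a pooled 72–120 h. Two-group comparisons use Welch's
t-test when both samples pass a Shapiro–Wilk normality gate at α = 0.05
(Anderson–Darling above n = 5000, where Shapiro–Wilk is unavailable) and the
Mann–Whitney test otherwise; the choice is recorded per test. The per-line
phenotype screen runs this comparison for every descriptor on the 24–48 h
window, without multiple-testing correction by default (per-descriptor
α = 0.05 reporting; Holm is available). The line×phenotype interaction is
tested by a two-way ANOVA with Type II sums of squares, appropriate for
unbalanced group sizes.

Calibration is part of the test suite: the type-I error of both the gated
comparison and the interaction F sits at 0.05 ± 0.01 over 2000 null
simulations, and a ±0.5 sd alternating interaction pattern (a 1 sd
interaction contrast) at n = 30 per design cell is detected in ≥95 % of
simulations. A pure additive design with zero noise has interaction sum of
squares exactly zero — the F ratio itself is 0/0 there, which is why the
tests assert the sum of squares rather than a p-value in that limit.

## Classification and the importance measure

The classifier is declared, not searched for: a single-hidden-layer
feed-forward network over a fixed grid (hidden units {4, 8, 16} × weight
decay {0.01, 0.1}), features standardized within each training fold, trained
with seeded initialization, evaluated by 10×5-fold stratified repeated CV;
the grid point with the best mean CV accuracy is reported, a deliberate,
documented stand-in for an automated configuration search that cannot be
reproduced otherwise (selecting the best grid point by the same CV adds a
small optimistic bias). A logistic-regression family is available where many
repeated fits are needed cheaply (the exhaustive-subset simulations). Within
`train_cv()` the predictor subset is canonicalized to alphabetical order, so
equal sets give bit-identical results.

For p descriptors, all subsets of size 2..p are enumerated (120 for p = 7)
and each is trained once. The importance of a descriptor is the unweighted
mean CV accuracy of the 2^(p−1) − 1 = 63 subsets containing it; descending
order, alphabetical tie-break. The top-k curve retrains on the k best
descriptors for k = 2..p; the minimal model is the smallest k whose accuracy
is within one SEM (taken at the maximizer) of the curve's maximum.

Two properties of this rule matter in practice. First, the SEM across CV
repeats underestimates the true uncertainty of a CV accuracy (repeats share
the data), so on gently sloping plateaus the selected k can wobble; the
package applies the rule exactly as stated and leaves interpretation to the
analyst. Second, the planted-signal tests therefore use constructions where
the answer is forced: a single informative descriptor at a 1.5 sd shift
(rank-first recovery), and a pair of *fully* separating descriptors (10 sd)
for which the curve is exactly flat at its ceiling from k = 2, making the
minimal-model selection deterministic.

Whole-sample confusion matrices are built from pooled out-of-fold predictions
of one CV repeat (resubstitution is available by flag); per-class rates are
the class recalls (correct members of an observed class over that class's
observed total), reported as half-up-rounded integer percents, and per-line
misclassification counts are attached when line metadata is present. A
correlation pre-filter (`drop_correlated()`, threshold 0.95) reproduces the
preliminary exclusion of near-collinear cellular descriptors before
exhaustive enumeration.

## Relative expression

Technical replicates are averaged first; the biological repeat is the unit of
inference. Per repeat, ΔCt = mean Ct(target) − mean Ct(reference gene), the
relative quantity is 2^−ΔCt (amplification efficiency fixed at 2), and a
group's fold change is its mean relative quantity divided by the reference
group's — so the reference group's pooled fold change is exactly 1, and a
global Ct shift cancels exactly. SEM is over biological repeats on the fold
scale; per-gene tests against the reference group reuse the normality-gated
comparison (unpaired), with the usual star coding. Reference-gene candidates
are ranked by the SD of their sample-mean Ct across all samples — the
simplest stability score consistent with screening a housekeeping panel;
geNorm-style pairwise scores are out of scope. The embryoid-body
differentiation-marker analysis is the same operations on a different gene
list and grouping; there is no separate code path.

## Pipeline, sizes and limitations

`run_pipeline()` chains simulate → measure → stats → classify → express from
one seeded config (YAML-readable) and writes one CSV per result plus a report
stamped with the config hash; identical (config, seed) gives byte-identical
outputs. Defaults are sized for interactive use: 40 records per (line,
phenotype) group for the tabular stages, one image per (line, phenotype,
time) for the measurement demonstration, and 2000-replicate null simulations
where calibration is being estimated. The phenotype screen defaults to the
24–48 h window; classification uses all records by default, with a
configurable window, because the subset of records entering a published
classification is in general ambiguous.

Known limitations: the perimeter default is tuned for smooth biological
boundaries and will under-read jagged axis-aligned structures (use
`"corner"` there); the minimal-model rule inherits the optimism of repeated
CV SEMs; expression tests at n = 3 biological repeats have little power, as
in any standard triplicate design — planted-effect recovery in the tests is
demonstrated at higher replication; and the synthetic data, by design,
contains none of the segmentation noise of real phase-contrast imagery, so
green tests validate the computational chain, not an imaging protocol.
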