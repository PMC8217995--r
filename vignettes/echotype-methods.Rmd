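---
title: "Echogenicity-based tissue characterization and edema typing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echogenicity-based tissue characterization and edema typing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echotype)
```

## The problem

Lower-limb edema can be of venous, lymphatic, or mixed origin, and the
therapeutic response differs by origin. On B-mode ultrasound the affected
subcutaneous tissue looks different by etiology — lymphedematous tissue
shows hypoechoic, vertically oriented fluid spaces ("lymphatic lakes"),
venous edema a granular mid-brightness texture — but the unaided eye
resolves only about 16 of the 256 gray tones a frame carries. `echotype`
quantifies the full grayscale: it calibrates frames against a fascia
reference, summarizes a region by its Gray Scale Median (GSM) and by the
fraction of pixels falling into each of 14 echogenicity intervals, renders
a pseudocolor map, and types the edema from the shape of that interval
distribution.

## Brightness-axis structure

The 0–255 axis carries two nested structures. Five *color bands* drive the
pseudocolor rendering: non-echogenic [0,4], low echogenicity [5,60],
echogenic [61,132], high echogenicity [133,210], saturation [211,255].
The histogram works on a finer canonical partition of exactly 14
intervals, built by splitting each color band into equal-width
sub-intervals (the low band into hypoechogenic I–IV, the echogenic band
into echogenic I–III, the high band into hyperechogenic I–V; any integer
remainder goes to the earliest sub-intervals):

```{r partition}
build_canonical_partition()
```

This subdivision was a genuinely open design point: group-level results
are reported in Roman-numeral interval names while the classical tissue
reference bands (Lal et al.: blood 0–4, fat 8–26, muscle 41–76, fibrosis
112–196, calcium 211–255) are neither contiguous nor 14 in number, so no
verbatim 14-interval table exists to copy. The equal-width subdivision of
the five quotable color bands is the unique construction consistent with
(a) exactly 14 intervals, (b) the color-band bounds, and (c) the
Roman-numeral naming scheme. The Lal bands are kept as annotations
(`tissue_tag`) on intervals fully nested inside one band; they never
affect binning. The whole table is overridable through the YAML config
(`inst/extdata/canonical_partition.yaml` ships the canonical one).

A related inconsistency is the lymphatic-lake brightness bound: lakes are
described both by the numeric range 0–40 and by an interval-name span that
does not resolve to 40 under any consistent table. The package keeps the
quotable numeric bound: `lake_fraction` is the share of ROI pixels with
brightness ≤ 40, and phantom lake lumina draw only from intervals wholly
inside [0,40].

## Fascia-anchored calibration

Absolute echo brightness depends on gain, so frames are normalized by
anchoring a user-selected bright fascia band to level 200. Only the anchor
level is well defined; the mapping itself was open. The package uses the
simplest monotone map consistent with anchoring a single level: one
multiplicative gain `s = 200 / median(fascia ROI)`, applied as
`round_half_up(pixel × s)` clipped to [0,255]. The median (rather than the
mean) resists speckle outliers inside the fascia ROI. Alternatives (gain +
offset, two-point maps) would need a second anchor that is not available.
Consequences tested as properties: the calibrated fascia median is
200 ± 1; recalibration changes no pixel by more than 1; pixel ordering is
preserved below the clipping ceiling; GSM commutes with calibration when
nothing clips. The fraction of clipped pixels is recorded and a clipped
fraction above 5% (configurable) warns of an over-bright anchor.

## Characterization and classification

For an ROI the package computes the GSM (sample median; even counts give
the mean of the two middle order statistics), the 14-interval mass vector,
and the lake fraction. Pixels outside the ROI never contribute, and a true
brightness 0 inside the ROI counts toward the non-echogenic interval —
there is no background special-casing.

Each edema class concentrates pixel mass in a characteristic interval
span: venous (VEG) 88.31% in hypoechogenic IV–echogenic III ([47,132]),
lymphatic (LEG) 71.73% in hypoechogenic II–echogenic I ([19,84]), mixed
(MEG) 76.17% in hypoechogenic III–echogenic II ([33,108]), control (NEG)
84.87% in echogenic II–hyperechogenic I ([85,148]). These are group-level
distributions, not a decision procedure, so the classifier is this
package's own operationalization: score each class by its range mass
*density-normalized* by span width (`mass / width × 256`, i.e. the
concentration relative to a uniform distribution over the scale) and take
the argmax. Raw mass would bias toward wide spans, since the four spans
overlap and differ in width (86, 66, 76, 64 levels). When the top two
density scores differ by less than `decision_margin` (default 0.05 — small
relative to the ≳0.25 gaps the shipped class profiles produce, but enough
to catch near-uniform histograms) the result is `INDETERMINATE`, flagged
for human review rather than forced into a class — mirroring how a mixed
phenotype emerges during analysis. The lake flag (lake fraction ≥ 0.25,
configurable) is advisory metadata supporting the lymphatic-lake finding;
it never overrides the argmax.

## The phantom generator

No clinical images are distributable, so the generator *is* the study
condition for every end-to-end test. A phantom is built from a target
14-interval mass vector: each tissue pixel gets an interval by multinomial
sampling from that vector and then a brightness uniform within its
interval, so the mass contract holds exactly up to sampling noise
(±0.02 at the default 240×256-pixel tissue area is a generous bound; the
actual multinomial standard error is ≈0.002). Class morphology:

* **Lakes** (lymphatic, mixed): vertically elongated ellipses (axis ratio
  3, minor diameter 3–10 px, matching lumina of a few tenths of a mm at
  typical linear-probe resolutions) whose pixels take only labels from
  intervals inside the [0,40] lumen band — so "all lake pixels ≤ 40" is
  assertable by construction. Defaults: 6 lakes for lymphatic phantoms, 3
  for mixed.
* **Granularity** (venous, mixed): remaining labels are laid out along a
  box-blurred Gaussian random field (window = `granularity_px`, default
  4 px), placing similar brightness into patches without changing any
  count.
* **Speckle**: multiplicative log-normal noise (σ = 0.15) re-quantized
  with an interval-preserving correction — a pixel pushed out of its
  assigned interval is resampled uniformly within it. Texture therefore
  never breaks the mass contract the recovery tests rely on.

Each phantom carries a built-in fascia band (top 16 rows) whose median is
exactly 200 by construction (a strict majority of band pixels at 200), so
the pipeline's calibration step runs for real on phantoms yet is an
identity map, keeping the generated mass vector interpretable as the
calibrated one. Cohorts jitter each phantom's class-range mass by a
uniform ±0.02 to mimic inter-limb variability; ±0.02 keeps cohort means
testable at the ±1-percentage-point level with n = 40. All generation is
seed-deterministic and restores the caller's RNG state.

What phantoms do *not* emulate: acoustic physics (point-spread function,
attenuation, depth-dependent gain), anatomy (layered dermis/subcutis),
vendor post-processing. Passing recovery tests therefore shows the
pipeline is a faithful measurement chain for distributions of the
prescribed shape — not that real limbs produce those distributions.

## Group statistics

`compare_groups()` reproduces the testing plan for per-limb GSM: classic
mean-centered Levene's test gates at α = 0.05 between one-way ANOVA with
Tukey-HSD (homogeneous variances) and Kruskal–Wallis with Dunn's post hoc
(heterogeneous). Dunn's test is implemented in-package (tie-corrected
pairwise z on mean ranks) with Bonferroni adjustment by default — the
adjustment is configurable because none is canonical. Its correctness is
checked against the identity z² = tie-corrected Kruskal–Wallis H for two
groups, and the whole gate is validated by a seeded type-I-error
simulation (nominal 5%, accepted within binomial tolerance) rather than
against published statistics, since none are printed for this design.
Degenerate input in which every value is identical leaves the F statistics
undefined (0/0); such data carry no evidence against any null, so the
report fixes all p-values at 1 on the ANOVA branch. Limbs are treated as
exchangeable observations even though several limbs may come from one
participant; with participant identity unavailable this overstates the
effective sample size, and users with participant IDs should aggregate
first.

## Problem sizes and numerical choices

Recovery checks run four cohorts of 40 phantoms at 256×256 px — large
enough that the multinomial and jitter noise on a cohort mean (~0.2
percentage points) sits well inside the ±1-point acceptance band, small
enough to run in seconds. The type-I simulation uses 1000 null datasets of
two groups × 50 values. Rounding is half-up everywhere a brightness is
produced; polygon ROIs include a pixel iff its center (row+0.5, col+0.5 in
0-based coordinates) lies inside the polygon under the even-odd rule,
which makes shared borders between adjacent ROIs partition pixels cleanly.
Color inputs are rejected rather than luma-converted: a colorized frame no
longer carries raw echo brightness. DICOM secondary captures must be
exported to PNG/TIFF upstream; only single-frame grayscale input is
accepted.

## Known limitations

* The classifier is an operationalization of group-level distributions;
  it is not validated against clinical diagnoses and makes no
  diagnosis-grade claims.
* Calibration assumes a single multiplicative gain; depth-dependent gain
  differences between frames are not corrected.
* Phantom realism is statistical, not acoustic (see above).
* Group comparisons ignore within-participant correlation between limbs.
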