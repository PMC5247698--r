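---
title: "Measuring steatosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring steatosis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatomorph)
```

## The measurement problem

Hepatic steatosis is conventionally called when more than 5% of the liver
parenchyma is fat, but a pathologist's visual estimate of that percentage is
coarse and poorly repeatable. `steatomorph` implements a digital-image-analysis
alternative: the **measured fat proportionate area (mFPA)**, the area occupied
by fat vacuoles as a proportion of the whole parenchyma area in H&E-stained
sections. On top of the fat measurement, the package carries the morphometric
quantities that describe how the liver lobule accommodates fat — hepatocyte
area (HA), lobule radius (LR) and hepatocytes per lobule (HpL) — and the
non-parametric statistics that relate mFPA to serum transaminases.

Because no image archive ships with the package, a synthetic-histology module
generates ground-truthed fields and cohorts. Everything downstream is tested
against that ground truth.

## Fat segmentation

In H&E material, fat vacuoles are unstained: near-white, near-circular holes
in eosin-pink cytoplasm. `segment_fat()` exploits exactly that:

1. **Whiteness rule.** A pixel is candidate fat when all three RGB channels
   reach their thresholds (default 200/200/200 on the 8-bit scale). The
   default sits between the synthetic eosin band (red ≈ 200, green ≈ 120,
   blue ≈ 150) and vacuole white (≈ 245 on all channels); with real scanner
   output the thresholds are the first thing to recalibrate.
2. **Background removal.** Off-section background is also white. Candidate
   components touching the field border with area above 10% of the field are
   treated as section edge, not fat. The size condition keeps genuine
   vacuoles near the border in play.
3. **Object filters.** Remaining candidate components (8-connected, holes
   optionally filled) are kept as fat only if their area lies in 20–8000 µm²
   and their circularity `4πA/P²` is at least 0.5, with the perimeter taken
   along the 8-connected boundary contour. Everything that fails moves to an
   exclusion mask. This is an *automated proxy* for the manual editing step
   of the original protocol, in which dilated sinusoids, vessels and fibrous
   areas were edited out by hand; a user-supplied exclusion mask is also
   honoured for true manual editing.
4. **The ratio.** Excluded pixels leave numerator *and* denominator:
   parenchyma is everything that is neither background nor excluded, fat
   pixels included. mFPA per biopsy is the pooled ratio
   `100 · Σ fat / Σ parenchyma` over its fields — a single area proportion,
   not a mean of per-field percentages.

The area window deserves a note: an 8000 µm² disc has diameter ≈ 101 µm,
just above the largest macrovesicular vacuoles, so round vessel lumens
(diameter well above 110 µm in the generator) fail on size even though they
pass on shape, while elongated sinusoids fail on shape long before size.

The standard protocol images 21 random non-overlapping fields per biopsy
(`sample_fields()`, seeded). `adequacy_check()` reconstructs a stopping rule
for that number: the running pooled estimate (cumulative mean of per-field
fractions) must drift by no more than 0.5 percentage points over the last
five fields. The exact historical adequacy procedure is not documented in
the source material; this convergence rule is our reconstruction and is
labelled as such.

## Lobule morphometry

Hepatocyte profiles are modelled as ovals: `ellipse_area(d1, d2) =
π(d1/2)(d2/2)` from two perpendicular diameters, with per-biopsy HA the
median of (nominally 50) cell areas. LR is the median
portal-tract-to-central-vein distance.

HpL divides the cross-sectional area of an idealised hexagonal lobule by the
hepatocyte area. The genuinely ambiguous design point is what the measured
distance is: the distance from a portal tract (a lobule *corner*) to the
central vein is the hexagon's **circumradius**, giving area `(3√3/2)R²`; if
instead it is read as the apothem, the area is `2√3a²`, exactly 4/3 larger
for the same measured value. We default to the circumradius on the
anatomical argument and expose the apothem behind a switch
(`hepatocytes_per_lobule(..., convention = "apothem")`). HpL is an areal
index, not a stereological cell count: no 3-D correction is attempted, and
even-count medians are midpoints of the central pair throughout.

## Cohort statistics

`cohort_report()` reproduces the analysis bundle: medians/IQRs overall, by
sex and at the 5% split; Spearman correlations of mFPA with ALT, AST, HA,
LR and HpL (pooled *and* sex-stratified, labelled explicitly because the two
can differ appreciably); bracket medians over `<5 / 5–9.9 / 10–19.9 / ≥20` %
mFPA with adjacent-bracket Mann–Whitney tests and an overall Kruskal–Wallis;
and ROC curves of ALT/AST against the 5% and 20% labels with
sensitivity/specificity at clinical cut-offs (31, 33, 41, 67, 75 U/L by
default, `score ≥ cutoff` calling positive).

Numerical conventions worth stating:

* **Bracket edges** 5/10/20 are assigned upward (5.0% is steatotic) and are
  deliberately not configurable.
* **Mann–Whitney** uses full enumeration of group assignments when the
  combined sample is ≤ 14 — this handles ties naturally and yields `p = 1`
  for identical groups — and the tie- and continuity-corrected normal
  approximation otherwise. Both behaviours match `wilcox.test` where the
  latter is defined.
* **AUROC** is the trapezoidal area over the threshold sweep, which equals
  the tie-adjusted concordance probability `P(s⁺ > s⁻) + ½P(s⁺ = s⁻)`; the
  test suite checks the identity to 1e-12 against an O(n²) oracle.
* **No multiplicity adjustment** by default, matching the raw-p reporting
  style of the source analysis; Holm is available behind a flag.
* A fully tied Kruskal–Wallis input returns `H = 0, p = 1` rather than the
  0/0 of the textbook tie correction.
* Missing biochemistry is dropped pairwise per analysis.

## What the generator emulates — and what it does not

`generate_field()` renders eosin-pink parenchyma (RGB ≈ 200/120/150 with
Gaussian texture), haematoxylin nuclear speckle (one ≈ 3 µm nucleus per
300 µm² of tissue), fat vacuoles as non-overlapping near-white discs
(default diameters 10–80 µm, spanning micro- to macrovesicular fat — a
modelling choice, since vacuole size distributions are not documented in
our source material), and optional artifacts: elongated sinusoid ribbons
and oversized vessel lumens, never overlapping fat. Packing is rejection
sampling with a 2 px minimum gap (components stay separable), radius
shrink-on-congestion, bounded total retries, and a loud error naming the
achieved fraction when the target is infeasible (> 60% is refused up
front). The last disc is sized to close the remaining pixel deficit, so the
rasterised true fraction lands within about half a minimum-disc area of the
target.

The generator is *not* photorealistic: no stain variation between slides, no
focus or illumination gradients, no compression artifacts, no fibrosis, no
ballooned or apoptotic cells, and vacuoles are perfect discs rather than the
slightly polygonal profiles of contiguous distended hepatocytes. Passing the
recovery tests therefore demonstrates that the measurement machinery is
correct — not that the default thresholds are right for any particular
scanner's output. Sinusoid ribbons are generated wholly inside the field; a
border-clipped stub can be as round as a vacuole, which is a genuine
limitation of shape-based editing rather than something the simulation
should hide.

`generate_cohort()` draws mFPA from a log-normal (median 5%, quartiles ≈
1.7–9.5%, truncated at 40%) with a male excess, and produces HA, LR, ALT
and AST through monotone links with noise:

* `HA(m) = 260 + 7·min(m,10) + 11·(min(m,25)−10)₊` µm², noise sd 24;
* `LR(m) = 455 + 11·min(m,10)` µm, noise sd 45 — the lobule stops expanding
  above 10% mFPA;
* `ALT(m) = (45 + 2.2m)·e^N(0,0.45)`, `AST(m) = (30 + 0.55m)·e^N(0,0.40)` U/L.

The HA/LR shapes encode the architectural story the package is built to
detect: hepatocytes swell with fat and keep swelling, the lobule expands
until about 10% mFPA and then stops, so HpL (= lobule area over cell area)
first rises slightly and then falls. With these defaults the generator
targets Spearman correlations with mFPA of about 0.82 (HA), 0.64 (LR),
0.43 (ALT) and 0.25 (AST); the suite verifies the HA target within ±0.05
over 200 cohorts. GGT, bilirubin, albumin, ALP and age are drawn
independently of fat, and HpL is always computed from HA and LR, never
sampled.

## Reproducibility and problem sizes

Every stochastic routine takes an explicit seed and uses one global RNG per
call; equal seeds give bit-identical images, cohorts and report files
(checked byte for byte). The test and acceptance workloads use 512 px
(256 µm) fields at 0.5 µm/px for ground-truth recovery — 21 fields per
biopsy at five fat levels — 256 px fields for the 50-field artifact study,
cohorts of n = 136 for trend recovery (100 seeds), and 2000 replicates for
the type-I-error calibration; unit tests run on 256 px fields and smaller
cohorts to stay fast.

## Known limitations

* Channel thresholds, the area window and the circularity cut are tuned to
  the synthetic colour model; real-slide use requires recalibration and
  ideally a stain-normalisation step, which is out of scope.
* The adequacy rule is a reconstruction (see above).
* HpL inherits both the hexagon idealisation and the 2-D section view;
  its absolute scale depends on the circumradius-vs-apothem convention.
* Automated artifact editing is shape/size-based only; pathology that
  mimics vacuoles (e.g. sharply punched-out necrosis) would not be excluded.
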