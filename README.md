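# steatomorph

Quantitative liver steatosis from H&E histology, for pathologists and
image-analysis researchers who need a reproducible alternative to visual fat
grading.

Hepatic steatosis is conventionally defined as more than 5% of the liver
parenchyma being fat, but visual estimates of that percentage are coarse.
`steatomorph` measures it: the **measured fat proportionate area**

```
mFPA = 100 · Σ fat area / Σ parenchyma area   (pooled over ~21 fields per biopsy)
```

is computed from calibrated RGB field images by channel thresholding — fat
vacuoles are near-white, near-circular holes in eosin-pink cytoplasm —
followed by connected-component filtering on area (20–8000 µm²) and
circularity (4πA/P² ≥ 0.5) that stands in for manual editing of sinusoids,
vessels and other near-white confounders.

Around the fat measurement the package carries the lobule morphometry that
describes how the liver accommodates fat:

* hepatocyte area `HA = π(d1/2)(d2/2)` from perpendicular diameters (oval
  model), per-biopsy median of 50 cells;
* lobule radius `LR` = median portal-tract-to-central-vein distance;
* hepatocytes per lobule `HpL = (3√3/2)·LR² / HA` under a hexagonal lobule
  model (circumradius convention; an apothem variant, exactly 4/3 larger, is
  available);

and the cohort statistics relating mFPA to liver biochemistry: Spearman
correlations, Mann–Whitney / Kruskal–Wallis tests across the
`<5 / 5–9.9 / 10–19.9 / ≥20 %` mFPA brackets, and ROC analysis of ALT/AST
against the 5% and 20% steatosis labels.

A synthetic-histology module generates ground-truthed H&E-like fields and
patient cohorts with the full statistical structure (right-skewed mFPA,
monotone mFPA→HA/LR/ALT/AST links, plateauing lobule expansion), so the whole
pipeline is testable end to end without any slide archive.

## Worked example

```r
library(steatomorph)

# one synthetic field: 512 px at 0.5 um/px, 10% fat, with ground truth
gf <- generate_field(field_spec(target_fat_fraction = 0.10, seed = 7),
                     field_id = "demo")
gf$field
#> <rgb_field 'demo'> 512 x 512 px @ 0.5 um/px (256 x 256 um)

segment_fat(gf$field)
#> <segmentation_result 'demo'> fat 6554 um^2 / parenchyma 65536 um^2 = 10.00%
# ground truth for this field: 10.00%

# a 21-field biopsy, pooled
segs <- lapply(1:21, function(f) {
  g <- generate_field(field_spec(target_fat_fraction = 0.10, seed = 100 + f))
  segment_fat(g$field)
})
aggregate_mfpa(segs, biopsy_id = "demo_biopsy")
#> <biopsy_mfpa 'demo_biopsy'> mFPA 10.00% over 21 fields (adequacy: TRUE)

# a synthetic cohort and its full analysis
co  <- generate_cohort(cohort_spec(seed = 1))
rep <- cohort_report(co)
rep
#> <cohort_report> n = 136 patients
#>   bracket occupancy: <5=80  5-9.9=22  10-19.9=23  >=20=11
#>   AUROC ALT vs 5% mFPA: 0.696
#>   AUROC ALT vs 20% mFPA: 0.812
#>   AUROC AST vs 5% mFPA: 0.564
#>   AUROC AST vs 20% mFPA: 0.661

subset(rep$correlations, stratum == "together")
#>   stratum variable          rs            p   n
#>  together      ALT  0.45569391 3.594557e-08 136
#>  together      AST  0.10464195 2.250604e-01 136
#>  together       HA  0.73704499 0.000000e+00 136
#>  together       LR  0.52415438 3.915689e-11 136
#>  together      HpL -0.09449454 2.734678e-01 136
```

Reading the output: the segmenter recovers this field's true 10% fat fraction
exactly; the biopsy-level pooled mFPA over 21 fields is likewise on target.
In the cohort, ALT discriminates ≥20% steatosis well (AUROC 0.81) but ≥5%
only modestly (0.70), AST is weaker at both — and mFPA correlates strongly
with hepatocyte area (rs 0.74), moderately with lobule radius, and weakly
negatively with hepatocytes per lobule, the architectural signature of a
lobule that stops expanding while its cells keep swelling.

The hexagonal-lobule index for a non-steatotic biopsy (LR 466 µm, HA
273 µm²) is `hepatocytes_per_lobule(466, 273)` → 2066.6.

`run_end_to_end(pipeline_config(...))` chains everything — simulate cohort →
render fields → segment → pool mFPA → morphometry → report — and writes
byte-reproducible tables for a fixed seed.

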