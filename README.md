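# drquant

Quantitative assessment of **desmoplastic reaction (DR)** at the colorectal
cancer invasive front from H&E slide imagery.

Immature DR — defined by large areas of myxoid stroma just beyond the
muscularis propria — is a strong adverse prognostic factor in stage II/III
colorectal cancer, but its manual grading (comparing the largest myxoid
area against one 40x microscope field, 0.196 mm²) is subjective. `drquant`
makes the assessment quantitative and reproducible:

* **Margin bands.** From an invasive-front polyline and a tumour polygon it
  rasterises the outward bands Margin 1 (500 µm) and Margin 2 (1000 µm):
  a pixel is in the band iff its centre lies within the width of the front
  (exact Euclidean point-to-segment distance) and outside the tumour.
* **Morphometry.** 8-connected myxoid objects are measured inside each
  band: total, average and largest single area (mm²), plus Dice evaluation
  (`2·TP/(2·TP+FP+FN)` on areas) of any segmentation against ground truth.
* **Classification.** A patient is *immature* when the chosen feature
  strictly exceeds its cut-off — the data-derived automatic cut-off point
  (ACP) or the manual 0.196 mm² field area (MCP).
* **Survival statistics.** Optimal cut-point discovery by the maximally
  selected rank statistic (log-rank scores, permutation p-value),
  Kaplan–Meier + log-rank, univariate and forward-stepwise Cox models
  (Breslow ties), Benjamini–Hochberg correction, and stratified
  train/test splitting.
* **Segmentation interface.** Any model producing a per-pixel myxoid
  probability map plugs in; a reference colour/texture pixel classifier
  with HSV colour augmentation ships in the package (threshold 0.80,
  minimum object 0.1 mm², 1 µm/px).
* **Synthetic data.** Generators for H&E-like invasive-front slides with
  exact ground-truth masks and for survival cohorts with a planted hazard
  ratio, so the entire pipeline runs without external data.

## Worked example

```r
library(drquant)

# a synthetic slide: image, ground-truth myxoid mask, front + tumour annotation
s <- generate_slide(slide_gen_params(seed = 42))

# margin bands and area features from the ground-truth mask
res  <- resolution(1.0)                        # 1 um/px
obj  <- extract_objects(s$mask, res)
m1   <- build_margin_band(s$front, s$tumour,  500, res, dim(s$mask))
m2   <- build_margin_band(s$front, s$tumour, 1000, res, dim(s$mask))
rbind(compute_margin_features(obj, m1, "demo"),
      compute_margin_features(obj, m2, "demo"))
#>   patient_id  margin total_mm2 average_mm2 largest_mm2 n_objects
#> 1       demo Margin1  0.276098    0.138049    0.233138         2
#> 2       demo Margin2  0.560588    0.280294    0.327450         2

# classify DR: largest single area in Margin 1 vs the ACP (1.04863 mm^2)
classify_dr(compute_margin_features(obj, m1, "demo"), feature = "largest")
#>         patient_id feature  margin regime value_mm2 threshold_mm2 category
#> Margin1       demo largest Margin1    ACP  0.233138       1.04863    other

# a synthetic cohort with a planted hazard ratio of 3.5 for immature DR
d  <- generate_cohort(cohort_gen_params(n_patients = 528, seed = 7))
sp <- stratified_split(d, 0.75, strata = "dr_true", seed = 7)
tr <- d[sp$train, ]

# optimal cut-point for the largest-area feature, then a univariate Cox fit
ms <- maxstat_cutpoint(tr$largest_m1, tr$time_months, tr$event,
                       n_perm = 1000, seed = 7)
ms$best_cutpoint                               # near the 1.04863 mm^2 ACP
#> [1] 1.0439
tr$high <- as.integer(tr$largest_m1 > ms$best_cutpoint)
cox_fit(tr, "high")$table
#>   term       hr    lower   upper            p     coef        se
#> 1 high 3.329502 2.245518 4.93676 2.159762e-09 1.202823 0.2009624
```

The recovered cut-point lands next to the planted class boundary and the
hazard ratio next to the planted 3.5 — the generator and the statistics
agree end to end. (Numbers above are the output of this exact script.)

A thin command-line wrapper over the same functions is installed at
`inst/cli/drquant` (subcommands `segment`, `quantify`, `classify`, `dice`,
`cutpoint`, `simulate`, `run`).

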